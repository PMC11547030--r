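## Annotated circular mitogenome: the single source of coordinate conventions.
## Coordinates are 1-based inclusive throughout; a feature with end < start on
## a circular genome wraps the origin.

FEATURE_KINDS <- c("PCG", "tRNA", "rRNA", "noncoding")

empty_features <- function() {
  data.frame(name = character(0), kind = character(0), strand = character(0),
             start = integer(0), end = integer(0),
             start_codon = character(0), stop_codon = character(0),
             anticodon = character(0), stringsAsFactors = FALSE)
}

#' Construct an annotated (circular) genome
#'
#' The container every downstream analysis consumes: an optional DNA sequence,
#' a genome length, a topology, and an ordered feature table with 1-based
#' inclusive coordinates. On circular genomes a feature whose `end` is less
#' than its `start` wraps the origin.
#'
#' @param features data.frame with columns `name`, `kind` (one of PCG, tRNA,
#'   rRNA, noncoding), `strand` ("+"/"-"), `start`, `end`, and optionally
#'   `start_codon`, `stop_codon`, `anticodon`.
#' @param genome_length genome size in bp; defaults to `nchar(sequence)`.
#' @param sequence optional DNA string over A/C/G/T/N.
#' @param topology "circular" (default) or "linear".
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(features = empty_features(), genome_length = NULL,
                             sequence = NULL, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!is.null(sequence)) {
    sequence <- check_dna(sequence)
    if (is.null(genome_length)) genome_length <- nchar(sequence)
    if (genome_length != nchar(sequence))
      stop("genome_length does not match sequence length", call. = FALSE)
  }
  if (is.null(genome_length))
    stop("genome_length is required when no sequence is given", call. = FALSE)
  genome_length <- as.integer(genome_length)

  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (col in c("start_codon", "stop_codon", "anticodon"))
    if (is.null(features[[col]])) features[[col]] <- rep(NA_character_, nrow(features))
  needed <- c("name", "kind", "strand", "start", "end")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0)
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  features <- features[, c(needed, "start_codon", "stop_codon", "anticodon")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)

  if (nrow(features) > 0) {
    if (!all(features$kind %in% FEATURE_KINDS))
      stop("unknown feature kind: ",
           paste(setdiff(features$kind, FEATURE_KINDS), collapse = ", "),
           call. = FALSE)
    if (!all(features$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'", call. = FALSE)
    bad <- features$start < 1L | features$start > genome_length |
      features$end < 1L | features$end > genome_length
    if (any(bad))
      stop("feature coordinates outside [1, genome_length] for: ",
           paste(features$name[bad], collapse = ", "), call. = FALSE)
    if (topology == "linear" && any(features$end < features$start))
      stop("end < start is only valid on circular genomes", call. = FALSE)
    key <- paste(features$name, features$strand)
    if (anyDuplicated(key))
      stop("duplicate feature name on the same strand: ",
           paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(sequence = sequence, genome_length = genome_length,
                 topology = topology, features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("Annotated %s genome: %s bp, %d features%s\n", x$topology,
              format(x$genome_length, big.mark = ","), nrow(x$features),
              if (is.null(x$sequence)) " (no sequence)" else ""))
  if (nrow(x$features) > 0) {
    tab <- table(factor(x$features$kind, levels = FEATURE_KINDS))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

## length of one feature row, wrapping-aware
feature_length_one <- function(start, end, genome_length) {
  if (end >= start) end - start + 1L else genome_length - start + 1L + end
}

#' Read an annotation feature table (TSV)
#'
#' Reads a tab-separated table with columns Gene/Strand/Start/End/Kind and
#' optional StartCodon/StopCodon/Anticodon into an [annotated_genome()]
#' (sequence absent).
#'
#' @param path path to the TSV file (UTF-8, header row).
#' @param genome_length genome size in bp; coordinates are validated against it.
#' @param topology passed to [annotated_genome()].
#' @return an `annotated_genome` without sequence.
#' @export
read_feature_tsv <- function(path, genome_length, topology = "circular") {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, fill = TRUE,
                    na.strings = c("", "NA"))
  needed <- c("Gene", "Strand", "Start", "End", "Kind")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0)
    stop("feature TSV lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  opt <- function(col) if (col %in% names(tab)) tab[[col]] else rep(NA_character_, nrow(tab))
  features <- data.frame(name = tab$Gene, kind = tab$Kind, strand = tab$Strand,
                         start = tab$Start, end = tab$End,
                         start_codon = opt("StartCodon"),
                         stop_codon = opt("StopCodon"),
                         anticodon = opt("Anticodon"),
                         stringsAsFactors = FALSE)
  annotated_genome(features, genome_length = genome_length, topology = topology)
}

#' Write an annotation feature table (TSV)
#'
#' Inverse of [read_feature_tsv()]: canonical column order
#' Gene/Strand/Start/End/Kind/StartCodon/StopCodon/Anticodon, tab-separated,
#' empty string for missing codon/anticodon fields.
#'
#' @param genome an `annotated_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(genome, path) {
  f <- genome$features
  out <- data.frame(Gene = f$name, Strand = f$strand, Start = f$start,
                    End = f$end, Kind = f$kind,
                    StartCodon = ifelse(is.na(f$start_codon), "", f$start_codon),
                    StopCodon = ifelse(is.na(f$stop_codon), "", f$stop_codon),
                    Anticodon = ifelse(is.na(f$anticodon), "", f$anticodon),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

## ---- GenBank flat file ----------------------------------------------------

## Minimal GenBank flat-file reader: LOCUS length/topology, FEATURES entries of
## type CDS/tRNA/rRNA/misc_feature/D-loop, ORIGIN sequence. Locations may use
## complement() and join(); qualifiers /gene, /product, /codon_start,
## /anticodon are honoured where present.

parse_gb_location <- function(loc, feature_label) {
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  rng <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$|^(\\d+)$", parts))
  starts <- ends <- integer(length(parts))
  for (i in seq_along(parts)) {
    m <- rng[[i]]
    if (length(m) == 0 || m[1] == "")
      stop("malformed location for feature '", feature_label, "': ", parts[i],
           call. = FALSE)
    if (m[2] != "") {
      starts[i] <- as.integer(m[2]); ends[i] <- as.integer(m[3])
    } else {
      starts[i] <- ends[i] <- as.integer(m[4])
    }
  }
  ## join() across the origin (e.g. join(15000..15772,1..100)) collapses to a
  ## single wrapping feature; contiguous joins collapse to their span
  list(start = starts[1], end = ends[length(ends)], strand = strand)
}

#' Read a GenBank flat file
#'
#' Parses a GenBank flat file into an [annotated_genome()]. CDS entries become
#' kind "PCG", tRNA/rRNA entries their own kinds, and misc_feature/D-loop
#' entries kind "noncoding". `complement()` locations set the minus strand;
#' `join()` locations are collapsed to their span (wrapping the origin when the
#' segments cross it). A file without an ORIGIN block yields a genome with
#' sequence absent and a warning.
#'
#' @param path path to a GenBank flat file.
#' @return an `annotated_genome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  genome_length <- NA_integer_
  topology <- "linear"
  if (length(locus) > 0) {
    m <- regmatches(locus[1], regexec("(\\d+)\\s+bp", locus[1]))[[1]]
    if (length(m) == 2) genome_length <- as.integer(m[2])
    if (grepl("circular", locus[1], ignore.case = TRUE)) topology <- "circular"
  }

  ## sequence from ORIGIN block
  io <- grep("^ORIGIN", lines)
  sequence <- NULL
  if (length(io) == 1) {
    iend <- grep("^//", lines)
    iend <- if (length(iend) > 0) min(iend[iend > io]) else length(lines) + 1L
    seq_lines <- lines[seq(io + 1L, iend - 1L)]
    sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
    if (nchar(sequence) == 0) sequence <- NULL
  }
  if (is.null(sequence))
    warning("no ORIGIN sequence in ", basename(path),
            "; genome returned without sequence", call. = FALSE)
  if (is.na(genome_length)) {
    if (is.null(sequence))
      stop("GenBank file has neither a LOCUS length nor an ORIGIN sequence",
           call. = FALSE)
    genome_length <- nchar(sequence)
  }

  ## feature block: entries start at column 6, qualifiers at column 22
  if_start <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(if_start) == 1) {
    iend <- if (length(io) == 1) io else length(lines) + 1L
    block <- lines[seq(if_start + 1L, iend - 1L)]
    is_entry <- grepl("^ {5}\\S", block)
    entry_idx <- which(is_entry)
    kinds <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
               misc_feature = "noncoding", `D-loop` = "noncoding")
    rows <- list()
    for (j in seq_along(entry_idx)) {
      i0 <- entry_idx[j]
      i1 <- if (j < length(entry_idx)) entry_idx[j + 1] - 1L else length(block)
      header <- block[i0]
      key <- sub("^ {5}(\\S+).*$", "\\1", header)
      if (!key %in% names(kinds)) next
      body <- block[seq(i0, i1)]
      ## location may continue over lines until the first qualifier
      qual_start <- grep("^ {21}/", body)
      loc_end <- if (length(qual_start) > 0) qual_start[1] - 1L else length(body)
      loc <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", body[1]),
                            if (loc_end >= 2) trimws(body[2:loc_end]) else character(0))),
                   collapse = "")
      quals <- body[grepl("^ {21}/", body)]
      getq <- function(name) {
        hit <- grep(paste0("^ {21}/", name, "="), quals, value = TRUE)
        if (length(hit) == 0) return(NA_character_)
        gsub('"', "", sub(paste0("^ {21}/", name, "="), "", hit[1]))
      }
      label <- getq("gene")
      if (is.na(label)) label <- getq("product")
      if (is.na(label)) label <- paste0(key, "_", j)
      pos <- parse_gb_location(loc, label)
      rows[[length(rows) + 1L]] <- data.frame(
        name = label, kind = unname(kinds[key]), strand = pos$strand,
        start = pos$start, end = pos$end,
        start_codon = NA_character_, stop_codon = NA_character_,
        anticodon = toupper(getq("anticodon")), stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) feats <- do.call(rbind, rows)
  }
  annotated_genome(feats, genome_length = genome_length, sequence = sequence,
                   topology = topology)
}

## ---- sequence extraction --------------------------------------------------

## raw slice on the annotated (+) strand, wrapping-aware
slice_region <- function(genome, start, end) {
  if (is.null(genome$sequence))
    stop("genome has no sequence; cannot extract regions", call. = FALSE)
  if (end >= start) {
    substr(genome$sequence, start, end)
  } else {
    if (genome$topology != "circular")
      stop("end < start on a linear genome", call. = FALSE)
    paste0(substr(genome$sequence, start, genome$genome_length),
           substr(genome$sequence, 1, end))
  }
}

#' Extract a feature's sequence in coding orientation
#'
#' Returns the feature's sequence read 5'->3' on its annotated strand:
#' minus-strand features are reverse-complemented, origin-wrapping features
#' concatenate tail + head. Incomplete stop codons (feature length not a
#' multiple of 3, e.g. the single terminal T of COX1/NAD4) are preserved.
#'
#' @param genome an `annotated_genome` with sequence.
#' @param feature a feature name (string) or a single-row subset of
#'   `genome$features`.
#' @return DNA string of length equal to the feature length.
#' @export
extract_cds <- function(genome, feature) {
  if (is.character(feature)) {
    hit <- genome$features[genome$features$name == feature, , drop = FALSE]
    if (nrow(hit) == 0) stop("no feature named '", feature, "'", call. = FALSE)
    feature <- hit[1, , drop = FALSE]
  }
  s <- slice_region(genome, feature$start, feature$end)
  if (feature$strand == "-") revcomp(s) else s
}
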