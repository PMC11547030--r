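## Base composition, AT/GC content and strand-asymmetry skews.
## Skews follow the signed convention AT skew = (A-T)/(A+T),
## GC skew = (G-C)/(G+C); they are computed from counts (or from printed
## percentages in table-replay use, which is equivalent up to rounding).

#' Base composition of a DNA string
#'
#' @param seq DNA string (A/C/G/T/N); N bases are excluded from denominators.
#' @param region label stored in the profile.
#' @return one-row data.frame of class `composition_profile`: region, length
#'   (bp, N included), A/T/G/C percentages, at_percent, gc_percent, at_skew,
#'   gc_skew. Percentages are full precision; round only for display.
#' @export
base_composition <- function(seq, region = "region") {
  seq <- check_dna(seq)
  v <- seq_to_vec(seq)
  counts <- table(factor(v, levels = c(DNA_BASES, "N")))
  n_acgt <- sum(counts[DNA_BASES])
  if (n_acgt == 0) stop("sequence is empty or all-N", call. = FALSE)
  freq <- 100 * counts[DNA_BASES] / n_acgt
  sk <- skews(freq)
  out <- data.frame(region = region, length = length(v),
                    A = freq[["A"]], T = freq[["T"]],
                    G = freq[["G"]], C = freq[["C"]],
                    at_percent = freq[["A"]] + freq[["T"]],
                    gc_percent = freq[["G"]] + freq[["C"]],
                    at_skew = sk[["at_skew"]], gc_skew = sk[["gc_skew"]],
                    stringsAsFactors = FALSE)
  class(out) <- c("composition_profile", class(out))
  out
}

#' AT and GC skew
#'
#' `AT skew = (A - T)/(A + T)`, `GC skew = (G - C)/(G + C)` (signed). Accepts
#' counts or percentages (the ratio is scale-free), so it can replay printed
#' composition tables directly.
#'
#' @param freq named numeric with elements A, T, G, C (counts or percentages).
#' @return named numeric `c(at_skew, gc_skew)`; a zero denominator yields NA
#'   with a warning rather than NaN.
#' @export
skews <- function(freq) {
  stopifnot(all(c("A", "T", "G", "C") %in% names(freq)))
  at <- freq[["A"]] + freq[["T"]]
  gc <- freq[["G"]] + freq[["C"]]
  at_skew <- if (at > 0) (freq[["A"]] - freq[["T"]]) / at else {
    warning("A + T == 0; AT skew undefined", call. = FALSE); NA_real_
  }
  gc_skew <- if (gc > 0) (freq[["G"]] - freq[["C"]]) / gc else {
    warning("G + C == 0; GC skew undefined", call. = FALSE); NA_real_
  }
  c(at_skew = at_skew, gc_skew = gc_skew)
}

#' Composition profiles per genomic region
#'
#' Reproduces a per-region composition table (full genome, concatenated PCGs,
#' each rRNA, concatenated tRNAs, control region, repeat region, per strand).
#' Multi-feature regions are concatenated in feature order. Two reading
#' conventions are emitted for regions containing minus-strand features:
#' `"annotated"` (each feature read 5'->3' on its own strand, i.e. its coding
#' sequence) and `"plus"` (the plus-strand slice of the same span); rows are
#' labelled with the convention used. For `by_strand`, features on each strand
#' are concatenated and read on their annotated strand.
#'
#' @param genome an `annotated_genome` with sequence.
#' @param grouping one of "full", "PCGs", "rRNA_each", "tRNAs", "CR", "RR",
#'   "by_strand".
#' @param orientation "annotated", "plus", or "both" (default "both"; "full"
#'   and "by_strand" have a single natural reading and ignore it).
#' @return data.frame of composition profiles, one row per region (x reading).
#' @export
region_profiles <- function(genome, grouping = c("full", "PCGs", "rRNA_each",
                                                 "tRNAs", "CR", "RR", "by_strand"),
                            orientation = c("both", "annotated", "plus")) {
  grouping <- match.arg(grouping)
  orientation <- match.arg(orientation)
  if (is.null(genome$sequence))
    stop("genome has no sequence; composition requires one", call. = FALSE)
  f <- genome$features

  concat <- function(rows, reading) {
    paste(vapply(seq_len(nrow(rows)), function(i) {
      s <- slice_region(genome, rows$start[i], rows$end[i])
      if (reading == "annotated" && rows$strand[i] == "-") revcomp(s) else s
    }, character(1)), collapse = "")
  }
  both_rows <- function(rows, label) {
    if (nrow(rows) == 0)
      stop("no features for region '", label, "'", call. = FALSE)
    readings <- if (orientation == "both") c("annotated", "plus") else orientation
    ## identical when no minus-strand feature is involved
    if (all(rows$strand == "+")) readings <- readings[1]
    do.call(rbind, lapply(readings, function(r)
      base_composition(concat(rows, r), region = paste0(label, " (", r, ")"))))
  }

  out <- switch(grouping,
    full = base_composition(genome$sequence, region = "Fulllength"),
    PCGs = both_rows(f[f$kind == "PCG", , drop = FALSE], "PCGs"),
    rRNA_each = do.call(rbind, lapply(which(f$kind == "rRNA"), function(i)
      both_rows(f[i, , drop = FALSE], f$name[i]))),
    tRNAs = both_rows(f[f$kind == "tRNA", , drop = FALSE], "tRNAs"),
    CR = both_rows(f[f$name == "CR", , drop = FALSE], "CR"),
    RR = both_rows(f[f$name == "RR", , drop = FALSE], "RR"),
    by_strand = rbind(
      base_composition(concat(f[f$strand == "+", , drop = FALSE], "annotated"),
                       region = "+ strand"),
      base_composition(concat(f[f$strand == "-", , drop = FALSE], "annotated"),
                       region = "- strand")))
  rownames(out) <- NULL
  out
}
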