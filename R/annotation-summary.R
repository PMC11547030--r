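## Gene-organization arithmetic: sizes, intergenic spacers, overlaps, strand
## partition. The single gap convention is
##   gap(i -> i+1) = start(i+1) - end(i) - 1
## (circular across the origin); gap > 0 is a spacer, gap < 0 an overlap of
## |gap| bp, gap == 0 abutting and counted in neither class.

#' Feature lengths
#'
#' @param genome an `annotated_genome` with at least one feature.
#' @return named integer vector of feature lengths in bp (end - start + 1,
#'   wrapping-aware).
#' @export
feature_lengths <- function(genome) {
  f <- genome$features
  if (nrow(f) == 0) stop("genome has no features", call. = FALSE)
  setNames(mapply(feature_length_one, f$start, f$end,
                  MoreArgs = list(genome_length = genome$genome_length)),
           f$name)
}

## signed gap between consecutive features; last->first across the origin on
## circular genomes
adjacent_gaps <- function(genome) {
  f <- genome$features
  n <- nrow(f)
  if (is.unsorted(f$start))
    stop("features must be sorted by start", call. = FALSE)
  if (n < 2) return(integer(0))
  gaps <- f$start[-1] - f$end[-n] - 1L
  nms <- paste(f$name[-n], f$name[-1], sep = " -> ")
  if (genome$topology == "circular") {
    ## when the last feature itself wraps the origin its end is already in
    ## [1, start(first)) coordinates, so no extra turn is added
    wrap <- if (f$end[n] < f$start[n])
      f$start[1] - f$end[n] - 1L
    else
      f$start[1] + genome$genome_length - f$end[n] - 1L
    gaps <- c(gaps, wrap)
    nms <- c(nms, paste(f$name[n], f$name[1], sep = " -> "))
  }
  setNames(gaps, nms)
}

#' Gene-organization report: spacers, overlaps, counts
#'
#' For every pair of consecutive features (including last -> first across the
#' origin on circular genomes) computes the signed gap
#' `start(next) - end(prev) - 1`; positive gaps are intergenic spacers,
#' negative gaps overlaps, zero gaps neither. Also tabulates feature counts by
#' kind and by (kind, strand), and the two PCG size sums (raw, and excluding
#' stop codons).
#'
#' @param genome an `annotated_genome` with sorted features.
#' @return object of class `organization_report`: list with `per_feature`
#'   (data.frame: name, kind, strand, length, intergenic = gap to the previous
#'   feature), `n_spacers`, `n_overlaps`, `spacer_range`, `overlap_range`,
#'   `counts`, `strand_counts`, `pcg_bp`, `pcg_codons_excl_stop`.
#' @export
intergenic_profile <- function(genome) {
  f <- genome$features
  if (nrow(f) == 0) stop("genome has no features", call. = FALSE)
  lens <- feature_lengths(genome)
  gaps <- adjacent_gaps(genome)
  ## gap printed on a row = gap between the previous feature and this one;
  ## on circular genomes the first row receives the origin-crossing gap
  if (genome$topology == "circular" && length(gaps) == nrow(f)) {
    intergenic <- c(gaps[length(gaps)], gaps[-length(gaps)])
  } else {
    intergenic <- c(NA_integer_, gaps)
  }
  per_feature <- data.frame(name = f$name, kind = f$kind, strand = f$strand,
                            length = as.integer(lens),
                            intergenic = as.integer(intergenic),
                            stringsAsFactors = FALSE)
  spacers <- gaps[!is.na(gaps) & gaps > 0]
  overlaps <- -gaps[!is.na(gaps) & gaps < 0]
  counts <- table(factor(f$kind, levels = FEATURE_KINDS))
  strand_counts <- table(factor(f$kind, levels = FEATURE_KINDS),
                         factor(f$strand, levels = c("+", "-")))
  pcg_len <- lens[f$kind == "PCG"]
  pcg_codons <- sum((pcg_len - pcg_len %% 3L) / 3L) - sum(pcg_len %% 3L == 0L)
  structure(list(per_feature = per_feature,
                 n_spacers = length(spacers),
                 n_overlaps = length(overlaps),
                 spacer_range = if (length(spacers)) range(spacers) else c(NA_integer_, NA_integer_),
                 overlap_range = if (length(overlaps)) range(overlaps) else c(NA_integer_, NA_integer_),
                 counts = counts,
                 strand_counts = strand_counts,
                 pcg_bp = sum(pcg_len),
                 pcg_codons_excl_stop = pcg_codons,
                 genome_length = genome$genome_length),
            class = "organization_report")
}

#' @export
print.organization_report <- function(x, ...) {
  cat(sprintf("Organization report: %d features on a %s bp genome\n",
              nrow(x$per_feature), format(x$genome_length, big.mark = ",")))
  cat("  counts:", paste(sprintf("%s %d", names(x$counts), x$counts),
                         collapse = ", "), "\n")
  cat(sprintf("  %d intergenic spacers (%s-%s bp), %d overlaps (%s-%s bp)\n",
              x$n_spacers, x$spacer_range[1], x$spacer_range[2],
              x$n_overlaps, x$overlap_range[1], x$overlap_range[2]))
  cat(sprintf("  PCGs: %s bp raw; %s codons excluding stop codons\n",
              format(x$pcg_bp, big.mark = ","),
              format(x$pcg_codons_excl_stop, big.mark = ",")))
  invisible(x)
}

#' Partition features by kind and strand
#'
#' @param genome an `annotated_genome`.
#' @return named list, one element per (kind, strand) combination present,
#'   e.g. `$"PCG:-"`, each a character vector of feature names. Every feature
#'   appears exactly once.
#' @export
strand_partition <- function(genome) {
  f <- genome$features
  if (nrow(f) == 0) return(setNames(list(), character(0)))
  split(f$name, paste(f$kind, f$strand, sep = ":"))
}
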