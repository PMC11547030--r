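## Shared generators for test inputs (no stored fixtures beyond the shipped
## annotation tables; everything else is built in code).

random_dna <- function(n, at = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

random_codon_counts <- function(code, lambda = 20) {
  counts <- rpois(length(code$sense_codons), lambda)
  names(counts) <- code$sense_codons
  counts
}

## tiny genome whose features tile the circle exactly
tiling_plan <- function() {
  data.frame(
    name = c("g1", "t1", "g2", "r1", "nc"),
    kind = c("PCG", "tRNA", "PCG", "rRNA", "noncoding"),
    strand = c("+", "+", "-", "-", "+"),
    length = c(300L, 70L, 450L, 120L, 60L),
    gap_after = c(5L, -3L, 0L, 10L, -12L),
    stringsAsFactors = FALSE)
}
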