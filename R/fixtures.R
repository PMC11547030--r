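## Shipped reference data: the annotation table and the printed per-region
## composition table of the Rhopalosiphum nymphaeae (waterlily aphid)
## mitochondrial genome, GenBank accession OM214586.1 (15,772 bp, circular).
## The annotation fixture carries coordinates only, so every organization
## statistic is recomputable without downloading the accession sequence.

#' Annotated waterlily-aphid mitogenome (coordinates only)
#'
#' The 39-feature annotation (13 protein-coding genes, 22 tRNAs, 2 rRNAs,
#' control region CR and aphid repeat region RR) of the R. nymphaeae
#' mitochondrial genome (GenBank OM214586.1), 15,772 bp circular, as an
#' [annotated_genome()] without sequence.
#'
#' @return an `annotated_genome`.
#' @export
waterlily_aphid_genome <- function() {
  read_feature_tsv(
    system.file("extdata", "rhopalosiphum_nymphaeae_mt_features.tsv",
                package = "mitocodon", mustWork = TRUE),
    genome_length = 15772, topology = "circular")
}

#' Published per-region base composition of the waterlily-aphid mitogenome
#'
#' The printed composition table (percent A/T/G/C, AT%, GC% per region) for
#' the R. nymphaeae mitochondrial genome; input for skew replay via [skews()].
#'
#' @return data.frame with columns Region, Length, A, T, G, C, AT, GC.
#' @export
waterlily_aphid_composition <- function() {
  read.delim(system.file("extdata", "rhopalosiphum_nymphaeae_mt_composition.tsv",
                         package = "mitocodon", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Feature plan replaying the waterlily-aphid gene organization
#'
#' Converts the shipped annotation into a [genome_spec()] feature plan
#' (lengths and signed gaps), so [make_genome()] can synthesize a sequence
#' whose organization arithmetic reproduces the published annotation exactly.
#'
#' @param at_target AT fraction for the synthetic sequence (default 0.8434,
#'   the published genome-wide value).
#' @param seed integer seed.
#' @return a `genome_spec`.
#' @export
waterlily_aphid_replay_spec <- function(at_target = 0.8434, seed = 1) {
  g <- waterlily_aphid_genome()
  f <- g$features
  lens <- feature_lengths(g)
  gaps <- adjacent_gaps(g)
  plan <- data.frame(name = f$name, kind = f$kind, strand = f$strand,
                     length = as.integer(lens), gap_after = as.integer(gaps),
                     stringsAsFactors = FALSE)
  genome_spec(plan, genome_length = g$genome_length, at_target = at_target,
              seed = seed)
}
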