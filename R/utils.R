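#' @import Biostrings
#' @importFrom stats lm coef pt t.test setNames rexp var sd
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## complement without reversal (for 'complementary' dispersed repeats)
complement_seq <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

reverse_seq <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(v) paste(rev(v), collapse = ""), character(1))
}

seq_to_vec <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

vec_to_seq <- function(v) paste(v, collapse = "")

check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  bases <- if (allow_n) c(DNA_BASES, "N") else DNA_BASES
  bad <- setdiff(unique(seq_to_vec(toupper(x))), bases)
  if (length(bad) > 0)
    stop(sprintf("%s contains non-DNA characters: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(toupper(x))
}

#' Read a FASTA file as a named character vector
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

split_codons <- function(cds) {
  n <- nchar(cds)
  n_codon <- n %/% 3L
  if (n_codon == 0L) return(character(0))
  substring(cds, seq(1L, by = 3L, length.out = n_codon),
            seq(3L, by = 3L, length.out = n_codon))
}
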