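## NCBI translation tables, stored as 64-character strings in TTT..GGG order
## (first base slowest, T C A G order), the layout NCBI uses.

.code_strings <- list(
  `1` = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `2` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
  `5` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG"
)

.aa3 <- c(F = "Phe", L = "Leu", S = "Ser", Y = "Tyr", C = "Cys", W = "Trp",
          P = "Pro", H = "His", Q = "Gln", R = "Arg", I = "Ile", M = "Met",
          T = "Thr", N = "Asn", K = "Lys", V = "Val", A = "Ala", D = "Asp",
          E = "Glu", G = "Gly", `*` = "Stop")

#' Genetic code with split synonymous families
#'
#' Builds the codon table for an NCBI translation table (default 5, the
#' invertebrate mitochondrial code: AGA/AGG = Ser, ATA = Met, TGA = Trp) and
#' partitions the sense codons into synonymous families. Families that span
#' more than one first-two-base "codon box" are split into separate families
#' named by the conventional suffixes (under code 5: Leu1 = CTN, Leu2 = TTR,
#' Ser1 = AGN, Ser2 = TCN), so every family shares its first two bases and,
#' under code 5, has size 2 or 4.
#'
#' @param table_id NCBI translation table id; one of 1, 2, 5.
#' @return an object of class `genetic_code`: list with `table_id`,
#'   `codon_to_aa` (named character, 64 codons, "*" = stop), `stop_codons`,
#'   `sense_codons`, `families` (named list of codon vectors) and
#'   `codon_to_family`.
#' @export
genetic_code <- function(table_id = 5) {
  key <- as.character(table_id)
  if (!key %in% names(.code_strings))
    stop("unsupported translation table: ", table_id, call. = FALSE)
  bases <- c("T", "C", "A", "G")
  ## codons enumerated with first base slowest in T,C,A,G order
  codons <- character(64)
  k <- 1L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons[k] <- paste0(b1, b2, b3); k <- k + 1L
  }
  aa <- strsplit(.code_strings[[key]], "")[[1]]
  codon_to_aa <- setNames(aa, codons)
  stop_codons <- codons[aa == "*"]
  sense <- codons[aa != "*"]

  ## split families by (amino acid, first two bases)
  box <- substr(sense, 1, 2)
  fam_key <- paste(codon_to_aa[sense], box, sep = ".")
  fam_list <- split(sense, fam_key)
  ## name families: Xxx if the amino acid has a single box, Xxx1/Xxx2 ... if split
  aa_of_fam <- vapply(fam_list, function(cs) unname(codon_to_aa[cs[1]]), character(1))
  fam_names <- character(length(fam_list))
  for (a in unique(aa_of_fam)) {
    idx <- which(aa_of_fam == a)
    if (length(idx) == 1L) {
      fam_names[idx] <- .aa3[[a]]
    } else {
      ## conventional numbering for mito codes: Leu1 = CTN, Leu2 = TTR,
      ## Ser1 = AGN, Ser2 = TCN; otherwise number by box alphabetically
      boxes <- vapply(fam_list[idx], function(cs) substr(cs[1], 1, 2), character(1))
      num <- rank(boxes)  # AG < CT < TC < TT alphabetical
      if (a == "L") num <- ifelse(boxes == "CT", 1, 2)
      if (a == "S") num <- ifelse(boxes == "AG", 1, 2)
      if (a == "R") num <- ifelse(boxes == "CG", 1, 2)
      fam_names[idx] <- paste0(.aa3[[a]], num)
    }
  }
  names(fam_list) <- fam_names
  fam_list <- fam_list[order(names(fam_list))]
  codon_to_family <- setNames(rep(names(fam_list), lengths(fam_list)),
                              unlist(fam_list, use.names = FALSE))
  structure(list(table_id = as.integer(table_id),
                 codon_to_aa = codon_to_aa,
                 stop_codons = stop_codons,
                 sense_codons = sense,
                 families = fam_list,
                 codon_to_family = codon_to_family),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("Genetic code (NCBI table %d): %d sense codons, %d stop codons, %d synonymous families\n",
              x$table_id, length(x$sense_codons), length(x$stop_codons),
              length(x$families)))
  sizes <- table(lengths(x$families))
  cat("  family sizes:",
      paste(sprintf("%s-fold x %d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Translate in-frame codons
#'
#' @param codons character vector of codons (DNA alphabet).
#' @param code a [genetic_code()].
#' @return character vector of one-letter amino acids ("*" = stop, NA for
#'   codons containing non-ACGT characters).
#' @export
translate_codons <- function(codons, code = genetic_code(5)) {
  unname(code$codon_to_aa[toupper(codons)])
}
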