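## Codon counting, RSCU, third-position composition, Wright's effective number
## of codons (ENc) with the ENc-plot expected curve, PR2-bias coordinates and
## the neutrality (GC12 ~ GC3) regression.

#' Count codons of an in-frame coding sequence
#'
#' The sequence is read in frame 0. Trailing 1-2 nt (an incomplete stop codon,
#' completed by polyadenylation in mitochondrial transcripts) are dropped.
#' Stop codons are tallied separately and never enter codon-usage statistics.
#' Codons containing N are ignored. An internal (non-terminal) stop codon
#' triggers a warning naming its position, as a likely frame error.
#'
#' @param cds DNA string, length >= 3.
#' @param code a [genetic_code()].
#' @param drop_incomplete_stop drop the trailing partial codon (default TRUE;
#'   FALSE raises an error if length is not a multiple of 3).
#' @return list of class `codon_counts`: `counts` (named integer over the
#'   code's sense codons), `stop_counts` (named integer over stop codons),
#'   `n_codons` (sum of sense counts), `dropped_nt`.
#' @export
count_codons <- function(cds, code = genetic_code(5), drop_incomplete_stop = TRUE) {
  cds <- check_dna(cds, what = "CDS")
  if (nchar(cds) < 3) stop("CDS shorter than one codon", call. = FALSE)
  rem <- nchar(cds) %% 3L
  if (rem != 0L && !drop_incomplete_stop)
    stop("CDS length not a multiple of 3", call. = FALSE)
  codons <- split_codons(cds)
  keep <- !grepl("N", codons, fixed = TRUE)
  is_stop <- codons %in% code$stop_codons
  internal_stop <- which(is_stop & seq_along(codons) < length(codons))
  if (length(internal_stop) > 0)
    warning(sprintf("internal stop codon(s) at codon position(s) %s (frame error?)",
                    paste(internal_stop, collapse = ", ")), call. = FALSE)
  counts <- table(factor(codons[keep & !is_stop], levels = code$sense_codons))
  stop_counts <- table(factor(codons[keep & is_stop], levels = code$stop_codons))
  structure(list(counts = setNames(as.integer(counts), names(counts)),
                 stop_counts = setNames(as.integer(stop_counts), names(stop_counts)),
                 n_codons = sum(counts), dropped_nt = rem),
            class = "codon_counts")
}

as_sense_counts <- function(codon_counts, code) {
  if (inherits(codon_counts, "codon_counts")) return(codon_counts$counts)
  if (is.null(names(codon_counts)))
    stop("codon counts must be named by codon", call. = FALSE)
  out <- setNames(integer(length(code$sense_codons)), code$sense_codons)
  known <- intersect(names(codon_counts), code$sense_codons)
  out[known] <- as.integer(codon_counts[known])
  out
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) * family_size / sum(family counts)`: the observed count
#' divided by the count expected under uniform usage within the synonymous
#' family. Unused codons in a used family get 0; codons of entirely unused
#' families get NA (undefined).
#'
#' @param codon_counts a `codon_counts` object or named integer vector.
#' @param code a [genetic_code()].
#' @return named numeric over sense codons.
#' @export
rscu <- function(codon_counts, code = genetic_code(5)) {
  counts <- as_sense_counts(codon_counts, code)
  out <- setNames(rep(NA_real_, length(counts)), names(counts))
  for (fam in code$families) {
    tot <- sum(counts[fam])
    if (tot > 0) out[fam] <- counts[fam] * length(fam) / tot
  }
  out
}

#' Amino-acid (synonymous-family) usage frequencies
#'
#' @param codon_counts a `codon_counts` object or named integer vector.
#' @param code a [genetic_code()].
#' @return named numeric, percent of total codons per family (Leu1/Leu2 and
#'   Ser1/Ser2 reported separately under split mito conventions).
#' @export
aa_frequencies <- function(codon_counts, code = genetic_code(5)) {
  counts <- as_sense_counts(codon_counts, code)
  fam_tot <- vapply(code$families, function(fam) sum(counts[fam]), numeric(1))
  100 * fam_tot / sum(counts)
}

#' Positional GC content and third-position base composition
#'
#' @param codon_counts a `codon_counts` object or named integer vector.
#' @param code a [genetic_code()].
#' @return list: `A3`, `T3`, `G3`, `C3` (third-position base counts over sense
#'   codons), `gc3` (percent GC at third positions), `gc3s` (same, restricted
#'   to codons in synonymous families of size >= 2 -- under the split code-5
#'   convention that is every sense codon, so gc3s == gc3 there), `gc12`
#'   (percent GC averaged over first and second positions), `gc1`, `gc2`.
#' @export
third_position_composition <- function(codon_counts, code = genetic_code(5)) {
  counts <- as_sense_counts(codon_counts, code)
  n <- sum(counts)
  if (n == 0) stop("no sense codons", call. = FALSE)
  base_at <- function(pos, base, subset = names(counts))
    sum(counts[subset][substr(subset, pos, pos) == base])
  n3 <- setNames(vapply(DNA_BASES, function(b) base_at(3, b), numeric(1)), DNA_BASES)
  syn_codons <- names(counts)[lengths(code$families)[code$codon_to_family[names(counts)]] >= 2]
  n_syn <- sum(counts[syn_codons])
  gc1 <- 100 * (base_at(1, "G") + base_at(1, "C")) / n
  gc2 <- 100 * (base_at(2, "G") + base_at(2, "C")) / n
  list(A3 = n3[["A"]], T3 = n3[["T"]], G3 = n3[["G"]], C3 = n3[["C"]],
       gc3 = 100 * (n3[["G"]] + n3[["C"]]) / n,
       gc3s = if (n_syn > 0)
         100 * (base_at(3, "G", syn_codons) + base_at(3, "C", syn_codons)) / n_syn
       else NA_real_,
       gc12 = (gc1 + gc2) / 2, gc1 = gc1, gc2 = gc2)
}

#' Wright's effective number of codons (ENc)
#'
#' Per synonymous family with n >= 2 codons observed, the codon homozygosity is
#' estimated as `F = (n * sum(p_i^2) - 1) / (n - 1)`; families with F == 0 or
#' n < 2 are excluded. Family F values are averaged within each degeneracy
#' class (family size), and `ENc = sum over classes of N_class / mean(F_class)`.
#' A degeneracy class with no estimable family gets the mean homozygosity of
#' the available classes imputed, with a warning. The raw estimate is
#' reported, with attribute `above_nominal = TRUE` when it exceeds 61.
#'
#' @param codon_counts a `codon_counts` object or named integer vector.
#' @param code a [genetic_code()].
#' @return ENc estimate (numeric scalar).
#' @export
enc <- function(codon_counts, code = genetic_code(5)) {
  counts <- as_sense_counts(codon_counts, code)
  fam_size <- lengths(code$families)
  f_hat <- rep(NA_real_, length(code$families))
  for (i in seq_along(code$families)) {
    cnt <- counts[code$families[[i]]]
    n <- sum(cnt)
    if (n < 2) next
    f <- (n * sum((cnt / n)^2) - 1) / (n - 1)
    if (f > 0) f_hat[i] <- f
  }
  classes <- sort(unique(fam_size))
  class_mean <- setNames(vapply(classes, function(k) {
    vals <- f_hat[fam_size == k]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1)), classes)
  if (anyNA(class_mean)) {
    if (all(is.na(class_mean)))
      stop("no synonymous family has 2 or more codons; ENc undefined", call. = FALSE)
    warning("degeneracy class(es) ", paste(classes[is.na(class_mean)], collapse = ", "),
            " have no estimable family; imputing the mean homozygosity of the other classes",
            call. = FALSE)
    class_mean[is.na(class_mean)] <- mean(class_mean, na.rm = TRUE)
  }
  n_class <- vapply(classes, function(k) sum(fam_size == k), numeric(1))
  val <- sum(n_class / class_mean)
  if (val > 61) attr(val, "above_nominal") <- TRUE
  val
}

#' Expected ENc under mutation alone (ENc-plot curve)
#'
#' `ENc_exp = 2 + s + 29 / (s^2 + (1 - s)^2)` where `s` is GC3s as a fraction.
#'
#' @param gc3s numeric in `[0, 1]` (fraction, not percent).
#' @return expected ENc (vectorised).
#' @export
enc_expected <- function(gc3s) {
  stopifnot(all(gc3s >= 0 & gc3s <= 1))
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' PR2-bias coordinates
#'
#' Parity-rule-2 plot coordinates from third-position base counts:
#' x = G3/(G3 + C3) (GC bias, abscissa), y = A3/(A3 + T3) (AT bias, ordinate).
#' (0.5, 0.5) indicates no strand-specific bias. A zero denominator yields NA
#' for that coordinate with a warning.
#'
#' @param codon_counts a `codon_counts` object or named integer vector.
#' @param code a [genetic_code()].
#' @return named numeric `c(x, y)`.
#' @export
pr2_point <- function(codon_counts, code = genetic_code(5)) {
  p3 <- third_position_composition(codon_counts, code)
  x <- if (p3$G3 + p3$C3 > 0) p3$G3 / (p3$G3 + p3$C3) else {
    warning("G3 + C3 == 0; PR2 abscissa undefined", call. = FALSE); NA_real_
  }
  y <- if (p3$A3 + p3$T3 > 0) p3$A3 / (p3$A3 + p3$T3) else {
    warning("A3 + T3 == 0; PR2 ordinate undefined", call. = FALSE); NA_real_
  }
  c(x = x, y = y)
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean GC at codon positions 1 and 2) on GC3,
#' with the two-sided t-test p-value for slope != 0 on n - 2 df. A slope near
#' 1 indicates mutation pressure dominating; a flat slope, selection.
#'
#' @param gc3 numeric vector (percent or fraction, one per gene).
#' @param gc12 numeric vector, same length.
#' @return list of class `neutrality_fit`: `slope`, `intercept`, `r2`,
#'   `p_value`, `n`, and the underlying `lm` fit.
#' @export
neutrality_fit <- function(gc3, gc12) {
  stopifnot(length(gc3) == length(gc12))
  if (length(gc3) < 3) stop("need at least 3 points", call. = FALSE)
  if (isTRUE(all.equal(var(gc3), 0)))
    stop("zero variance in GC3; slope undefined", call. = FALSE)
  fit <- lm(gc12 ~ gc3)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(gc3), fit = fit),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("Neutrality regression (n = %d): GC12 = %.4f + %.4f * GC3; R^2 = %.4f, p = %.4g\n",
              x$n, x$intercept, x$slope, x$r2, x$p_value))
  invisible(x)
}

#' Full codon-usage table for one gene
#'
#' Convenience wrapper bundling [count_codons()], [rscu()],
#' [aa_frequencies()], [third_position_composition()], [enc()] and
#' [pr2_point()] for a single coding sequence.
#'
#' @param cds DNA string (frame 0) or a `codon_counts` object.
#' @param gene gene label.
#' @param code a [genetic_code()].
#' @return object of class `codon_usage_table`: list with `gene`, `counts`,
#'   `stop_counts`, `n_codons`, `n_codons_used` (codons with count > 0),
#'   `rscu`, `aa_freq`, `gc3`, `gc3s`, `gc12`, `enc`, `pr2`.
#' @export
codon_usage_table <- function(cds, gene = "gene", code = genetic_code(5)) {
  cc <- if (inherits(cds, "codon_counts")) cds else count_codons(cds, code)
  p3 <- third_position_composition(cc, code)
  structure(list(gene = gene, counts = cc$counts, stop_counts = cc$stop_counts,
                 n_codons = cc$n_codons,
                 n_codons_used = sum(cc$counts > 0),
                 rscu = rscu(cc, code),
                 aa_freq = aa_frequencies(cc, code),
                 gc3 = p3$gc3, gc3s = p3$gc3s, gc12 = p3$gc12,
                 enc = enc(cc, code),
                 pr2 = pr2_point(cc, code)),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("Codon usage for %s: %d codons (%d distinct used)\n",
              x$gene, x$n_codons, x$n_codons_used))
  cat(sprintf("  ENc %.2f | GC3 %.2f%% | GC3s %.2f%% | GC12 %.2f%% | PR2 (%.3f, %.3f)\n",
              x$enc, x$gc3, x$gc3s, x$gc12, x$pr2[["x"]], x$pr2[["y"]]))
  top <- sort(x$rscu[x$counts > 0], decreasing = TRUE)
  top <- top[seq_len(min(3, length(top)))]
  cat("  top RSCU:", paste(sprintf("%s %.2f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
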