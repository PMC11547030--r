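## Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, and sliding-window
## nucleotide diversity (pi).
##
## Conventions (matching pairwise-deletion behaviour of the standard desktop
## tools): codons containing a gap or N in either sequence are wholly excluded
## from site and difference counts; synonymous + nonsynonymous site fractions
## sum to 3 per codon (changes creating a stop codon count as nonsynonymous);
## multi-hit codons are averaged over all minimal mutational pathways with
## equal weight, a step being synonymous iff it preserves the amino acid (stop
## treated as its own residue).

## per-codon synonymous site count: for each position, the fraction of the 3
## single-nucleotide changes that are synonymous
syn_sites_codon <- function(codon, code) {
  aa <- code$codon_to_aa[[codon]]
  s <- 0
  v <- seq_to_vec(codon)
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, v[pos])) {
      w <- v; w[pos] <- b
      if (code$codon_to_aa[[vec_to_seq(w)]] == aa) s <- s + 1 / 3
    }
  }
  s
}

## average synonymous/nonsynonymous differences between two codons over all
## minimal mutational pathways (equal weights)
codon_path_diffs <- function(c1, c2, code) {
  v1 <- seq_to_vec(c1); v2 <- seq_to_vec(c2)
  pos <- which(v1 != v2)
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- list(list(1L), list(c(1L, 2L), c(2L, 1L)),
                list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))[[nd]]
  tot_s <- 0
  for (ord in perms) {
    cur <- v1
    for (k in ord) {
      nxt <- cur; nxt[pos[k]] <- v2[pos[k]]
      if (code$codon_to_aa[[vec_to_seq(cur)]] == code$codon_to_aa[[vec_to_seq(nxt)]])
        tot_s <- tot_s + 1
      cur <- nxt
    }
  }
  s <- tot_s / length(perms)
  c(sd = s, nd = nd - s)
}

## memoised tables, built once per genetic code
.ng_cache <- new.env(parent = emptyenv())

ng_tables <- function(code) {
  key <- as.character(code$table_id)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  codons <- names(code$codon_to_aa)
  syn_sites <- vapply(codons, syn_sites_codon, numeric(1), code = code)
  .ng_cache[[key]] <- list(codons = codons, syn_sites = syn_sites,
                           pair = new.env(parent = emptyenv()))
  .ng_cache[[key]]
}

pair_diffs_cached <- function(c1, c2, code, tabs) {
  key <- paste0(c1, c2)
  hit <- tabs$pair[[key]]
  if (!is.null(hit)) return(hit)
  val <- codon_path_diffs(c1, c2, code)
  tabs$pair[[key]] <- val
  tabs$pair[[paste0(c2, c1)]] <- val
  val
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NaN)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Ka/Ks by the Nei-Gojobori method
#'
#' Counts synonymous and nonsynonymous sites and differences per the
#' Nei-Gojobori (1986) method (site counts averaged between the two
#' sequences, multi-hit codons averaged over all minimal pathways), applies
#' the Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)` to both proportions
#' and reports `omega = Ka/Ks`.
#'
#' @param seq_a,seq_b equal-length in-frame coding sequences (gaps `-` and N
#'   allowed; codons containing either in either sequence are excluded).
#' @param code a [genetic_code()].
#' @return one-row data.frame of class `pairwise_rates`: `ka`, `ks`, `omega`
#'   (NA when Ks == 0), `syn_sites` (S), `nonsyn_sites` (N), `syn_diffs`,
#'   `nonsyn_diffs`, `n_codons_compared`. Ka or Ks is NaN (flagged by warning)
#'   when a proportion reaches the Jukes-Cantor limit p >= 3/4.
#' @export
nei_gojobori <- function(seq_a, seq_b, code = genetic_code(5)) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must be aligned (equal length)", call. = FALSE)
  if (nchar(seq_a) %% 3L != 0L)
    stop("alignment length must be a multiple of 3", call. = FALSE)
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (length(ca) == 0) stop("no comparable codons", call. = FALSE)
  tabs <- ng_tables(code)
  S <- (sum(tabs$syn_sites[ca]) + sum(tabs$syn_sites[cb])) / 2
  N <- 3 * length(ca) - S
  sd_tot <- 0; nd_tot <- 0
  diff <- which(ca != cb)
  for (i in diff) {
    d <- pair_diffs_cached(ca[i], cb[i], code, tabs)
    sd_tot <- sd_tot + d[["sd"]]
    nd_tot <- nd_tot + d[["nd"]]
  }
  ps <- if (S > 0) sd_tot / S else NA_real_
  pn <- if (N > 0) nd_tot / N else NA_real_
  ks <- jukes_cantor(ps); ka <- jukes_cantor(pn)
  if (any(is.nan(c(ka, ks))))
    warning("proportion of differences >= 3/4; Jukes-Cantor correction undefined",
            call. = FALSE)
  omega <- if (!is.na(ks) && !is.nan(ks) && ks > 0) ka / ks else NA_real_
  out <- data.frame(ka = ka, ks = ks, omega = omega,
                    syn_sites = S, nonsyn_sites = N,
                    syn_diffs = sd_tot, nonsyn_diffs = nd_tot,
                    n_codons_compared = length(ca))
  class(out) <- c("pairwise_rates", class(out))
  out
}

#' Per-gene Ka/Ks across a set of taxa
#'
#' Runs [nei_gojobori()] on every unordered pair of rows of each codon
#' alignment and summarizes each gene with the mean omega over defined pairs
#' and a paired t statistic comparing Ka against Ks across pairs.
#'
#' @param alignments named list (one element per gene) of named character
#'   vectors of equal-length in-frame sequences.
#' @param code a [genetic_code()].
#' @return list of class `rate_matrix`: `pairs` (data.frame with gene,
#'   taxon_a, taxon_b and the [nei_gojobori()] columns), `summary` (data.frame
#'   with gene, n_pairs, mean_omega, mean_ka, mean_ks, t_ka_ks, p_ka_ks).
#'   Genes with fewer than 2 taxa are skipped with a warning.
#' @export
gene_rate_matrix <- function(alignments, code = genetic_code(5)) {
  if (is.null(names(alignments)))
    names(alignments) <- paste0("gene", seq_along(alignments))
  pair_rows <- list(); summ_rows <- list()
  for (gene in names(alignments)) {
    aln <- alignments[[gene]]
    if (length(aln) < 2) {
      warning("gene '", gene, "' has fewer than 2 taxa; skipped", call. = FALSE)
      next
    }
    taxa <- names(aln)
    if (is.null(taxa)) taxa <- paste0("taxon", seq_along(aln))
    idx <- utils::combn(length(aln), 2)
    rows <- lapply(seq_len(ncol(idx)), function(j) {
      i1 <- idx[1, j]; i2 <- idx[2, j]
      r <- nei_gojobori(aln[[i1]], aln[[i2]], code)
      cbind(data.frame(gene = gene, taxon_a = taxa[i1], taxon_b = taxa[i2],
                       stringsAsFactors = FALSE), r)
    })
    rows <- do.call(rbind, rows)
    pair_rows[[gene]] <- rows
    ok <- !is.na(rows$ka) & !is.na(rows$ks) & !is.nan(rows$ka) & !is.nan(rows$ks)
    tt <- if (sum(ok) >= 2 && var(rows$ka[ok] - rows$ks[ok]) > 0)
      t.test(rows$ka[ok], rows$ks[ok], paired = TRUE) else NULL
    om <- rows$omega[!is.na(rows$omega)]
    summ_rows[[gene]] <- data.frame(
      gene = gene, n_pairs = nrow(rows),
      mean_omega = if (length(om)) mean(om) else NA_real_,
      mean_ka = mean(rows$ka[ok]), mean_ks = mean(rows$ks[ok]),
      t_ka_ks = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p_ka_ks = if (is.null(tt)) NA_real_ else tt$p.value,
      stringsAsFactors = FALSE)
  }
  if (length(pair_rows) == 0)
    stop("no gene with 2 or more taxa", call. = FALSE)
  structure(list(pairs = do.call(rbind, c(pair_rows, list(make.row.names = FALSE))),
                 summary = do.call(rbind, c(summ_rows, list(make.row.names = FALSE)))),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("Ka/Ks rate matrix:", nrow(x$summary), "gene(s),",
      nrow(x$pairs), "pairwise comparisons\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sliding-window nucleotide diversity (pi)
#'
#' Pi in a window is the mean over all sequence pairs of (differences /
#' compared sites) within the window; sites with a gap or N in either row of a
#' pair are excluded pairwise. Windows advance by `step` from position 1; a
#' trailing shorter window is emitted when fewer than `window` columns remain.
#'
#' @param alignment named character vector of equal-length aligned sequences
#'   (>= 2 rows).
#' @param window window width in bp (default 200).
#' @param step step size in bp (default 20).
#' @return object of class `diversity_series`: data.frame with `window_start`,
#'   `window_end`, `window_mid`, `pi` (NA when a window has no comparable
#'   site), plus attribute `overall_pi` (pi over the full alignment).
#' @export
sliding_pi <- function(alignment, window = 200, step = 20) {
  if (length(alignment) < 2) stop("need at least 2 sequences", call. = FALSE)
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop("sequences differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  valid <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  n <- nrow(mat)
  idx <- utils::combn(n, 2)
  ## per-column, per-pair: comparable? different?
  n_pairs <- ncol(idx)
  comp <- matrix(FALSE, n_pairs, L); dif <- matrix(FALSE, n_pairs, L)
  for (j in seq_len(n_pairs)) {
    a <- idx[1, j]; b <- idx[2, j]
    comp[j, ] <- valid[a, ] & valid[b, ]
    dif[j, ] <- comp[j, ] & (mat[a, ] != mat[b, ])
  }
  pi_of <- function(cols) {
    cs <- rowSums(comp[, cols, drop = FALSE])
    ds <- rowSums(dif[, cols, drop = FALSE])
    ok <- cs > 0
    if (!any(ok)) return(NA_real_)
    mean(ds[ok] / cs[ok])
  }
  starts <- seq(1L, max(1L, L - window + 1L), by = step)
  ## a final partial window when the last full window does not reach the end
  if (max(starts) + window - 1L < L) starts <- c(starts, max(starts) + step)
  starts <- starts[starts <= L]
  out <- data.frame(window_start = starts,
                    window_end = pmin(starts + window - 1L, L))
  out$window_mid <- (out$window_start + out$window_end) / 2
  out$pi <- vapply(seq_len(nrow(out)), function(i)
    pi_of(out$window_start[i]:out$window_end[i]), numeric(1))
  attr(out, "overall_pi") <- pi_of(seq_len(L))
  class(out) <- c("diversity_series", class(out))
  out
}
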