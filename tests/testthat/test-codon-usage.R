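code5 <- genetic_code(5)

test_that("invertebrate mito code has the split family structure", {
  expect_equal(length(code5$sense_codons), 62)
  expect_equal(code5$stop_codons, c("TAA", "TAG"))
  expect_equal(code5$codon_to_aa[["TGA"]], "W")
  expect_equal(code5$codon_to_aa[["ATA"]], "M")
  expect_equal(code5$codon_to_aa[["AGA"]], "S")
  sizes <- table(lengths(code5$families))
  expect_equal(unname(sizes[["2"]]), 13)
  expect_equal(unname(sizes[["4"]]), 9)
  ## split-family naming convention
  expect_setequal(code5$families$Leu1, c("CTT", "CTC", "CTA", "CTG"))
  expect_setequal(code5$families$Leu2, c("TTA", "TTG"))
  expect_setequal(code5$families$Ser1, c("AGT", "AGC", "AGA", "AGG"))
  expect_setequal(code5$families$Ser2, c("TCT", "TCC", "TCA", "TCG"))
  ## families partition the sense codons
  expect_setequal(unlist(code5$families, use.names = FALSE), code5$sense_codons)
})

test_that("codon counting handles stops, incomplete stops and frame errors", {
  cc <- count_codons("ATGTTATAA", code5)
  expect_equal(cc$counts[["ATG"]], 1)
  expect_equal(cc$counts[["TTA"]], 1)
  expect_equal(cc$stop_counts[["TAA"]], 1)
  expect_equal(cc$n_codons, 2)
  ## trailing nucleotide dropped
  cc2 <- count_codons("ATGT", code5)
  expect_equal(cc2$counts[["ATG"]], 1)
  expect_equal(cc2$dropped_nt, 1)
  expect_equal(sum(cc2$counts), 1)
  ## internal stop warns with its position
  expect_warning(count_codons("ATGTAAATG", code5), "position.*2")
  ## codon total arithmetic over the 13 simulated PCGs
  g <- make_genome(waterlily_aphid_replay_spec(seed = 2))
  pcgs <- g$features[g$features$kind == "PCG", ]
  lens <- feature_lengths(g)[pcgs$name]
  total <- sum(vapply(pcgs$name, function(nm) {
    cc <- suppressWarnings(count_codons(extract_cds(g, nm), code5))
    cc$n_codons + sum(cc$stop_counts)
  }, numeric(1)))
  expect_equal(total, sum((lens - lens %% 3) / 3))
})

test_that("RSCU follows the defining formula and its invariants", {
  ## one codon of a 2-fold family used exclusively
  r <- rscu(setNames(c(5L, 0L), c("TTA", "TTG")), code5)
  expect_equal(r[["TTA"]], 2)
  expect_equal(r[["TTG"]], 0)
  ## uniform usage in a 4-fold family
  r2 <- rscu(setNames(rep(3L, 4), code5$families$Val), code5)
  expect_equal(unname(r2[code5$families$Val]), rep(1, 4))
  ## unused family is undefined, not zero
  expect_true(all(is.na(r2[code5$families$Pro])))
  ## multinomial sampling: 9:1 profile recovers RSCU ~ 1.8
  prof <- setNames(rep(0, 62), code5$sense_codons)
  prof[c("TTA", "TTG")] <- c(0.9, 0.1)
  cds <- make_codon_set(prof, 1000, seed = 42)
  r3 <- rscu(count_codons(cds, code5), code5)
  expect_lt(abs(r3[["TTA"]] - 1.8), 0.1)
  ## family-sum invariant on random tables
  set.seed(8)
  for (i in 1:25) {
    counts <- random_codon_counts(code5)
    r <- rscu(counts, code5)
    for (fam in code5$families) {
      if (sum(counts[fam]) > 0)
        expect_equal(sum(r[fam]), length(fam), tolerance = 1e-12)
    }
  }
})

test_that("third-position composition and GC fractions", {
  ## all codons ending in A
  counts <- setNames(rep(0L, 62), code5$sense_codons)
  counts[c("TTA", "GGA", "CCA")] <- 10L
  p3 <- third_position_composition(counts, code5)
  expect_equal(p3$gc3, 0)
  expect_equal(unname(suppressWarnings(pr2_point(counts, code5))[["y"]]), 1)
  ## GGG homogeneous
  gg <- setNames(rep(0L, 62), code5$sense_codons); gg[["GGG"]] <- 10L
  p3g <- third_position_composition(gg, code5)
  expect_equal(p3g$gc3, 100)
  expect_equal(p3g$gc12, 100)
  ## under the split convention every family has size >= 2, so gc3s == gc3
  set.seed(9)
  counts_r <- random_codon_counts(code5)
  p3r <- third_position_composition(counts_r, code5)
  expect_equal(p3r$gc3s, p3r$gc3)
  ## planted GC3 recovered within a point at n = 2000
  prof <- codon_profile_at(0.90, code5)
  planted_gc3 <- 100 * sum(prof[substr(names(prof), 3, 3) %in% c("G", "C")])
  cds <- make_codon_set(prof, 2000, seed = 11)
  est <- third_position_composition(count_codons(cds, code5), code5)$gc3
  expect_lt(abs(est - planted_gc3), 1)
})

test_that("ENc spans its theoretical extremes and tracks concentration", {
  ## extreme bias: one codon per family -> ENc equals the number of families
  one <- setNames(rep(0L, 62), code5$sense_codons)
  for (fam in code5$families) one[fam[1]] <- 20L
  expect_equal(enc(one, code5), length(code5$families))
  ## uniform usage at large n approaches the sense-codon count (62 split code)
  unif <- setNames(rep(500L, 62), code5$sense_codons)
  expect_lt(abs(enc(unif, code5) - sum(lengths(code5$families))), 0.5)
  ## concentrating one family monotonically lowers ENc
  base <- setNames(rep(50L, 62), code5$sense_codons)
  fam <- code5$families$Val
  prev <- enc(base, code5)
  for (shift in c(20L, 40L, 49L)) {
    x <- base
    x[fam] <- c(50L + 3L * shift, rep(50L - shift, 3))
    now <- enc(x, code5)
    expect_lt(now, prev)
    prev <- now
  }
  ## a whole missing degeneracy class is imputed with a warning
  two_only <- setNames(rep(0L, 62), code5$sense_codons)
  for (fam in code5$families[lengths(code5$families) == 2]) two_only[fam] <- 10L
  expect_warning(e <- enc(two_only, code5), "imputing")
  expect_true(is.finite(e))
})

test_that("ENc recovers a profile tuned to a target of 30", {
  ## within-family geometric concentration w; theoretical ENc from exact
  ## family homozygosities, solved for ENc == 30, then estimated from a draw
  theo_enc <- function(w) {
    fs <- lengths(code5$families)
    f_of <- function(k) { p <- w^(0:(k - 1)); p <- p / sum(p); sum(p^2) }
    f2 <- f_of(2); f4 <- f_of(4)
    sum(fs == 2) / f2 + sum(fs == 4) / f4
  }
  w <- uniroot(function(w) theo_enc(w) - 30, c(0.01, 0.99))$root
  prof <- unlist(lapply(code5$families, function(fam) {
    p <- w^(0:(length(fam) - 1)); setNames(p / sum(p), fam)
  }))
  names(prof) <- sub("^[A-Za-z0-9]+\\.", "", names(prof))
  prof <- prof / sum(prof)
  cds <- make_codon_set(prof, 3000, seed = 13)
  expect_lt(abs(enc(count_codons(cds, code5), code5) - 30), 1)
})

test_that("expected-ENc curve matches the closed form and is symmetric", {
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1), 32)
  ## symmetry of the rational term: curves at 0.5 +/- s differ only by the
  ## linear GC3s term
  s <- seq(0.05, 0.45, by = 0.05)
  expect_equal(enc_expected(0.5 + s) - enc_expected(0.5 - s), 2 * s,
               tolerance = 1e-12)
  expect_error(enc_expected(1.2))
})

test_that("PR2 coordinates behave at the center and the degenerate edges", {
  bal <- setNames(rep(0L, 62), code5$sense_codons)
  bal[c("TTA", "ATT", "GGG", "CCC")] <- 5L   # A3 == T3, G3 == C3
  expect_equal(unname(pr2_point(bal, code5)), c(0.5, 0.5))
  ## G3 == 0 with C3 > 0 -> x == 0
  noG <- setNames(rep(0L, 62), code5$sense_codons)
  noG[c("TTA", "CCC")] <- 4L
  expect_equal(unname(pr2_point(noG, code5)[["x"]]), 0)
  ## all third positions T -> y == 0
  allT <- setNames(rep(0L, 62), code5$sense_codons)
  allT[c("TTT", "CAT")] <- 4L
  expect_equal(unname(suppressWarnings(pr2_point(allT, code5))[["y"]]), 0)
  ## fully absent G and C at third positions -> x undefined, flagged
  noGC <- setNames(rep(0L, 62), code5$sense_codons)
  noGC[c("TTA", "TTT")] <- 4L
  expect_warning(p <- pr2_point(noGC, code5), "abscissa")
  expect_true(is.na(p[["x"]]))
})

test_that("neutrality regression recovers known relationships", {
  gc3 <- c(3, 5, 8, 11, 14)
  ## exact fits make summary.lm grumble; that is the point of the case
  fit <- suppressWarnings(neutrality_fit(gc3, gc3))  # mutation-bias diagonal
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  fit0 <- suppressWarnings(neutrality_fit(gc3, rep(20, 5)))  # flat
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_equal(fit0$r2, 0, tolerance = 1e-12)
  expect_error(neutrality_fit(rep(4, 5), gc3), "variance")
  expect_error(neutrality_fit(1:2, 1:2), "3 points")
  ## planted slope recovered within 2 SE at n = 12
  set.seed(14)
  x <- runif(12, 3, 15)
  y <- 30 - 0.9 * x + rnorm(12, sd = 1.5)
  f <- neutrality_fit(x, y)
  se <- summary(f$fit)$coefficients[2, 2]
  expect_lt(abs(f$slope - (-0.9)), 2 * se)
})

test_that("codon usage table bundles consistent per-gene statistics", {
  set.seed(15)
  cds <- make_codon_set(codon_profile_at(0.84, code5), 400, seed = 16)
  tab <- codon_usage_table(cds, gene = "g", code = code5)
  expect_equal(tab$n_codons, 400)
  expect_equal(sum(tab$aa_freq), 100, tolerance = 1e-9)
  expect_equal(tab$n_codons_used, sum(tab$counts > 0))
  expect_true(tab$enc >= 20 - 1e-9)
  expect_true(all(tab$pr2 >= 0 & tab$pr2 <= 1))
})
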