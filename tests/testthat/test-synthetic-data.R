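code5 <- genetic_code(5)

test_that("genome specs validate tiling and feasibility", {
  plan <- tiling_plan()
  expect_s3_class(genome_spec(plan, 1000), "genome_spec")
  expect_error(genome_spec(plan, 999), "tile")
  bad <- plan; bad$gap_after[1] <- -400   # deeper than the 300 bp feature
  expect_error(genome_spec(bad, sum(bad$length) + sum(bad$gap_after)),
               "overlap")
})

test_that("generators are pure functions of their spec", {
  spec <- genome_spec(tiling_plan(), 1000, seed = 9)
  expect_identical(make_genome(spec)$sequence, make_genome(spec)$sequence)
  expect_identical(make_genome(spec)$features, make_genome(spec)$features)
  prof <- codon_profile_at(0.8, code5)
  expect_identical(make_codon_set(prof, 200, seed = 4),
                   make_codon_set(prof, 200, seed = 4))
  dsp <- divergence_spec(3, 100, 0.5, 1, 0.1, seed = 5)
  expect_identical(evolve_pair(dsp)$sequences, evolve_pair(dsp)$sequences)
  ## different seeds give different draws
  expect_false(identical(make_codon_set(prof, 200, seed = 4),
                         make_codon_set(prof, 200, seed = 5)))
})

test_that("synthetic genomes carry valid gene structure and composition", {
  g <- make_genome(genome_spec(tiling_plan(), 1000, at_target = 0.84, seed = 10))
  expect_equal(nchar(g$sequence), 1000)
  ## PCGs read in their own orientation start with ATN and end with a stop
  for (nm in c("g1", "g2")) {
    cds <- extract_cds(g, nm)
    expect_match(substr(cds, 1, 3), "^AT[AGT]$")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG"))
  }
  ## whole-circle single feature: zero spacers, zero overlaps
  whole <- genome_spec(data.frame(name = "all", kind = "noncoding",
                                  strand = "+", length = 500L,
                                  gap_after = 0L), 500, seed = 2)
  r <- intergenic_profile(make_genome(whole))
  expect_equal(r$n_spacers + r$n_overlaps, 0)
  ## composition close to target on a >= 1 kb genome
  g2 <- make_genome(waterlily_aphid_replay_spec(seed = 12))
  expect_lt(abs(base_composition(g2$sequence)$at_percent - 84.34), 1)
  ## start codons valid for all 13 simulated PCGs
  pcgs <- g2$features[g2$features$kind == "PCG", "name"]
  starts <- vapply(pcgs, function(nm) substr(extract_cds(g2, nm), 1, 3),
                   character(1))
  expect_true(all(grepl("^AT[AGT]$", starts)))
})

test_that("planted repeats are recovered by the detectors", {
  plan <- data.frame(name = c("nc1", "nc2"), kind = "noncoding",
                     strand = "+", length = c(600L, 400L),
                     gap_after = c(0L, 0L))
  set.seed(40)
  seg <- random_dna(40, at = 0.5)
  planted <- data.frame(class = c("ssr", "palindromic"),
                        motif = c("AT", seg),
                        at = c(50L, 120L), n = c(8L, NA),
                        pos_b = c(NA, 700L))
  g <- make_genome(genome_spec(plan, 1000, planted_repeats = planted, seed = 41))
  ssr <- find_ssrs(g$sequence)
  ## the maximal run may start a base early in phase with the AT-rich flank,
  ## so assert coverage of the planted copies rather than exact bounds
  expect_true(any(ssr$motif_min_rotation == "AT" & ssr$n_repeats >= 8 &
                    ssr$start <= 50 & ssr$end >= 64))
  d <- find_dispersed(g$sequence, min_len = 35)
  pal <- d[d$class == "palindromic", ]
  expect_gt(nrow(pal), 0)
  expect_true(any(pal$pos_a <= 120 & pal$end_a >= 155))
  ## planted tandem units drive decompose_tandem (unit order recovery)
  set.seed(42)
  u1 <- random_dna(142, at = 0.84); u2 <- random_dna(93, at = 0.84)
  planted_t <- data.frame(class = "tandem",
                          motif = paste(u1, u2, u1, u2, u1, sep = ","),
                          at = 101L, n = NA, pos_b = NA)
  g2 <- make_genome(genome_spec(plan, 1000, planted_repeats = planted_t,
                                seed = 43))
  region <- substr(g2$sequence, 101, 101 + 612 - 1)
  expect_equal(decompose_tandem(region)$order_string, "I-II-I-II-I")
})

test_that("codon-set generator respects the profile contract", {
  prof <- codon_profile_at(0.84, code5)
  cds <- make_codon_set(prof, 500, seed = 6)
  expect_equal(nchar(cds), 3 * 501)
  expect_equal(substr(cds, nchar(cds) - 2, nchar(cds)), "TAA")
  bad <- c(prof, TAA = 0.01); bad <- bad / sum(bad)
  expect_error(make_codon_set(bad, 10, seed = 1), "stop codons")
  expect_error(make_codon_set(prof[1:10], 10, seed = 1), "sum to 1")
  ## point-mass profile: a homogeneous codon run; ENc collapses to the
  ## family count (maximal bias), with the missing fourfold class imputed
  pm <- setNames(rep(0, 62), names(codon_profile_at(0.8, code5)))
  pm[["TTA"]] <- 1
  run <- make_codon_set(pm, 50, seed = 9)
  expect_equal(substr(run, 1, 150), strrep("TTA", 50))
  expect_warning(e_pm <- enc(count_codons(run, code5), code5), "imputing")
  expect_equal(e_pm, length(code5$families))
  ## uniform profile: RSCU concentrates near 1 at n = 10,000
  unif <- setNames(rep(1 / 62, 62), code5$sense_codons)
  r <- rscu(count_codons(make_codon_set(unif, 10000, seed = 7), code5), code5)
  expect_true(all(abs(r - 1) < 0.35))
  ## AT-rich profile yields >= 28 codons with RSCU > 1, all ending A or T
  at_prof <- codon_profile_at(0.85, code5)
  r2 <- rscu(count_codons(make_codon_set(at_prof, 4000, seed = 8), code5), code5)
  high <- names(r2)[!is.na(r2) & r2 > 1]
  expect_gte(length(high), 28)
  expect_true(mean(substr(high, 3, 3) %in% c("A", "T")) > 0.9)
})

test_that("codon divergence simulator honours its ground truth", {
  ## zero branch length: identical sequences, zero events
  a0 <- evolve_pair(divergence_spec(2, 100, 0.5, 1, 0, seed = 3))
  expect_equal(a0$sequences[[1]], a0$sequences[[2]])
  expect_equal(sum(a0$events$n_syn) + sum(a0$events$n_nonsyn), 0)
  ## omega 0: no nonsynonymous events, Ka exactly 0
  aw <- evolve_pair(divergence_spec(2, 200, 0, 1, 0.2, seed = 4))
  expect_equal(sum(aw$events$n_nonsyn), 0)
  expect_gt(sum(aw$events$n_syn), 0)
  r <- nei_gojobori(aw$sequences[[1]], aw$sequences[[2]], code5)
  expect_equal(r$ka, 0)
  ## events are consistent with the observed sequence diff: each event moves
  ## one nucleotide, so per-tip diffs from the ancestor cannot exceed events
  a1 <- evolve_pair(divergence_spec(2, 150, 0.5, 1, 0.1, seed = 5))
  for (k in 1:2) {
    nd <- sum(strsplit(a1$sequences[[k]], "")[[1]] !=
                strsplit(a1$ancestor, "")[[1]])
    ev <- sum(a1$events[k, c("n_syn", "n_nonsyn")])
    expect_lte(nd, ev)
    expect_gt(ev, 0)
  }
  ## no stop codons ever appear in frame
  codons <- substring(a1$sequences[[1]], seq(1, 448, 3), seq(3, 450, 3))
  expect_false(any(codons %in% code5$stop_codons))
})

test_that("omega recovery from simulated alignments", {
  sp <- divergence_spec(n_taxa = 10, n_codons = 500, omega = 0.1, kappa = 1,
                        branch_length = 0.15, seed = 101)
  aln <- evolve_pair(sp)
  rm_ <- gene_rate_matrix(list(sim = aln$sequences), code5)
  expect_gt(rm_$summary$mean_omega, 0.05)
  expect_lt(rm_$summary$mean_omega, 0.2)
  ## Ka significantly below Ks under purifying selection
  expect_lt(rm_$summary$t_ka_ks, 0)
  expect_lt(rm_$summary$p_ka_ks, 0.001)
})
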