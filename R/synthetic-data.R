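## Seedable generators for every input class the pipeline consumes, with known
## ground truth: annotated circular genomes built from an explicit feature
## plan, codon sets drawn from a codon-frequency profile, and codon alignments
## diverged under a continuous-time codon model with specified omega.
## All generators are pure functions of (spec, seed): the same seed gives
## byte-identical output (R's default Mersenne-Twister, set locally via
## withr-style on.exit restore).

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## base sampling probabilities for a target AT fraction (A/T and G/C equal)
base_probs <- function(at_target) {
  stopifnot(at_target > 0, at_target < 1)
  c(A = at_target / 2, C = (1 - at_target) / 2,
    G = (1 - at_target) / 2, T = at_target / 2)
}

#' Sense-codon profile with a target AT fraction
#'
#' Builds a codon-frequency profile over the sense codons of `code` whose
#' expected AT fraction equals `at_target` exactly. Independent-base weights
#' are tilted (by root finding) before the stop codons are removed: dropping
#' TAA/TAG, which are AT-rich, from an untilted profile would leave coding
#' regions about a point below the target.
#'
#' @param at_target AT fraction in (0, 1).
#' @param code a [genetic_code()].
#' @return named numeric over sense codons, summing to 1.
#' @export
codon_profile_at <- function(at_target, code = genetic_code(5)) {
  raw <- function(a) {
    p <- base_probs(a)
    w <- vapply(code$sense_codons, function(cd) {
      v <- seq_to_vec(cd); p[[v[1]]] * p[[v[2]]] * p[[v[3]]]
    }, numeric(1))
    w / sum(w)
  }
  at_of <- function(w) {
    at_frac <- vapply(names(w), function(cd)
      mean(seq_to_vec(cd) %in% c("A", "T")), numeric(1))
    sum(w * at_frac)
  }
  a_star <- stats::uniroot(function(a) at_of(raw(a)) - at_target,
                           c(1e-3, 1 - 1e-3), tol = 1e-10)$root
  raw(a_star)
}

#' Specification for a synthetic annotated genome
#'
#' @param feature_plan data.frame with columns `name`, `kind`, `strand`,
#'   `length`, `gap_after` (signed gap to the next feature; negative =
#'   overlap; the last row's gap closes the circle). The plan must tile the
#'   circle: `sum(length) + sum(gap_after) == genome_length`.
#' @param genome_length genome size in bp.
#' @param at_target target AT fraction in (0, 1) (default 0.8434).
#' @param planted_repeats optional data.frame with columns `class` ("ssr",
#'   "forward", "reverse", "palindromic", "complementary", "tandem"), `motif`
#'   (motif, unit, or for tandem several units separated by ","), `at` (1-based
#'   insertion position) and, for ssr/dispersed classes, `n` (copies of an SSR
#'   motif) or `pos_b` (position of the second copy).
#' @param seed integer seed stored in the spec.
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(feature_plan, genome_length, at_target = 0.8434,
                        planted_repeats = NULL, seed = 1) {
  stopifnot(is.data.frame(feature_plan),
            all(c("name", "kind", "strand", "length", "gap_after") %in%
                  names(feature_plan)))
  if (any(feature_plan$length <= 0))
    stop("feature lengths must be positive", call. = FALSE)
  tile <- sum(feature_plan$length) + sum(feature_plan$gap_after)
  if (tile != genome_length)
    stop(sprintf("feature plan does not tile the circle: lengths + gaps = %d != genome_length = %d",
                 tile, genome_length), call. = FALSE)
  if (any(-feature_plan$gap_after >= feature_plan$length))
    stop("an overlap exceeds the feature length; infeasible plan", call. = FALSE)
  structure(list(feature_plan = feature_plan, genome_length = as.integer(genome_length),
                 at_target = at_target, planted_repeats = planted_repeats,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic annotated circular genome
#'
#' Lays features head-to-tail from position 1 according to the plan's lengths
#' and signed gaps, fills the sequence by iid draws at the target AT fraction,
#' rewrites each PCG's interior as sense codons drawn from the AT-matched
#' codon profile with a valid ATN start and a TAA/TAG (or incomplete T/TA)
#' stop on the annotated strand, and finally plants any requested repeats by
#' overwriting the sequence.
#'
#' @param spec a [genome_spec()].
#' @return an [annotated_genome()] with sequence; reproducible given
#'   `spec$seed`.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  plan <- spec$feature_plan
  n <- spec$genome_length
  with_seed(spec$seed, {
    v <- sample(DNA_BASES, n, replace = TRUE, prob = base_probs(spec$at_target))

    ## feature coordinates from the plan
    starts <- integer(nrow(plan)); ends <- integer(nrow(plan))
    pos <- 1L
    wrap1 <- function(x) ((x - 1L) %% n) + 1L
    for (i in seq_len(nrow(plan))) {
      starts[i] <- wrap1(pos)
      ends[i] <- wrap1(pos + plan$length[i] - 1L)
      pos <- pos + plan$length[i] + plan$gap_after[i]
    }
    features <- data.frame(name = plan$name, kind = plan$kind,
                           strand = plan$strand, start = starts, end = ends,
                           stringsAsFactors = FALSE)

    ## rewrite PCGs as codon draws with valid start/stop on their own strand
    code <- genetic_code(5)
    profile <- codon_profile_at(spec$at_target, code)
    write_feature <- function(i, coding) {
      idx <- wrap1(seq(0L, plan$length[i] - 1L) + starts[i])
      if (plan$strand[i] == "-") coding <- revcomp(coding)
      v[idx] <<- seq_to_vec(coding)
    }
    sc_row <- rep(NA_character_, nrow(plan))
    st_row <- rep(NA_character_, nrow(plan))
    for (i in which(plan$kind == "PCG")) {
      len <- plan$length[i]
      rem <- len %% 3L
      stop_codon <- switch(as.character(rem), `0` = sample(c("TAA", "TAG"), 1),
                           `1` = "T", `2` = "TA")
      start_codon <- sample(c("ATA", "ATG", "ATT"), 1)
      n_inner <- (len - rem) / 3L - 1L - (rem == 0L)
      if (n_inner < 0)
        stop("PCG '", plan$name[i], "' too short for start + stop codons",
             call. = FALSE)
      inner <- if (n_inner > 0)
        paste(sample(names(profile), n_inner, replace = TRUE, prob = profile),
              collapse = "") else ""
      write_feature(i, paste0(start_codon, inner, stop_codon))
      sc_row[i] <- start_codon
      st_row[i] <- stop_codon
    }
    features$start_codon <- sc_row
    features$stop_codon <- st_row

    ## plant repeats by overwriting
    pr <- spec$planted_repeats
    if (!is.null(pr)) {
      overwrite <- function(s, at) {
        idx <- wrap1(seq(0L, nchar(s) - 1L) + as.integer(at))
        v[idx] <<- seq_to_vec(s)
      }
      for (i in seq_len(nrow(pr))) {
        cls <- pr$class[i]; motif <- toupper(pr$motif[i]); at <- pr$at[i]
        if (cls == "ssr") {
          overwrite(paste(rep(motif, pr$n[i]), collapse = ""), at)
        } else if (cls == "tandem") {
          overwrite(gsub(",", "", motif, fixed = TRUE), at)
        } else {
          overwrite(motif, at)
          second <- switch(cls, forward = motif, reverse = reverse_seq(motif),
                           palindromic = revcomp(motif),
                           complementary = complement_seq(motif))
          overwrite(second, pr$pos_b[i])
        }
      }
    }
    annotated_genome(features, genome_length = n, sequence = vec_to_seq(v),
                     topology = "circular")
  })
}

#' Draw a coding sequence from a codon-frequency profile
#'
#' Multinomial draw of `n_codons` sense codons followed by a TAA stop codon.
#'
#' @param profile named numeric over sense codons, summing to 1 (codons not
#'   named get probability 0). Mass on a stop codon is an error.
#' @param n_codons number of sense codons to draw.
#' @param seed integer seed.
#' @param code a [genetic_code()].
#' @return DNA string of length `3 * (n_codons + 1)`.
#' @export
make_codon_set <- function(profile, n_codons, seed = 1, code = genetic_code(5)) {
  if (any(names(profile) %in% code$stop_codons & profile > 0))
    stop("profile puts mass on stop codons", call. = FALSE)
  bad <- setdiff(names(profile), code$sense_codons)
  if (length(bad) > 0)
    stop("unknown codons in profile: ", paste(bad, collapse = ", "), call. = FALSE)
  if (abs(sum(profile) - 1) > 1e-8)
    stop("profile must sum to 1", call. = FALSE)
  with_seed(seed, {
    draws <- sample(names(profile), n_codons, replace = TRUE, prob = profile)
    paste0(paste(draws, collapse = ""), "TAA")
  })
}

#' Specification for omega-divergent codon alignments
#'
#' @param n_taxa number of taxa (tips of a star tree; default 2).
#' @param n_codons codons per sequence.
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param kappa transition/transversion rate ratio (default 2).
#' @param branch_length expected substitutions per codon site from the common
#'   ancestor to each tip.
#' @param seed integer seed.
#' @return list of class `divergence_spec`.
#' @export
divergence_spec <- function(n_taxa = 2, n_codons = 500, omega = 0.1,
                            kappa = 2, branch_length = 0.2, seed = 1) {
  stopifnot(n_taxa >= 2, n_codons > 0, omega >= 0, kappa > 0, branch_length >= 0)
  structure(list(n_taxa = as.integer(n_taxa), n_codons = as.integer(n_codons),
                 omega = omega, kappa = kappa, branch_length = branch_length,
                 seed = as.integer(seed)),
            class = "divergence_spec")
}

is_transition <- function(b1, b2) {
  (b1 %in% c("A", "G") && b2 %in% c("A", "G")) ||
    (b1 %in% c("C", "T") && b2 %in% c("C", "T"))
}

## single-nucleotide neighbour moves of a codon with their relative rates
## under the (kappa, omega) model; moves into stop codons are forbidden
codon_moves <- function(code, kappa, omega) {
  moves <- list()
  for (cd in code$sense_codons) {
    v <- seq_to_vec(cd)
    tos <- character(0); rates <- numeric(0); syn <- logical(0)
    for (pos in 1:3) for (b in setdiff(DNA_BASES, v[pos])) {
      w <- v; w[pos] <- b
      to <- vec_to_seq(w)
      if (to %in% code$stop_codons) next
      r <- if (is_transition(v[pos], b)) kappa else 1
      s <- code$codon_to_aa[[to]] == code$codon_to_aa[[cd]]
      if (!s) r <- r * omega
      tos <- c(tos, to); rates <- c(rates, r); syn <- c(syn, s)
    }
    moves[[cd]] <- list(to = tos, rate = rates, syn = syn,
                        total = sum(rates))
  }
  moves
}

#' Simulate a codon alignment diverged at a known omega
#'
#' Gillespie simulation of a continuous-time codon substitution process on a
#' star tree: a uniform-sense-codon ancestor evolves independently to each of
#' `n_taxa` tips. Single-nucleotide moves have rate kappa (transitions) or 1
#' (transversions), multiplied by omega when nonsynonymous; moves into stop
#' codons are forbidden. Rates are normalised so that `branch_length` is the
#' expected number of substitutions per codon site along one branch at
#' omega = 1 intensity of the ancestral sequence. True synonymous and
#' nonsynonymous event counts are recorded per tip.
#'
#' @param spec a [divergence_spec()].
#' @param code a [genetic_code()].
#' @return list of class `codon_alignment`: `sequences` (named character
#'   vector, no gaps), `ancestor`, `events` (data.frame: taxon, n_syn,
#'   n_nonsyn), `spec`.
#' @export
evolve_pair <- function(spec, code = genetic_code(5)) {
  stopifnot(inherits(spec, "divergence_spec"))
  moves <- codon_moves(code, spec$kappa, spec$omega)
  with_seed(spec$seed, {
    anc <- sample(code$sense_codons, spec$n_codons, replace = TRUE)
    ## time scaling: mean per-codon total rate of the ancestor defines the
    ## clock so that t = branch_length gives ~branch_length events per codon
    mean_rate <- mean(vapply(anc, function(cd) moves[[cd]]$total, numeric(1)))
    seqs <- character(spec$n_taxa)
    ev <- vector("list", spec$n_taxa)
    for (k in seq_len(spec$n_taxa)) {
      res <- evolve_lineage_scaled(anc, moves, spec$branch_length, mean_rate)
      seqs[k] <- paste(res$codons, collapse = "")
      ev[[k]] <- data.frame(taxon = paste0("t", k), n_syn = res$n_syn,
                            n_nonsyn = res$n_nonsyn, stringsAsFactors = FALSE)
    }
    names(seqs) <- paste0("t", seq_len(spec$n_taxa))
    structure(list(sequences = seqs,
                   ancestor = paste(anc, collapse = ""),
                   events = do.call(rbind, ev), spec = spec),
              class = "codon_alignment")
  })
}

## Gillespie over scaled time: rates divided by the ancestral mean rate, so
## expected substitutions per codon over time t equals t at the ancestral
## composition
evolve_lineage_scaled <- function(codons, moves, t, mean_rate) {
  n <- length(codons)
  events_syn <- 0L; events_nonsyn <- 0L
  if (mean_rate <= 0 || t <= 0)
    return(list(codons = codons, n_syn = 0L, n_nonsyn = 0L))
  rates <- vapply(codons, function(cd) moves[[cd]]$total, numeric(1)) / mean_rate
  total <- sum(rates)
  clock <- 0
  repeat {
    if (total <= 0) break
    clock <- clock + rexp(1, rate = total)
    if (clock > t) break   # total scaled rate ~ n, so t is subs per codon
    i <- sample.int(n, 1, prob = rates)
    mv <- moves[[codons[i]]]
    j <- if (length(mv$to) == 1) 1 else sample.int(length(mv$to), 1, prob = mv$rate)
    if (mv$syn[j]) events_syn <- events_syn + 1L else events_nonsyn <- events_nonsyn + 1L
    codons[i] <- mv$to[j]
    total <- total - rates[i]
    rates[i] <- moves[[codons[i]]]$total / mean_rate
    total <- total + rates[i]
  }
  list(codons = codons, n_syn = events_syn, n_nonsyn = events_nonsyn)
}
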