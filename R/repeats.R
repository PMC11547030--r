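## Repeat detection: MISA-threshold perfect microsatellites, maximal exact
## dispersed repeats (four orientation classes, REPuter-style length floor),
## tandem-unit decomposition of non-coding regions, and combinatorial
## stem-loop (inverted-repeat) candidates.

## lexicographically minimal rotation of a motif
min_rotation <- function(motif) {
  n <- nchar(motif)
  if (n == 1) return(motif)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(motif, i, n), substr(motif, 1, i - 1)), character(1))
  sort(rots)[1]
}

## smallest period of a string (motif primitivity check)
smallest_period <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n)) {
    if (n %% p != 0) next
    if (s == paste(rep(substr(s, 1, p), n / p), collapse = "")) return(p)
  }
  n
}

#' Find perfect microsatellites (SSRs)
#'
#' MISA-style scan for perfect simple sequence repeats with motif lengths 1-6.
#' Only maximal, non-extendable runs are reported; a run is reported under its
#' shortest motif (so an (A)10 run is never double-reported as (AA)5), and the
#' reported span covers the complete motif copies from the run start.
#'
#' @param seq DNA string.
#' @param min_repeats integer vector of length 6: minimum number of motif
#'   copies for motif lengths 1-6 (default `c(10, 5, 4, 3, 3, 3)`).
#' @return data.frame of class `ssr_catalog`: `motif` (as it occurs),
#'   `motif_min_rotation`, `motif_length`, `n_repeats`, `start`, `end`.
#' @export
find_ssrs <- function(seq, min_repeats = c(10, 5, 4, 3, 3, 3)) {
  seq <- check_dna(seq)
  stopifnot(length(min_repeats) == 6)
  v <- seq_to_vec(seq)
  n <- length(v)
  rows <- list()
  for (m in 1:6) {
    if (n < m * min_repeats[m]) next
    ## run[i] = TRUE when v[i] == v[i + m]
    eq <- v[seq_len(n - m)] == v[seq_len(n - m) + m]
    ## maximal stretches of TRUE
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      ## periodic run occupies v[starts[k] .. ends[k] + m]
      run_start <- starts[k]
      run_len <- r$lengths[k] + m
      n_copies <- run_len %/% m
      if (n_copies < min_repeats[m]) next
      motif <- vec_to_seq(v[run_start:(run_start + m - 1L)])
      ## report under the shortest motif only
      if (smallest_period(motif) != m) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, motif_min_rotation = min_rotation(motif),
        motif_length = m, n_repeats = n_copies,
        start = run_start, end = run_start + n_copies * m - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), motif_min_rotation = character(0),
               motif_length = integer(0), n_repeats = integer(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$motif_length), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ssr_catalog", class(out))
  out
}

## ---- dispersed repeats -----------------------------------------------------

## seed-and-extend search for maximal equal substrings between s (positions
## map to a) and t (positions map to b); returns maximal pairs (a, b, len)
max_pairs_seed_extend <- function(s, t, min_len) {
  n <- nchar(s); m <- nchar(t)
  if (n < min_len || m < min_len) return(NULL)
  k <- min_len
  sv <- seq_to_vec(s); tv <- seq_to_vec(t)
  skmers <- substring(s, 1:(n - k + 1), k:n)
  tkmers <- substring(t, 1:(m - k + 1), k:m)
  common <- intersect(skmers, tkmers)
  if (length(common) == 0) return(NULL)
  si <- which(skmers %in% common)
  hits <- list()
  tmap <- split(seq_along(tkmers), tkmers)
  seen <- new.env(parent = emptyenv())
  self <- identical(s, t)
  for (i in si) {
    for (j in tmap[[skmers[i]]]) {
      if (self && i == j) next            # trivial self-diagonal
      ## only extend from the leftmost seed of each diagonal run
      if (i > 1 && j > 1 && sv[i - 1] == tv[j - 1]) next
      a <- i; b <- j
      ## extend right
      ea <- i + k - 1; eb <- j + k - 1
      while (ea < n && eb < m && sv[ea + 1] == tv[eb + 1]) { ea <- ea + 1; eb <- eb + 1 }
      key <- paste(a, b, sep = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      hits[[length(hits) + 1L]] <- c(a = a, b = b, len = ea - a + 1)
    }
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

#' Find maximal exact dispersed repeats
#'
#' Detects maximal exact repeats of at least `min_len` bp in four orientation
#' classes: forward (second copy identical), reverse (second copy is the
#' reversed first), palindromic (second copy is the reverse complement;
#' inverted repeat), and complementary (second copy is the base-by-base
#' complement, not reversed). Copies may overlap. Each reported pair is
#' maximal: extending both copies one base outward in either direction breaks
#' the class relation.
#'
#' @param seq DNA string of length >= `min_len`.
#' @param min_len minimum repeat length in bp (default 30).
#' @return data.frame of class `dispersed_catalog`: `class`, `length`,
#'   `pos_a`, `pos_b` (1-based starts of the two copies, `pos_a <= pos_b`),
#'   `end_a`, `end_b`.
#' @export
find_dispersed <- function(seq, min_len = 30) {
  seq <- check_dna(seq, allow_n = FALSE)
  n <- nchar(seq)
  if (n < min_len) stop("sequence shorter than min_len", call. = FALSE)
  out <- list()
  add <- function(cls, a, b, len) {
    out[[length(out) + 1L]] <<- data.frame(
      class = cls, length = len, pos_a = a, pos_b = b,
      end_a = a + len - 1L, end_b = b + len - 1L, stringsAsFactors = FALSE)
  }

  ## forward: s vs s, keep a < b (identical positions are trivial)
  fw <- max_pairs_seed_extend(seq, seq, min_len)
  if (!is.null(fw)) {
    fw <- fw[fw[, "a"] < fw[, "b"], , drop = FALSE]
    fw <- unique(fw)
    for (r in seq_len(nrow(fw)))
      add("forward", fw[r, "a"], fw[r, "b"], fw[r, "len"])
  }

  ## transformed-copy classes: match s against f(s), map coordinates back
  for (cls in c("reverse", "palindromic", "complementary")) {
    t <- switch(cls, reverse = reverse_seq(seq),
                palindromic = revcomp(seq),
                complementary = complement_seq(seq))
    hits <- max_pairs_seed_extend(seq, t, min_len)
    if (is.null(hits)) next
    res <- list()
    for (r in seq_len(nrow(hits))) {
      a <- hits[r, "a"]; j <- hits[r, "b"]; len <- hits[r, "len"]
      ## position j in the transformed string maps back to seq coordinates:
      b <- if (cls == "complementary") j else n - (j + len - 1L) + 1L
      if (a == b) next  # a segment paired with itself is not a repeat
      lo <- min(a, b); hi <- max(a, b)
      res[[length(res) + 1L]] <- c(lo, hi, len)
    }
    if (length(res) == 0) next
    res <- unique(do.call(rbind, res))
    ## symmetric relations (reverse/palindromic/complementary are involutions)
    ## produce each pair twice; unique() above removes the duplicates
    for (r in seq_len(nrow(res))) add(cls, res[r, 1], res[r, 2], res[r, 3])
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(class = character(0), length = integer(0), pos_a = integer(0),
               pos_b = integer(0), end_a = integer(0), end_b = integer(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$class, out$pos_a, out$pos_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dispersed_catalog", class(out))
  out
}

## ---- tandem decomposition --------------------------------------------------

## fraction of matching characters between two strings (prefix-aligned,
## normalised by the longer length)
string_identity <- function(x, y) {
  vx <- seq_to_vec(x); vy <- seq_to_vec(y)
  L <- min(length(vx), length(vy))
  if (L == 0) return(0)
  sum(vx[seq_len(L)] == vy[seq_len(L)]) / max(length(vx), length(vy))
}

#' Decompose a region into tandem repeat units
#'
#' Greedy period detection by exact-match autocorrelation: the fundamental
#' period p is the smallest shift at which at least `min_identity` of the
#' overlapping bases match. The region is segmented into consecutive blocks of
#' p from position 1. When a trailing partial block of length r matches the
#' block prefix (a truncated extra copy, the usual signature of a composite
#' two-unit period), each block is split at r into two sub-units. Units are
#' clustered into types by pairwise identity >= `min_identity`, labelled by
#' Roman numerals in order of first occurrence, and the unit-order string
#' (e.g. "I-II-I-II-I") is emitted.
#'
#' @param region_seq DNA string of the region.
#' @param max_unit maximum unit length in bp (default 200); periods up to
#'   `2 * max_unit` are scanned to catch composite two-unit periods.
#' @param min_units minimum number of full period copies (default 2).
#' @param min_identity clustering/periodicity identity threshold (default 0.8).
#' @return object of class `tandem_decomposition`: list with `units`
#'   (data.frame: unit_type, start, end, length), `unit_consensus` (named
#'   character), `order_string`, `period`. No detectable periodicity yields an
#'   empty decomposition (zero-row `units`, `order_string` "").
#' @export
decompose_tandem <- function(region_seq, max_unit = 200, min_units = 2,
                             min_identity = 0.8) {
  region_seq <- check_dna(region_seq)
  v <- seq_to_vec(region_seq)
  L <- length(v)
  empty <- structure(list(
    units = data.frame(unit_type = character(0), start = integer(0),
                       end = integer(0), length = integer(0),
                       stringsAsFactors = FALSE),
    unit_consensus = character(0), order_string = "", period = NA_integer_),
    class = "tandem_decomposition")
  max_shift <- min(2L * as.integer(max_unit), L %/% min_units)
  if (max_shift < 1) return(empty)
  period <- NA_integer_
  for (s in seq_len(max_shift)) {
    if (mean(v[seq_len(L - s)] == v[seq_len(L - s) + s]) >= min_identity) {
      period <- s
      break
    }
  }
  if (is.na(period)) return(empty)

  k <- L %/% period
  if (k < min_units) return(empty)
  r <- L - k * period
  block_starts <- seq(1L, by = period, length.out = k)
  bounds <- cbind(start = block_starts, end = block_starts + period - 1L)
  ## trailing partial copy: if it matches the block prefix, it is a truncated
  ## unit -- and its length marks the internal boundary of a two-unit period
  split_at <- 0L
  if (r > 0) {
    tail_seq <- vec_to_seq(v[(k * period + 1L):L])
    if (string_identity(tail_seq, vec_to_seq(v[1:r])) >= min_identity &&
        r <= max_unit && period - r <= max_unit && period > max_unit) {
      split_at <- r
    }
  }
  units <- list()
  for (i in seq_len(k)) {
    if (split_at > 0) {
      units[[length(units) + 1L]] <- c(bounds[i, "start"], bounds[i, "start"] + split_at - 1L)
      units[[length(units) + 1L]] <- c(bounds[i, "start"] + split_at, bounds[i, "end"])
    } else {
      units[[length(units) + 1L]] <- c(bounds[i, "start"], bounds[i, "end"])
    }
  }
  if (r > 0) {
    tail_seq <- vec_to_seq(v[(k * period + 1L):L])
    first_unit <- vec_to_seq(v[units[[1]][1]:units[[1]][2]])
    if (string_identity(tail_seq, first_unit) >= min_identity)
      units[[length(units) + 1L]] <- c(k * period + 1L, L)
  }
  udf <- data.frame(start = vapply(units, `[`, integer(1) + 0, 1),
                    end = vapply(units, `[`, integer(1) + 0, 2))
  udf$length <- udf$end - udf$start + 1L
  useqs <- vapply(seq_len(nrow(udf)), function(i)
    vec_to_seq(v[udf$start[i]:udf$end[i]]), character(1))

  ## cluster into types by identity to the first representative of each type
  reps <- character(0)
  type_id <- integer(nrow(udf))
  for (i in seq_len(nrow(udf))) {
    assigned <- FALSE
    for (t in seq_along(reps)) {
      if (string_identity(useqs[i], reps[t]) >= min_identity) {
        type_id[i] <- t; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps <- c(reps, useqs[i])
      type_id[i] <- length(reps)
    }
  }
  roman <- as.character(utils::as.roman(type_id))
  udf <- data.frame(unit_type = roman, udf, stringsAsFactors = FALSE)
  structure(list(units = udf,
                 unit_consensus = setNames(reps, as.character(utils::as.roman(seq_along(reps)))),
                 order_string = paste(roman, collapse = "-"),
                 period = period),
            class = "tandem_decomposition")
}

#' @export
print.tandem_decomposition <- function(x, ...) {
  if (nrow(x$units) == 0) {
    cat("Tandem decomposition: no periodicity detected\n")
  } else {
    cat(sprintf("Tandem decomposition: period %d bp, %d units (%s)\n",
                x$period, nrow(x$units), x$order_string))
  }
  invisible(x)
}

#' Stem-loop (inverted repeat) candidates
#'
#' Purely combinatorial scan for pairs of reverse-complementary segments
#' ("stems") separated by a short loop; no thermodynamic folding. Stems are
#' maximal: they cannot be extended outward or inward without breaking
#' complementarity or the loop constraint.
#'
#' @param region_seq DNA string.
#' @param min_stem minimum stem length in bp (default 5).
#' @param max_loop maximum loop length in bp (default 50).
#' @return data.frame of class `stemloop_catalog`: `stem_start` (5' arm
#'   start), `stem_len`, `loop_len`, `stem2_start`.
#' @export
stem_loop_candidates <- function(region_seq, min_stem = 5, max_loop = 50) {
  region_seq <- check_dna(region_seq, allow_n = FALSE)
  n <- nchar(region_seq)
  rows <- list()
  if (n >= 2 * min_stem) {
    hits <- max_pairs_seed_extend(region_seq, revcomp(region_seq), min_stem)
    if (!is.null(hits)) {
      seen <- character(0)
      for (r in seq_len(nrow(hits))) {
        a <- hits[r, "a"]; j <- hits[r, "b"]; len <- hits[r, "len"]
        b <- n - (j + len - 1L) + 1L           # start of the 3' arm in seq coords
        lo <- min(a, b); hi <- max(a, b)
        loop <- hi - (lo + len - 1L) - 1L
        ## overlapping arms cannot fold into a stem; loops beyond the window
        ## are not candidates either
        if (loop < 0 || loop > max_loop) next
        key <- paste(lo, hi, len)
        if (key %in% seen) next
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- data.frame(
          stem_start = lo, stem_len = as.integer(len), loop_len = as.integer(loop),
          stem2_start = as.integer(hi), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stem_start = integer(0), stem_len = integer(0),
               loop_len = integer(0), stem2_start = integer(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$stem_start, out$stem2_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stemloop_catalog", class(out))
  out
}
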