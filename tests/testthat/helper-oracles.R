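## Independent brute-force oracles. These deliberately share no code with the
## package internals: permutations are enumerated recursively, repeats are
## found by exhaustive diagonal scans, and sites are counted from first
## principles off the code table.

## all permutations of 1..n (tiny n)
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

## Nei-Gojobori oracle: per-codon sites and exhaustive pathway enumeration,
## straight off the genetic-code table
oracle_ng_sites <- function(codon, code) {
  aa <- code$codon_to_aa[[codon]]
  syn <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (b in setdiff(c("A", "C", "G", "T"), orig)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code$codon_to_aa[[mut]] == aa) syn <- syn + 1 / 3
    }
  }
  syn
}

oracle_ng_path <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perms <- permutations_of(length(pos))
  sd_sum <- 0; nd_sum <- 0
  for (p in perms) {
    cur <- c1
    for (step in p) {
      nxt <- cur
      substr(nxt, pos[step], pos[step]) <- substr(c2, pos[step], pos[step])
      if (code$codon_to_aa[[cur]] == code$codon_to_aa[[nxt]])
        sd_sum <- sd_sum + 1
      else nd_sum <- nd_sum + 1
      cur <- nxt
    }
  }
  c(sd = sd_sum / length(perms), nd = nd_sum / length(perms))
}

## full NG oracle over aligned sequences (no gap/N handling: callers feed
## clean sequences)
oracle_ng <- function(a, b, code) {
  n <- nchar(a) / 3
  ca <- substring(a, 3 * (1:n) - 2, 3 * (1:n))
  cb <- substring(b, 3 * (1:n) - 2, 3 * (1:n))
  S <- (sum(vapply(ca, oracle_ng_sites, 1, code = code)) +
          sum(vapply(cb, oracle_ng_sites, 1, code = code))) / 2
  N <- 3 * n - S
  d <- rowSums(vapply(seq_len(n), function(i) oracle_ng_path(ca[i], cb[i], code),
                      c(sd = 0, nd = 0)))
  jc <- function(p) suppressWarnings(-0.75 * log(1 - 4 * p / 3))
  list(S = S, N = N, sd = d[["sd"]], nd = d[["nd"]],
       ks = jc(d[["sd"]] / S), ka = jc(d[["nd"]] / N))
}

## SSR oracle: exhaustive scan over every start and motif length; same
## reporting convention as the spec (maximal runs, primitive motifs, complete
## copies from the run start)
oracle_ssrs <- function(seq, min_repeats = c(10, 5, 4, 3, 3, 3)) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  is_primitive <- function(motif) {
    m <- nchar(motif)
    for (p in seq_len(m - 1)) {
      if (m %% p == 0 &&
          motif == paste(rep(substr(motif, 1, p), m / p), collapse = ""))
        return(FALSE)
    }
    TRUE
  }
  rows <- list()
  for (m in 1:6) {
    i <- 1L
    while (i + m <= n + 1L) {
      ## does a periodic run start at i? (left-maximal)
      if (i > 1 && i + m - 1L <= n && v[i - 1L] == v[i + m - 1L]) { i <- i + 1L; next }
      ## extend: largest e with v[j] == v[j + m] for all j in i..(e - m)
      e <- i + m - 1L
      while (e + 1L <= n && v[e + 1L] == v[e + 1L - m]) e <- e + 1L
      run_len <- e - i + 1L
      k <- run_len %/% m
      motif <- paste(v[i:(i + m - 1L)], collapse = "")
      if (k >= min_repeats[m] && is_primitive(motif)) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motif, motif_length = m, n_repeats = k,
          start = i, end = i + k * m - 1L, stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(motif = character(0), motif_length = integer(0),
               n_repeats = integer(0), start = integer(0), end = integer(0))
  out <- out[order(out$start, out$motif_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## dispersed-repeat oracle: exhaustive diagonal scan of seq against a
## transformed copy; maximal equal runs of length >= min_len
oracle_diagonal_pairs <- function(s, t, min_len = 1) {
  sv <- strsplit(s, "")[[1]]; tv <- strsplit(t, "")[[1]]
  n <- length(sv); m <- length(tv)
  hits <- list()
  for (d in seq(-(m - 1L), n - 1L)) {
    i0 <- max(1L, 1L + d); j0 <- i0 - d
    len_d <- min(n - i0, m - j0) + 1L
    if (len_d < min_len) next
    eq <- sv[i0:(i0 + len_d - 1L)] == tv[j0:(j0 + len_d - 1L)]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      hits[[length(hits) + 1L]] <- c(a = i0 + starts[k] - 1L,
                                     b = j0 + starts[k] - 1L,
                                     len = r$lengths[k])
    }
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

oracle_dispersed <- function(seq, min_len = 30) {
  n <- nchar(seq)
  rev_s <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
  comp_s <- chartr("ACGT", "TGCA", seq)
  rc_s <- chartr("ACGT", "TGCA", rev_s)
  out <- list()
  grab <- function(cls, t, map_back) {
    hits <- oracle_diagonal_pairs(seq, t, min_len = min_len)
    if (is.null(hits)) return()
    res <- list()
    for (r in seq_len(nrow(hits))) {
      a <- hits[r, "a"]; j <- hits[r, "b"]; len <- hits[r, "len"]
      b <- map_back(j, len)
      if (cls == "forward" && a >= b) next
      if (cls != "forward" && a == b) next
      res[[length(res) + 1L]] <- c(min(a, b), max(a, b), len)
    }
    if (length(res) == 0) return()
    res <- unique(do.call(rbind, res))
    for (r in seq_len(nrow(res)))
      out[[length(out) + 1L]] <<- data.frame(
        class = cls, length = res[r, 3], pos_a = res[r, 1], pos_b = res[r, 2],
        stringsAsFactors = FALSE)
  }
  grab("forward", seq, function(j, len) j)
  grab("reverse", rev_s, function(j, len) n - (j + len - 1L) + 1L)
  grab("palindromic", rc_s, function(j, len) n - (j + len - 1L) + 1L)
  grab("complementary", comp_s, function(j, len) j)
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(class = character(0), length = integer(0),
               pos_a = integer(0), pos_b = integer(0))
  out <- out[order(out$class, out$pos_a, out$pos_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## stem-loop oracle: direct triple scan over arm start / arm2 start / length
oracle_stemloops <- function(seq, min_stem = 5, max_loop = 50) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs_ok <- function(a, b, len) {
    all(v[a:(a + len - 1L)] == comp[rev(v[b:(b + len - 1L)])])
  }
  rows <- list()
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      max_len <- min(b - a, n - b + 1L)   # arms must not cross b, stay in seq
      for (len in min_stem:max_len) {
        if (len > max_len) break
        if (!pairs_ok(a, b, len)) next
        ## maximal: cannot extend outward or inward
        outward <- a > 1 && b + len <= n && v[a - 1L] == comp[[v[b + len]]]
        inward <- (b - 1L) - (a + len) >= 0 && v[a + len] == comp[[v[b - 1L]]] &&
          b - 1L >= a + len
        loop <- b - (a + len)
        if (!outward && !inward && loop >= 0 && loop <= max_loop) {
          rows[[length(rows) + 1L]] <- data.frame(
            stem_start = a, stem_len = len, loop_len = loop, stem2_start = b,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(stem_start = integer(0), stem_len = integer(0),
               loop_len = integer(0), stem2_start = integer(0))
  out <- out[order(out$stem_start, out$stem2_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
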