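# Independent brute-force oracles used to pin numeric conventions.
# These deliberately avoid the code paths (and, where possible, the
# library calls) of the implementation they check.

# Rank-based percentile by explicit linear interpolation of order statistics.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Median by explicit sorting and mid-index arithmetic.
oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(a_range, r1, n - r1, c1)
  p_obs <- dhyper(a_obs, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
# Mirrors the standard two-sided doubling rule on the enumerated U
# distribution.
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- combn(n1 + n2, n1)
  u_all <- apply(picks, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  m <- n1 * n2
  if (u_obs > m / 2) {
    p <- 2 * mean(u_all >= u_obs)
  } else {
    p <- 2 * mean(u_all <= u_obs)
  }
  min(1, p)
}

# Exact permutation p of the Kruskal-Wallis H by enumerating all distinct
# group assignments, computing H with stats::kruskal.test each time.
oracle_kw_perm_p <- function(x, sizes) {
  n <- length(x)
  g_obs <- factor(rep(seq_along(sizes), sizes))
  h_obs <- suppressWarnings(kruskal.test(x, g_obs)$statistic)
  tot <- 0L; ge <- 0L
  walk <- function(remaining, labels, grp) {
    if (grp > length(sizes)) {
      tot <<- tot + 1L
      h <- suppressWarnings(kruskal.test(x, factor(labels))$statistic)
      if (h >= h_obs - 1e-9) ge <<- ge + 1L
      return(invisible())
    }
    picks <- combn(remaining, sizes[grp])
    for (j in seq_len(ncol(picks))) {
      labels2 <- labels
      labels2[picks[, j]] <- grp
      walk(setdiff(remaining, picks[, j]), labels2, grp + 1L)
    }
  }
  walk(seq_len(n), integer(n), 1L)
  ge / tot
}

# Number of connected components of the union of half-open slice
# intervals [onset, onset + dur) — the overlap-merged truth pulse count.
oracle_merged_pulse_count <- function(onset, dur) {
  if (length(onset) == 0) return(0L)
  o <- order(onset)
  onset <- onset[o]; dur <- dur[o]
  n_comp <- 1L
  reach <- onset[1] + dur[1]
  for (i in seq_along(onset)[-1L]) {
    if (onset[i] > reach) {
      n_comp <- n_comp + 1L
      reach <- onset[i] + dur[i]
    } else {
      reach <- max(reach, onset[i] + dur[i])
    }
  }
  n_comp
}

# Intersection-over-union of two intervals.
interval_iou <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  inter / (max(a1, b1) - min(a0, b0))
}
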