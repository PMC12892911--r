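# Tail-bout segmentation and cohort kinematic summaries: bout frequency,
# vigor probability density with bootstrap CI, and the mobility timecourse
# with a 99% bootstrap CI and group-divergence masking.

#' Segment tail bouts from a tail-angle trace
#'
#' Computes the absolute angular speed `|d theta/dt|`, smooths it with a
#' centered moving average of `smooth_ms`, and applies hysteresis
#' thresholding: a bout opens when the smoothed speed exceeds `on_thresh`
#' and closes when it falls below `off_thresh`. Bouts shorter than
#' `min_dur_ms` are dropped; bouts separated by less than `min_gap_ms` are
#' merged. Vigor is the RMS of the raw angular velocity within the bout.
#'
#' Data-driven default thresholds (a documented convention): the smoothed
#' absolute speed of a noisy baseline has a nonzero median, so thresholds
#' are centered at the noise floor: `on_thresh` = median + 5 x MAD of the
#' smoothed speed, `off_thresh` = median + 2 x MAD. When the MAD is 0
#' (silent baseline), 5% and 2% of the peak smoothed speed are used
#' instead.
#'
#' @param trace list with `t`, `angle_deg`, `frame_rate` (uniform
#'   sampling), as from [simulate_tail_trace()].
#' @param smooth_ms moving-average width in milliseconds.
#' @param on_thresh_deg_s,off_thresh_deg_s hysteresis thresholds in deg/s
#'   (`NULL` = data-driven defaults; `on >= off > 0` required).
#' @param min_dur_ms minimum bout duration.
#' @param min_gap_ms merge gap.
#' @return data.frame of class `bout_records`: `start_s`, `end_s`, `vigor`
#'   (deg/s).
#' @export
segment_bouts <- function(trace, smooth_ms = 15,
                          on_thresh_deg_s = NULL, off_thresh_deg_s = NULL,
                          min_dur_ms = 40, min_gap_ms = 20) {
  dt <- diff(trace$t)
  if (length(dt) > 0 && (max(dt) - min(dt)) > 1e-6 * mean(dt)) {
    zp_stop("value_error", "tail trace must be uniformly sampled")
  }
  fr <- trace$frame_rate
  speed_raw <- c(0, diff(trace$angle_deg)) * fr
  k <- max(1L, round(smooth_ms / 1000 * fr))
  kernel <- rep(1 / k, k)
  speed <- stats::filter(abs(speed_raw), kernel, sides = 2)
  speed[is.na(speed)] <- 0
  speed <- as.numeric(speed)

  if (is.null(on_thresh_deg_s)) {
    m <- stats::mad(speed)
    if (m > 0) {
      med <- stats::median(speed)
      on_thresh_deg_s <- med + 5 * m
      off_thresh_deg_s <- med + 2 * m
    } else {
      pk <- max(speed)
      if (pk == 0) {
        empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                            vigor = numeric(0))
        class(empty) <- c("bout_records", "data.frame")
        return(empty)
      }
      on_thresh_deg_s <- 0.05 * pk
      off_thresh_deg_s <- 0.02 * pk
    }
  }
  if (is.null(off_thresh_deg_s)) off_thresh_deg_s <- on_thresh_deg_s / 2.5
  if (!(on_thresh_deg_s >= off_thresh_deg_s && off_thresh_deg_s > 0)) {
    zp_stop("value_error", "need on_thresh >= off_thresh > 0")
  }

  # hysteresis state machine
  n <- length(speed)
  open <- FALSE
  starts <- integer(0); ends <- integer(0); s0 <- 0L
  for (i in seq_len(n)) {
    if (!open && speed[i] > on_thresh_deg_s) {
      open <- TRUE; s0 <- i
    } else if (open && speed[i] < off_thresh_deg_s) {
      open <- FALSE
      starts <- c(starts, s0); ends <- c(ends, i - 1L)
    }
  }
  if (open) { starts <- c(starts, s0); ends <- c(ends, n) }
  if (length(starts) == 0) {
    empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                        vigor = numeric(0))
    class(empty) <- c("bout_records", "data.frame")
    return(empty)
  }

  # merge bouts separated by < min_gap_ms, then drop bouts < min_dur_ms
  min_gap <- min_gap_ms / 1000 * fr
  merged_s <- starts[1L]; merged_e <- ends[1L]
  for (j in seq_along(starts)[-1L]) {
    if (starts[j] - merged_e[length(merged_e)] < min_gap) {
      merged_e[length(merged_e)] <- ends[j]
    } else {
      merged_s <- c(merged_s, starts[j]); merged_e <- c(merged_e, ends[j])
    }
  }
  dur_ok <- (merged_e - merged_s + 1L) >= min_dur_ms / 1000 * fr
  merged_s <- merged_s[dur_ok]; merged_e <- merged_e[dur_ok]

  vigor <- vapply(seq_along(merged_s), function(j) {
    sqrt(mean(speed_raw[merged_s[j]:merged_e[j]]^2))
  }, numeric(1))
  out <- data.frame(start_s = trace$t[merged_s],
                    end_s = trace$t[merged_e] + 1 / fr,
                    vigor = vigor)
  class(out) <- c("bout_records", "data.frame")
  out
}

#' Bout frequency in bouts per minute
#' @param bouts a `bout_records` or [bout_intervals()] data.frame.
#' @param recording_duration_s recording length (> 0).
#' @return numeric bouts/minute.
#' @export
bout_frequency <- function(bouts, recording_duration_s) {
  if (recording_duration_s <= 0) zp_stop("value_error", "duration must be > 0")
  60 * nrow(bouts) / recording_duration_s
}

#' Gaussian kernel density evaluated on a fixed grid
#' @noRd
kde_on_grid <- function(x, grid, bw) {
  rowMeans(outer(grid, x, function(g, xi) stats::dnorm(g, xi, bw)))
}

#' Vigor probability density with pointwise bootstrap CI
#'
#' Gaussian kernel density of the pooled per-bout vigors of a group,
#' evaluated on a fixed grid, with a pointwise 95% percentile-bootstrap
#' confidence band obtained by resampling individuals (never bouts).
#'
#' @param vigors_by_individual list of numeric vectors, one per larva.
#' @param grid evaluation grid (`NULL` = data range widened by 6
#'   bandwidths, 512 points).
#' @param n_boot bootstrap replicates (default 1000).
#' @param ci confidence level in percent (default 95).
#' @param seed integer seed.
#' @return list `grid`, `density`, `ci_lo`, `ci_hi`, `bw`.
#' @export
vigor_density <- function(vigors_by_individual, grid = NULL, n_boot = 1000,
                          ci = 95, seed = 1L) {
  if (length(vigors_by_individual) < 2) {
    zp_stop("insufficient_data_error",
            "bootstrap over individuals needs >= 2 individuals")
  }
  pooled <- unlist(vigors_by_individual)
  if (length(pooled) < 2) zp_stop("insufficient_data_error", "needs >= 2 bouts")
  bw <- stats::bw.nrd0(pooled)
  if (is.null(grid)) {
    grid <- seq(min(pooled) - 6 * bw, max(pooled) + 6 * bw, length.out = 512L)
  }
  dens <- kde_on_grid(pooled, grid, bw)
  set.seed(child_seed(seed, "vigor_density"))
  n_ind <- length(vigors_by_individual)
  boot <- matrix(0, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    take <- sample.int(n_ind, n_ind, replace = TRUE)
    xb <- unlist(vigors_by_individual[take])
    boot[b, ] <- kde_on_grid(xb, grid, bw)
  }
  alpha <- (1 - ci / 100) / 2
  qs <- apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  list(grid = grid, density = dens, ci_lo = qs[1L, ], ci_hi = qs[2L, ], bw = bw)
}

#' Bout-occupancy fraction of each time bin
#' @noRd
occupancy_by_bin <- function(bouts, edges) {
  vapply(seq_len(length(edges) - 1L), function(b) {
    lo <- edges[b]; hi <- edges[b + 1L]
    if (nrow(bouts) == 0) return(0)
    ov <- pmin(bouts$end_s, hi) - pmax(bouts$start_s, lo)
    sum(pmax(ov, 0)) / (hi - lo)
  }, numeric(1))
}

#' Group mobility timecourse with bootstrap CI and divergence mask
#'
#' Mobility of a larva in a time bin is its bout-occupancy fraction (time
#' spent in bouts / bin width). Each group's mean timecourse carries a
#' pointwise percentile-bootstrap CI over larvae (default 99%); the
#' divergence mask marks bins where the two groups' intervals are
#' disjoint.
#'
#' @param bouts_by_larva_g1,bouts_by_larva_g2 lists (one element per
#'   larva) of bout data.frames with `start_s`, `end_s`; at least 2 larvae
#'   per group.
#' @param duration_s recording length.
#' @param bin_s bin width.
#' @param n_boot bootstrap replicates (default 1000).
#' @param ci confidence level in percent (default 99).
#' @param seed integer seed.
#' @return list `bin_start_s`, `mean_g1`, `lo_g1`, `hi_g1`, `mean_g2`,
#'   `lo_g2`, `hi_g2`, `diverged` (logical mask).
#' @export
mobility_timecourse <- function(bouts_by_larva_g1, bouts_by_larva_g2,
                                duration_s, bin_s, n_boot = 1000, ci = 99,
                                seed = 1L) {
  if (length(bouts_by_larva_g1) < 2 || length(bouts_by_larva_g2) < 2) {
    zp_stop("insufficient_data_error", "needs >= 2 larvae per group")
  }
  edges <- seq(0, duration_s, by = bin_s)
  if (edges[length(edges)] < duration_s) edges <- c(edges, duration_s)
  occ1 <- t(vapply(bouts_by_larva_g1, occupancy_by_bin, edges = edges,
                   numeric(length(edges) - 1L)))
  occ2 <- t(vapply(bouts_by_larva_g2, occupancy_by_bin, edges = edges,
                   numeric(length(edges) - 1L)))
  alpha <- (1 - ci / 100) / 2
  boot_band <- function(occ, stream) {
    set.seed(child_seed(seed, stream))
    nb <- nrow(occ)
    means <- matrix(0, n_boot, ncol(occ))
    for (b in seq_len(n_boot)) {
      means[b, ] <- colMeans(occ[sample.int(nb, nb, replace = TRUE), ,
                                 drop = FALSE])
    }
    apply(means, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
          names = FALSE)
  }
  band1 <- boot_band(occ1, "mobility_g1")
  band2 <- boot_band(occ2, "mobility_g2")
  diverged <- band1[2L, ] < band2[1L, ] | band2[2L, ] < band1[1L, ]
  list(bin_start_s = edges[-length(edges)],
       mean_g1 = colMeans(occ1), lo_g1 = band1[1L, ], hi_g1 = band1[2L, ],
       mean_g2 = colMeans(occ2), lo_g2 = band2[1L, ], hi_g2 = band2[2L, ],
       diverged = diverged)
}
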