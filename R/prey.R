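# Prey-capture quantification: rotifer depletion curves and
# eye-convergence-gated hunting events.

#' Rolling median over a centered time window
#'
#' For each sample, the median of all values whose timestamps fall in the
#' centered window `[t - w/2, t + w/2]`; at the edges the window truncates
#' to the available samples (no padding, so early depletion is not biased).
#' Output length equals input length; medians of integer counts may be
#' half-integers for even window counts.
#'
#' @param series data.frame with columns `t` (strictly increasing seconds)
#'   and `count`.
#' @param window_s window width in seconds (default 10).
#' @return the series with `count` replaced by the filtered values
#'   (numeric).
#' @export
rolling_median <- function(series, window_s = 10) {
  if (window_s <= 0) zp_stop("value_error", "window_s must be > 0")
  tt <- series$t
  x <- series$count
  n <- length(x)
  out <- numeric(n)
  lo <- 1L; hi <- 0L
  for (i in seq_len(n)) {
    while (lo <= n && tt[lo] < tt[i] - window_s / 2 - 1e-12) lo <- lo + 1L
    while (hi < n && tt[hi + 1L] <= tt[i] + window_s / 2 + 1e-12) hi <- hi + 1L
    out[i] <- stats::median(x[lo:hi])
  }
  res <- series
  res$count <- out
  res
}

#' Proportion of rotifers consumed over time
#'
#' Normalizes the (filtered) count series to the mean count over the first
#' minute and subtracts from 1: `p(t) = 1 - count(t) / baseline`. Values
#' below 0 (count noise above baseline) are reported, not clamped, with a
#' QC warning.
#'
#' @param series filtered count series (data.frame `t`, `count`) covering
#'   at least 60 s.
#' @return data.frame `t`, `proportion`.
#' @export
proportion_consumed <- function(series) {
  if (max(series$t) - min(series$t) < 60) {
    zp_stop("value_error", "series must cover at least 60 s")
  }
  first_min <- series$count[series$t <= min(series$t) + 60]
  baseline <- mean(first_min)
  if (baseline <= 0) {
    zp_stop("value_error", "first-minute baseline count is <= 0")
  }
  p <- 1 - series$count / baseline
  if (any(p < 0)) {
    zp_warn("qc_warning", "%d sample(s) with proportion consumed < 0 (count above baseline)",
            sum(p < 0))
  }
  data.frame(t = series$t, proportion = p)
}

#' Proportion consumed at a single time point
#'
#' The depletion curve evaluated at the frame nearest `t` (earlier frame
#' on ties). The study's headline comparison point is 15 minutes (900 s),
#' when wild-type capture begins to slow from satiation.
#'
#' @param series filtered count series (data.frame `t`, `count`).
#' @param t time point in seconds (default 900).
#' @return numeric proportion.
#' @export
proportion_at <- function(series, t = 900) {
  if (t < min(series$t) || t > max(series$t)) {
    zp_stop("value_error", "t = %g s is outside the series span [%g, %g]",
            t, min(series$t), max(series$t))
  }
  p <- proportion_consumed(series)
  d <- abs(p$t - t)
  i <- which(d == min(d))[1L]  # ties -> earlier frame
  p$proportion[i]
}

#' Detect bout-aligned hunting events from eye convergence
#'
#' A bout is "converging" if the convergence is at or below the threshold
#' at the bout's onset sample and crosses above it during the bout; it is
#' "still-converged" if the convergence already exceeds the threshold at
#' its onset. A hunting event starts at a converging bout and extends
#' through the maximal run of immediately following still-converged bouts,
#' ending at the end of the last such bout. Events never overlap; bouts
#' with no super-threshold convergence belong to no event.
#'
#' @param convergence data.frame `t`, `convergence_deg` (summed nasal
#'   rotation of both eyes).
#' @param bouts a [bout_intervals()].
#' @param threshold_deg hunting criterion in degrees (default 60, the
#'   published value).
#' @return data.frame of class `hunting_events`: `start_s`, `end_s`,
#'   `n_bouts`, `duration_s`.
#' @export
detect_hunting_events <- function(convergence, bouts, threshold_deg = 60) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_bouts = integer(0), duration_s = numeric(0))
  class(empty) <- c("hunting_events", "data.frame")
  if (nrow(bouts) == 0) {
    if (any(convergence$convergence_deg > threshold_deg)) {
      zp_warn("qc_warning",
              "super-threshold convergence with no bouts: events cannot be aligned")
    }
    return(empty)
  }
  tt <- convergence$t
  cv <- convergence$convergence_deg
  n_b <- nrow(bouts)
  onset_conv <- numeric(n_b)
  has_above <- logical(n_b)
  for (i in seq_len(n_b)) {
    in_bout <- which(tt >= bouts$start_s[i] - 1e-9 & tt < bouts$end_s[i] - 1e-9)
    if (length(in_bout) == 0) {
      # convergence not sampled inside this bout: use the nearest earlier sample
      j <- findInterval(bouts$start_s[i], tt)
      onset_conv[i] <- if (j >= 1) cv[j] else cv[1L]
      has_above[i] <- FALSE
      next
    }
    onset_conv[i] <- cv[in_bout[1L]]
    has_above[i] <- any(cv[in_bout] > threshold_deg)
  }
  converging <- has_above & onset_conv <= threshold_deg
  still_converged <- onset_conv > threshold_deg

  ev <- list()
  i <- 1L
  while (i <= n_b) {
    if (converging[i]) {
      j <- i
      while (j + 1L <= n_b && still_converged[j + 1L]) j <- j + 1L
      ev[[length(ev) + 1L]] <- c(start_s = bouts$start_s[i],
                                 end_s = bouts$end_s[j],
                                 n_bouts = j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(ev) == 0) return(empty)
  m <- do.call(rbind, ev)
  out <- data.frame(start_s = m[, "start_s"], end_s = m[, "end_s"],
                    n_bouts = as.integer(m[, "n_bouts"]))
  out$duration_s <- out$end_s - out$start_s
  stopifnot(all(out$duration_s > 0),
            !is.unsorted(out$start_s),
            all(out$start_s[-1L] >= out$end_s[-nrow(out)] - 1e-12))
  class(out) <- c("hunting_events", "data.frame")
  out
}

#' Hunting-event counts and durations per time interval
#'
#' Tiles `[0, total_s)` into bins of `bin_s` seconds; an event belongs to
#' the bin containing its start. Empty bins report `n_events = 0` and an
#' undefined (`NA`) mean duration.
#'
#' @param events a `hunting_events` data.frame.
#' @param total_s session length (default 900).
#' @param bin_s bin width (default 300 = 5 min); must tile `total_s`.
#' @return data.frame `bin_start_s`, `bin_end_s`, `n_events`,
#'   `mean_duration_s`.
#' @export
interval_summary <- function(events, total_s = 900, bin_s = 300) {
  if (total_s %% bin_s != 0) {
    zp_stop("value_error", "bin_s = %g does not tile total_s = %g", bin_s, total_s)
  }
  edges <- seq(0, total_s, by = bin_s)
  n_bins <- length(edges) - 1L
  out <- data.frame(bin_start_s = edges[-length(edges)],
                    bin_end_s = edges[-1L],
                    n_events = 0L, mean_duration_s = NA_real_)
  if (nrow(events) > 0) {
    bin <- findInterval(events$start_s, edges, rightmost.closed = FALSE)
    keep <- bin >= 1 & bin <= n_bins
    for (b in unique(bin[keep])) {
      sel <- events[keep & bin == b, , drop = FALSE]
      out$n_events[b] <- nrow(sel)
      out$mean_duration_s[b] <- mean(sel$duration_s)
    }
  }
  out
}

#' Full per-session prey-capture summary
#'
#' Median-filters the counts, computes the depletion curve, the
#' 15-minute proportion consumed, the detected hunting events and their
#' 5-minute interval summary.
#'
#' @param session list with `counts`, `convergence`, `bouts` (as from
#'   [read_tracking_tables()] or [simulate_prey_session()]).
#' @param threshold_deg convergence criterion (default 60).
#' @param window_s median-filter window (default 10).
#' @param bin_s interval width (default 300).
#' @param at_s comparison time point (default 900).
#' @return list `filtered`, `depletion`, `proportion_at`, `events`,
#'   `intervals`.
#' @export
prey_session_summary <- function(session, threshold_deg = 60, window_s = 10,
                                 bin_s = 300, at_s = 900) {
  filtered <- rolling_median(session$counts, window_s)
  depletion <- proportion_consumed(filtered)
  events <- detect_hunting_events(session$convergence, session$bouts,
                                  threshold_deg)
  total <- ceiling(max(session$counts$t) / bin_s) * bin_s
  list(filtered = filtered,
       depletion = depletion,
       proportion_at = proportion_at(filtered, min(at_s, max(filtered$t))),
       events = events,
       intervals = interval_summary(events, total_s = total, bin_s = bin_s))
}
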