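test_that("rolling median matches the brute-force per-window oracle", {
  # constant series is unchanged
  const <- data.frame(t = seq(0, 100, by = 0.5), count = 7L)
  expect_equal(rolling_median(const)$count, rep(7, 201))

  # single-frame dropout is removed entirely
  spiky <- const
  spiky$count[100] <- 0L
  expect_equal(rolling_median(spiky)$count, rep(7, 201))

  # random integer series, including irregular time stamps
  set.seed(91)
  for (r in 1:5) {
    tt <- sort(runif(120, 0, 60))
    x <- rpois(120, 8)
    filt <- rolling_median(data.frame(t = tt, count = x), window_s = 10)
    brute <- vapply(seq_along(tt), function(i) {
      idx <- which(tt >= tt[i] - 5 - 1e-12 & tt <= tt[i] + 5 + 1e-12)
      oracle_median(x[idx])
    }, numeric(1))
    expect_equal(filt$count, brute)
  }
  expect_error(rolling_median(const, window_s = 0), "> 0")
})

test_that("rolling median is idempotent on monotone series away from the edges", {
  # within the edges the truncated windows re-center, so idempotence
  # holds one full window-width into the series
  mono <- data.frame(t = seq(0, 60, by = 0.2), count = sort(rpois(301, 20)))
  once <- rolling_median(mono)
  twice <- rolling_median(once)
  interior <- mono$t >= 10 & mono$t <= 50
  expect_equal(once$count[interior], twice$count[interior])
})

test_that("proportion consumed normalizes to the first-minute baseline", {
  # constant counts: nothing consumed
  const <- data.frame(t = seq(0, 900, by = 1), count = 20)
  expect_true(all(proportion_consumed(const)$proportion == 0))
  expect_equal(proportion_at(const, 900), 0)

  # counts halve after the first minute
  step <- data.frame(t = seq(0, 900, by = 1),
                     count = c(rep(20, 61), rep(10, 840)))
  p <- proportion_consumed(step)
  expect_equal(p$proportion[p$t > 61], rep(0.5, sum(p$t > 61)))
  expect_equal(proportion_at(step, 900), 0.5)

  # negative proportions are reported with a QC warning, not clamped
  bump <- data.frame(t = seq(0, 120, by = 1), count = c(rep(10, 61), rep(12, 60)))
  expect_warning(pb <- proportion_consumed(bump), "proportion consumed < 0")
  expect_lt(min(pb$proportion), 0)

  short <- data.frame(t = seq(0, 30, by = 1), count = 5)
  expect_error(proportion_consumed(short), "60 s")
  expect_error(proportion_at(const, 1200), "outside")
  zero <- data.frame(t = seq(0, 120, by = 1), count = 0)
  expect_error(proportion_consumed(zero), "baseline")
})

test_that("exponential depletion matches its closed form", {
  r <- 0.002
  n0 <- 1000
  tt <- seq(0, 900, by = 0.5)
  series <- data.frame(t = tt, count = round(n0 * exp(-r * tt)))
  filt <- rolling_median(series)
  # count rounding can nudge early samples above the baseline; the QC
  # warning for those sub-zero proportions is expected here
  p <- suppressWarnings(proportion_consumed(filt))
  baseline <- mean(filt$count[filt$t <= 60])
  t0 <- -log(baseline / n0) / r
  late <- p$t > 60
  expect_lt(max(abs(p$proportion[late] - (1 - exp(-r * (p$t[late] - t0))))),
            0.02)
})

test_that("hunting-event detection follows the bout-aligned semantics", {
  # convergence never above threshold: no events
  conv_low <- data.frame(t = seq(0, 10, by = 0.04), convergence_deg = 40)
  bouts <- bout_intervals(c(1, 3, 5), c(1.4, 3.4, 5.4))
  expect_equal(nrow(detect_hunting_events(conv_low, bouts)), 0L)

  # hand-built event: conv rises above 60 inside bout 1, stays high through
  # bout 2's onset, drops before bout 3
  tt <- seq(0, 10, by = 0.04)
  conv <- rep(40, length(tt))
  conv[tt > 1 & tt <= 3.4] <- 75
  ev <- detect_hunting_events(data.frame(t = tt, convergence_deg = conv), bouts)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_s, 1)
  expect_equal(ev$end_s, 3.4)
  expect_equal(ev$n_bouts, 2L)

  # a bout that is already converged at onset cannot start an event
  conv2 <- rep(40, length(tt))
  conv2[tt >= 2.9 & tt <= 3.5] <- 75  # high before and during bout 2 only
  ev2 <- detect_hunting_events(data.frame(t = tt, convergence_deg = conv2),
                               bouts)
  expect_equal(nrow(ev2), 0L)

  # convergence without any bouts warns and returns zero events
  expect_warning(
    ev3 <- detect_hunting_events(data.frame(t = tt, convergence_deg = 80),
                                 bout_intervals()),
    "no bouts"
  )
  expect_equal(nrow(ev3), 0L)
})

test_that("clean simulated sessions are recovered exactly", {
  for (s in 1:10) {
    ses <- simulate_prey_session(duration_s = 600, seed = s)
    ev <- detect_hunting_events(ses$convergence, ses$bouts)
    truth <- ses$truth$true_events
    expect_equal(nrow(ev), nrow(truth))
    expect_equal(ev$start_s, truth$start_s, tolerance = 1e-9)
    expect_equal(ev$end_s, truth$end_s, tolerance = 1e-9)
    expect_equal(ev$n_bouts, truth$n_bouts)
    # invariants: sorted, non-overlapping, bout-aligned
    if (nrow(ev) > 1) {
      expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
    }
    expect_true(all(ev$start_s %in% ses$bouts$start_s))
    expect_true(all(ev$end_s %in% ses$bouts$end_s))
  }
})

test_that("the detector is stable in the gap between baseline and hunting convergence", {
  # any threshold strictly between the baseline ceiling and the
  # hunting-convergence floor separates the same samples, so the events
  # are identical; a threshold above every sample yields none
  ses <- simulate_prey_session(duration_s = 600, seed = 77)
  ref <- detect_hunting_events(ses$convergence, ses$bouts, threshold_deg = 60)
  for (th in c(57, 60, 63)) {
    ev <- detect_hunting_events(ses$convergence, ses$bouts, threshold_deg = th)
    expect_equal(ev$start_s, ref$start_s)
    expect_equal(ev$end_s, ref$end_s)
  }
  above_all <- max(ses$convergence$convergence_deg) + 1
  expect_equal(nrow(detect_hunting_events(ses$convergence, ses$bouts,
                                          threshold_deg = above_all)), 0L)
})

test_that("interval summaries bin events by their start", {
  none <- detect_hunting_events(
    data.frame(t = seq(0, 10, 0.04), convergence_deg = 40),
    bout_intervals()
  )
  s0 <- interval_summary(none)
  expect_equal(s0$n_events, rep(0L, 3))
  expect_true(all(is.na(s0$mean_duration_s)))

  ev <- data.frame(start_s = c(10, 310, 320), end_s = c(12, 311, 321),
                   n_bouts = 1L, duration_s = c(2, 1, 1))
  s1 <- interval_summary(ev)
  expect_equal(s1$n_events, c(1L, 2L, 0L))
  expect_equal(s1$mean_duration_s, c(2, 1, NA))
  expect_error(interval_summary(ev, total_s = 900, bin_s = 400), "tile")

  # Poisson event starts fall into bins at the expected rate
  set.seed(13)
  rate <- 1 / 60
  n_sessions <- 200
  per_bin <- matrix(0, n_sessions, 3)
  for (i in seq_len(n_sessions)) {
    k <- rpois(1, rate * 900)
    starts <- sort(runif(k, 0, 900))
    evs <- data.frame(start_s = starts, end_s = starts + 1, n_bouts = 1L,
                      duration_s = 1)
    per_bin[i, ] <- interval_summary(evs)$n_events
  }
  expected <- rate * 300
  se <- sqrt(expected / n_sessions)
  for (b in 1:3) {
    expect_lt(abs(mean(per_bin[, b]) - expected), 3 * se)
  }
})

test_that("per-session summary ties the pieces together", {
  ses <- simulate_prey_session(duration_s = 900, hunt_success_prob = 0.9,
                               seed = 19)
  s <- prey_session_summary(ses)
  expect_equal(nrow(s$events), nrow(ses$truth$true_events))
  expect_equal(sum(s$intervals$n_events), nrow(s$events))
  expect_gte(s$proportion_at, 0)
  expect_lte(s$proportion_at, 1)
})
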