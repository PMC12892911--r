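test_that("event detection counts maximal runs with optional gap merging", {
  expect_equal(detect_events(c(0, 5, 0, 7, 7, 0), threshold = 1), 2L)
  expect_equal(detect_events(rep(0, 10), threshold = 1), 0L)
  expect_equal(detect_events(c(0, 5, 0, 7, 7, 0), threshold = 1,
                             merge_gap_slices = 1), 1L)
  expect_equal(detect_events(c(5, 5, 5), threshold = 1), 1L)
  expect_error(detect_events(1:3, threshold = 0), "positive")
})

test_that("event counts are monotone in merge gap, and in threshold for plateau pulses", {
  set.seed(77)
  for (r in 1:20) {
    # arbitrary non-negative traces: merging can only reduce the count
    v <- rpois(200, 1) * runif(200, 0, 10)
    gaps <- 0:5
    counts_g <- vapply(gaps, function(g) detect_events(v, 1, g), 0L)
    expect_true(all(diff(counts_g) <= 0))

    # non-overlapping rectangular pulses: raising the threshold can drop
    # whole events but never split one (each pulse is a flat plateau)
    v2 <- numeric(300)
    starts <- sort(sample(seq(1, 290, by = 10), 12))
    for (s0 in starts) v2[s0:(s0 + 3)] <- runif(1, 1, 10)
    thresholds <- c(0.5, 1, 2, 4, 8)
    counts <- vapply(thresholds, function(th) detect_events(v2, th), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("noiseless traces recover the overlap-merged truth pulse count", {
  proto <- lfr_protocol("simple")
  for (s in 1:20) {
    sim <- simulate_actinteg(proto, genotype_effect(bout_rate_hz = 0.4),
                             n_larvae = 1, seed = s)
    truth <- sim$truth
    if (nrow(truth) == 0) next
    th <- min(truth$amplitude) * 0.5
    if (th <= 0) next
    got <- detect_events(sim$traces[[1]]$values, th)
    expect_equal(got,
                 oracle_merged_pulse_count(truth$onset_slice,
                                           truth$duration_slices))
  }
})

test_that("simple-protocol LFR metrics use the first 4 s of light", {
  proto <- lfr_protocol("simple")
  n <- protocol_duration_slices(proto)
  light_start <- 300L * 15L

  vals <- numeric(n)
  m0 <- lfr_simple(activity_trace("w", vals, proto), threshold = 1)
  expect_equal(m0$max_activity, 0)
  expect_equal(m0$n_events, 0L)

  # a pulse inside the 4-s window is seen...
  vals_in <- vals
  vals_in[light_start + 30L] <- 9
  m1 <- lfr_simple(activity_trace("w", vals_in, proto), threshold = 1)
  expect_equal(m1$max_activity, 9)
  expect_equal(m1$n_events, 1L)

  # ...a pulse after 4 s of light (the freezing phase) is not
  vals_out <- vals
  vals_out[light_start + 61L] <- 9
  m2 <- lfr_simple(activity_trace("w", vals_out, proto), threshold = 1)
  expect_equal(m2$max_activity, 0)
  expect_equal(m2$n_events, 0L)

  # wrong protocol is rejected
  ext <- lfr_protocol("extended")
  tr_ext <- activity_trace("w", numeric(protocol_duration_slices(ext)), ext)
  expect_error(lfr_simple(tr_ext, threshold = 1), "simple")
})

test_that("responder and non-responder cohorts separate in event counts", {
  proto <- lfr_protocol("simple")
  n_larvae <- 120
  resp <- simulate_actinteg(proto,
                            genotype_effect(bout_rate_hz = 0,
                                            flash_response_prob = 0.9),
                            n_larvae, seed = 41)
  nonresp <- simulate_actinteg(proto,
                               genotype_effect(bout_rate_hz = 0,
                                               flash_response_prob = 0.2),
                               n_larvae, seed = 42)
  count_events <- function(sim) {
    vapply(sim$traces, function(tr) {
      lfr_simple(tr, threshold = 0.5)$n_events
    }, 0L)
  }
  # response latency is uniform on [0, 4), so every response lands in the
  # 4-s scoring window; the mean count difference estimates the
  # response-probability difference
  d <- mean(count_events(resp)) - mean(count_events(nonresp))
  se <- sqrt((0.9 * 0.1 + 0.2 * 0.8) / n_larvae)
  expect_lt(abs(d - 0.7), 3 * se)
})

test_that("triggered averages satisfy the constant and impulse identities", {
  ext <- lfr_protocol("extended")
  n <- protocol_duration_slices(ext)

  # constant trace c: v1 = v2 = 15 c
  tr_c <- activity_trace("w", rep(2, n), ext)
  ta <- triggered_average(tr_c)
  expect_equal(ta$v1, 30)
  expect_equal(ta$v2, 30)
  expect_equal(ta$per_flash[, "v1"], rep(30, 8), ignore_attr = TRUE)

  # impulse of summed actinteg A at one onset: v1 = A / 16, v2 = 0
  vals <- numeric(n)
  onset_slice <- seconds_to_slices(flash_onsets(ext)[3]) + 1L
  A <- 24
  vals[onset_slice] <- A
  ta2 <- triggered_average(activity_trace("w", vals, ext))
  expect_equal(ta2$v1, A / 16)
  expect_equal(ta2$v2, 0)

  # window past the trace end is an error
  expect_error(triggered_average(tr_c, onsets = 1111), "past the trace end")
})

test_that("per-flash averaging equals the pooled single-pass mean", {
  ext <- lfr_protocol("extended")
  set.seed(55)
  vals <- rpois(protocol_duration_slices(ext), 2) * runif(17100, 0, 3)
  tr <- activity_trace("w", vals, ext)
  ta <- triggered_average(tr)
  onsets <- flash_onsets(ext)
  pool_idx <- function(len0, len1) {
    unlist(lapply(onsets, function(o) {
      s0 <- seconds_to_slices(o) + 1L
      (s0 + len0):(s0 + len1 - 1L)
    }))
  }
  expect_equal(ta$v1, mean(vals[pool_idx(0L, 30L)]) * 15)
  expect_equal(ta$v2, mean(vals[pool_idx(30L, 450L)]) * 15)
})

test_that("fatigue makes per-flash V1 non-increasing in expectation", {
  ext <- lfr_protocol("extended")
  sim <- simulate_actinteg(ext,
                           genotype_effect(bout_rate_hz = 0,
                                           flash_response_prob = 1,
                                           fatigue = 0.7),
                           n_larvae = 200, seed = 61)
  per_flash <- sapply(sim$traces, function(tr) {
    triggered_average(tr)$per_flash[, "v1"]
  })
  mean_v1 <- rowMeans(per_flash)
  slope <- coef(lm(mean_v1 ~ seq_along(mean_v1)))[2]
  expect_lt(slope, 0)
})

test_that("spontaneous activity averages the 10-minute dark window", {
  ext <- lfr_protocol("extended")
  n <- protocol_duration_slices(ext)
  expect_equal(spontaneous_activity(activity_trace("w", numeric(n), ext)), 0)
  expect_equal(spontaneous_activity(activity_trace("w", rep(3, n), ext)), 45)

  # the adaptation window is excluded: activity only there scores zero
  vals <- numeric(n)
  vals[1:4500] <- 10
  expect_equal(spontaneous_activity(activity_trace("w", vals, ext)), 0)

  # point-process mean: rate x amplitude x duration / 15 per second
  rate <- 0.4; amp <- 30
  sim <- simulate_actinteg(ext,
                           genotype_effect(bout_rate_hz = rate,
                                           flash_response_prob = 0,
                                           response_amp_mean = amp,
                                           response_amp_sd = 0),
                           n_larvae = 300, seed = 71)
  sa <- vapply(sim$traces, spontaneous_activity, numeric(1))
  mean_dur <- 3.5  # slices, uniform on 2..5
  # each bout deposits amp x duration summed actinteg, so the expected
  # activity per second is rate x amp x mean duration (in seconds x 15)
  expected <- rate * amp * mean_dur
  expect_lt(abs(mean(sa) - expected), 3 * sd(sa) / sqrt(length(sa)))
})

test_that("LFR metrics are scale-equivariant", {
  proto <- lfr_protocol("simple")
  sim <- simulate_actinteg(proto, genotype_effect(), 2, seed = 81)
  tr <- sim$traces[[1]]
  k <- 3.7
  tr_k <- activity_trace(tr$well_id, tr$values * k, proto)
  m <- lfr_simple(tr, threshold = 2)
  m_k <- lfr_simple(tr_k, threshold = 2 * k)
  expect_equal(m_k$max_activity, k * m$max_activity)
  expect_equal(m_k$n_events, m$n_events)

  ext_sim <- simulate_actinteg(lfr_protocol("extended"), genotype_effect(),
                               1, seed = 82)
  tre <- ext_sim$traces[[1]]
  tre_k <- activity_trace(tre$well_id, tre$values * k, tre$protocol)
  expect_equal(triggered_average(tre_k)$v1, k * triggered_average(tre)$v1)
  expect_equal(spontaneous_activity(tre_k), k * spontaneous_activity(tre))
})

test_that("noiseless cohorts recover the injected effect sign every time", {
  proto <- lfr_protocol("simple")
  hits <- 0L
  for (s in 1:25) {
    strong <- simulate_actinteg(proto,
                                genotype_effect(flash_response_prob = 0.9,
                                                response_amp_mean = 50),
                                10, seed = s)
    weak <- simulate_actinteg(proto,
                              genotype_effect(flash_response_prob = 0.3,
                                              response_amp_mean = 20),
                              10, seed = s + 1000)
    mx <- function(sim) {
      mean(vapply(sim$traces,
                  function(tr) lfr_simple(tr, threshold = 0.5)$max_activity,
                  numeric(1)))
    }
    if (mx(strong) > mx(weak)) hits <- hits + 1L
  }
  expect_equal(hits, 25L)
})
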