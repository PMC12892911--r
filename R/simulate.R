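# Synthetic-data generators.
#
# Every input modality of the pipeline can be generated with known ground
# truth, so each detector and summary is testable without rig hardware.
# All generators are pure functions of (parameters, seed); one seed governs
# a session via a named child stream per sub-generator (child_seed()), so
# adding a generator never perturbs another's stream.

#' Truncated-normal draws (lower bound 0) via inverse CDF
#' @noRd
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, 1))
}

#' Genotype effect parameters for the activity generator
#'
#' Baseline dark bout rate, probability of responding to a light flash
#' within 4 s, response-pulse amplitude distribution, and a multiplicative
#' per-flash decay of the response probability (habituation/fatigue).
#'
#' @param label group label, conventionally `"wt"` or `"hom"`.
#' @param bout_rate_hz spontaneous bouts per second in the dark.
#' @param flash_response_prob probability in `[0, 1]` of one response bout
#'   within 4 s of a flash.
#' @param response_amp_mean,response_amp_sd actinteg units of the response
#'   pulse amplitude (normal, truncated at 0).
#' @param fatigue in `(0, 1]`; flash k responds with probability
#'   `flash_response_prob * fatigue^(k-1)`.
#' @return a `genotype_effect` list.
#' @export
genotype_effect <- function(label = "wt",
                            bout_rate_hz = 0.5,
                            flash_response_prob = 0.9,
                            response_amp_mean = 40,
                            response_amp_sd = 10,
                            fatigue = 0.95) {
  if (flash_response_prob < 0 || flash_response_prob > 1) {
    zp_stop("value_error", "flash_response_prob must be in [0, 1]")
  }
  if (bout_rate_hz < 0) zp_stop("value_error", "bout_rate_hz must be >= 0")
  if (fatigue <= 0 || fatigue > 1) zp_stop("value_error", "fatigue must be in (0, 1]")
  structure(list(label = label, bout_rate_hz = bout_rate_hz,
                 flash_response_prob = flash_response_prob,
                 response_amp_mean = response_amp_mean,
                 response_amp_sd = response_amp_sd,
                 fatigue = fatigue),
            class = "genotype_effect")
}

#' Simulate a fluorescence plate from a heterozygous in-cross
#'
#' Genotypes are drawn per well from the Mendelian 1:2:1 (wt:het:hom)
#' multinomial; each well's fluorescence is drawn from its genotype's
#' normal distribution. Defaults model a clear but imperfect separation of
#' homozygotes on a normalized-fluorescence scale: wt/het N(1.0, 0.15),
#' hom N(1.8, 0.25).
#'
#' @param n_wells number of wells (at least 4, or quartile sorting is
#'   undefined).
#' @param mendelian_probs length-3 probabilities for (wt, het, hom);
#'   must sum to 1.
#' @param mu_by_genotype,sd_by_genotype named numeric vectors with entries
#'   `wt`, `het`, `hom`; sds must be >= 0.
#' @param seed integer seed.
#' @return a [plate_fluorescence()] with `true_genotype` filled in.
#' @export
simulate_plate <- function(n_wells = 94,
                           mendelian_probs = c(0.25, 0.5, 0.25),
                           mu_by_genotype = c(wt = 1.0, het = 1.0, hom = 1.8),
                           sd_by_genotype = c(wt = 0.15, het = 0.15, hom = 0.25),
                           seed = 1L) {
  if (!is_count(n_wells) || n_wells < 4) {
    zp_stop("value_error", "n_wells must be an integer >= 4 (quartiles undefined below)")
  }
  if (abs(sum(mendelian_probs) - 1) > 1e-9) {
    zp_stop("value_error", "mendelian_probs must sum to 1")
  }
  if (any(sd_by_genotype < 0)) zp_stop("value_error", "sds must be >= 0")
  set.seed(child_seed(seed, "plate"))
  geno <- sample(c("wt", "het", "hom"), n_wells, replace = TRUE,
                 prob = mendelian_probs)
  fl <- stats::rnorm(n_wells, mu_by_genotype[geno], sd_by_genotype[geno])
  plate_fluorescence(sprintf("W%03d", seq_len(n_wells)), fl, geno)
}

#' Simulate actinteg activity traces with ground-truth bouts
#'
#' Spontaneous bouts arrive as a homogeneous Poisson process at the
#' genotype's `bout_rate_hz` over the whole recording; each light flash of
#' the protocol elicits, with probability `flash_response_prob *
#' fatigue^(k-1)` for flash k, one response bout at a latency uniform in
#' `[0, 4)` s. Every bout deposits a rectangular actinteg pulse (duration
#' uniform on 2--5 slices, amplitude normal truncated at 0); overlapping
#' pulses sum.
#'
#' @param protocol a [stimulus_protocol()].
#' @param effect a [genotype_effect()].
#' @param n_larvae number of larvae (>= 1).
#' @param seed integer seed.
#' @return list with `traces` (named list of [activity_trace()]) and
#'   `truth` (data.frame `larva`, `onset_slice` (0-based), `duration_slices`,
#'   `amplitude`, `kind` ("spontaneous"/"response"), `flash_index`).
#' @export
simulate_actinteg <- function(protocol, effect, n_larvae, seed = 1L) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(effect, "genotype_effect"))
  if (!is_count(n_larvae) || n_larvae < 1) {
    zp_stop("value_error", "n_larvae must be an integer >= 1")
  }
  set.seed(child_seed(seed, "actinteg"))
  n_slices <- protocol_duration_slices(protocol)
  total_s <- protocol_duration_s(protocol)
  onsets <- flash_onsets(protocol)
  traces <- vector("list", n_larvae)
  truth <- vector("list", n_larvae)
  for (i in seq_len(n_larvae)) {
    t_bout <- numeric(0); kind <- character(0); flash_idx <- integer(0)
    n_sp <- stats::rpois(1L, effect$bout_rate_hz * total_s)
    if (n_sp > 0) {
      t_bout <- sort(stats::runif(n_sp, 0, total_s))
      kind <- rep("spontaneous", n_sp)
      flash_idx <- rep(NA_integer_, n_sp)
    }
    for (k in seq_along(onsets)) {
      p_k <- effect$flash_response_prob * effect$fatigue^(k - 1L)
      if (stats::runif(1L) < p_k) {
        t_bout <- c(t_bout, onsets[k] + stats::runif(1L, 0, 4))
        kind <- c(kind, "response")
        flash_idx <- c(flash_idx, k)
      }
    }
    n_b <- length(t_bout)
    values <- numeric(n_slices)
    if (n_b > 0) {
      onset_slice <- pmin(floor(t_bout * 15), n_slices - 1L)
      dur <- sample(2:5, n_b, replace = TRUE)
      amp <- rnorm_trunc0(n_b, effect$response_amp_mean, effect$response_amp_sd)
      for (b in seq_len(n_b)) {
        s0 <- onset_slice[b] + 1L  # to 1-based
        s1 <- min(s0 + dur[b] - 1L, n_slices)
        values[s0:s1] <- values[s0:s1] + amp[b]
      }
      truth[[i]] <- data.frame(larva = i, onset_slice = as.integer(onset_slice),
                               duration_slices = as.integer(dur),
                               amplitude = amp, kind = kind,
                               flash_index = flash_idx)
    } else {
      truth[[i]] <- data.frame(larva = integer(), onset_slice = integer(),
                               duration_slices = integer(), amplitude = numeric(),
                               kind = character(), flash_index = integer())
    }
    traces[[i]] <- activity_trace(sprintf("L%03d", i), values, protocol)
  }
  names(traces) <- vapply(traces, function(x) x$well_id, character(1))
  list(traces = traces, truth = do.call(rbind, truth))
}

# Grid step of the synthetic convergence trace (25 Hz) and of the observed
# rotifer-count trace (5 Hz). Bout boundaries are snapped to the
# convergence grid so that detector semantics recover events exactly on
# clean simulations.
.conv_dt <- 0.04
.count_dt <- 0.2

#' Simulate a prey-capture session with ground truth
#'
#' Hunting events arrive as a Poisson process (candidates closer than 1 s
#' to the previous event are dropped to keep events non-overlapping). Each
#' event consists of 1--6 consecutive swim bouts; eye convergence rises
#' above the 60 degree criterion immediately after the first bout's onset
#' sample and stays high through the end of the last bout. Successful
#' events (Bernoulli `hunt_success_prob`) decrement the rotifer count at
#' event end. Observed counts are the true counts plus injected
#' single-frame dropout spikes (rate `count_noise` per frame), which the
#' 10-s rolling median filter is designed to remove. Non-hunting bouts
#' occur at `background_bout_rate_hz` with convergence below threshold.
#'
#' @param duration_s session length in seconds (default 900 = 15 min).
#' @param initial_rotifers starting prey count (>= 1).
#' @param hunt_rate_hz hunting-event arrival rate (events/s).
#' @param hunt_success_prob probability an event captures a rotifer.
#' @param max_bouts_per_event events span 1..`max_bouts_per_event` bouts.
#' @param count_noise per-frame probability of a dropout spike in the
#'   observed count trace.
#' @param background_bout_rate_hz rate of non-hunting bouts.
#' @param seed integer seed.
#' @return list with `counts`, `convergence`, `bouts` (the observed
#'   session, same shapes as [read_tracking_tables()]) and `truth` (list:
#'   `true_events` data.frame, `capture_times`, `initial_rotifers`,
#'   `true_counts` data.frame).
#' @export
simulate_prey_session <- function(duration_s = 900,
                                  initial_rotifers = 50,
                                  hunt_rate_hz = 0.05,
                                  hunt_success_prob = 0.5,
                                  max_bouts_per_event = 6L,
                                  count_noise = 0.02,
                                  background_bout_rate_hz = 0.5,
                                  seed = 1L) {
  if (!is_count(initial_rotifers) || initial_rotifers < 1) {
    zp_stop("value_error", "initial_rotifers must be an integer >= 1")
  }
  snap <- function(x) round(x / .conv_dt) * .conv_dt

  # -- hunting events ------------------------------------------------------
  set.seed(child_seed(seed, "prey_events"))
  n_cand <- stats::rpois(1L, hunt_rate_hz * duration_s)
  cand <- sort(stats::runif(n_cand, 65, duration_s - 10))
  ev_start <- numeric(0); ev_end <- numeric(0); ev_nb <- integer(0)
  ev_bouts <- list()
  prev_end <- -Inf
  for (s0 in cand) {
    if (s0 < prev_end + 1) next
    s0 <- snap(s0)
    nb <- sample.int(max_bouts_per_event, 1L)
    starts <- ends <- numeric(nb)
    cur <- s0
    for (b in seq_len(nb)) {
      dur <- snap(stats::runif(1L, 0.2, 0.4))
      starts[b] <- cur; ends[b] <- cur + dur
      cur <- cur + dur + snap(stats::runif(1L, 0.12, 0.24))
    }
    if (ends[nb] > duration_s - 1) next
    ev_start <- c(ev_start, s0); ev_end <- c(ev_end, ends[nb])
    ev_nb <- c(ev_nb, nb)
    ev_bouts[[length(ev_bouts) + 1L]] <- cbind(starts, ends)
    prev_end <- ends[nb]
  }
  n_ev <- length(ev_start)
  success <- if (n_ev > 0) stats::runif(n_ev) < hunt_success_prob else logical(0)

  # -- background (non-hunting) bouts -------------------------------------
  set.seed(child_seed(seed, "prey_background"))
  n_bg <- stats::rpois(1L, background_bout_rate_hz * duration_s)
  bg_start <- snap(sort(stats::runif(n_bg, 0, duration_s - 1)))
  bg_dur <- snap(stats::runif(n_bg, 0.2, 0.4))
  keep <- rep(TRUE, n_bg)
  for (j in seq_len(n_bg)) {
    if (n_ev > 0 && any(bg_start[j] < ev_end + 0.3 & bg_start[j] + bg_dur[j] > ev_start - 0.3)) {
      keep[j] <- FALSE
    }
    if (j > 1 && keep[j] && any(keep[seq_len(j - 1L)] &
                                bg_start[seq_len(j - 1L)] + bg_dur[seq_len(j - 1L)] > bg_start[j])) {
      keep[j] <- FALSE
    }
  }
  bg <- cbind(bg_start[keep], bg_start[keep] + bg_dur[keep])

  all_bouts <- rbind(do.call(rbind, ev_bouts), bg)
  bouts <- if (is.null(all_bouts) || nrow(all_bouts) == 0) {
    bout_intervals()
  } else {
    bout_intervals(all_bouts[, 1], all_bouts[, 2])
  }

  # -- convergence trace ---------------------------------------------------
  set.seed(child_seed(seed, "prey_convergence"))
  t_conv <- seq(0, duration_s, by = .conv_dt)
  conv <- pmin(35 + stats::rnorm(length(t_conv), 0, 3), 55)
  for (e in seq_len(n_ev)) {
    hi <- t_conv > ev_start[e] + 1e-9 & t_conv <= ev_end[e] + 1e-9
    conv[hi] <- pmax(75 + stats::rnorm(sum(hi), 0, 3), 65)
  }

  # -- rotifer counts ------------------------------------------------------
  set.seed(child_seed(seed, "prey_counts"))
  capture_times <- sort(ev_end[success])
  t_count <- seq(0, duration_s, by = .count_dt)
  true_counts <- initial_rotifers -
    pmin(findInterval(t_count, capture_times), initial_rotifers)
  observed <- true_counts
  spikes <- stats::runif(length(t_count)) < count_noise
  observed[spikes] <- pmax(observed[spikes] -
                             sample(1:3, sum(spikes), replace = TRUE), 0)

  list(
    counts = data.frame(t = t_count, count = as.integer(observed)),
    convergence = data.frame(t = t_conv, convergence_deg = conv),
    bouts = bouts,
    truth = list(
      true_events = data.frame(start_s = ev_start, end_s = ev_end,
                               n_bouts = ev_nb,
                               duration_s = ev_end - ev_start,
                               success = success),
      capture_times = capture_times,
      initial_rotifers = initial_rotifers,
      true_counts = data.frame(t = t_count, count = as.integer(true_counts))
    )
  )
}

#' Single synthetic tail-bout waveform (unit amplitude)
#'
#' Oscillation at `tailbeat_hz` under an envelope with a fast sine-squared
#' onset ramp (10 ms) and an exponential decay over the final third of the
#' bout, mimicking the rapid recruitment and passive damping of larval
#' tail bouts.
#' @noRd
tail_bout_waveform <- function(n, frame_rate, tailbeat_hz) {
  t <- (seq_len(n) - 1L) / frame_rate
  dur <- n / frame_rate
  env <- rep(1, n)
  ramp_n <- max(1L, round(0.010 * frame_rate))
  env[seq_len(min(ramp_n, n))] <- sin(pi / 2 * seq_len(min(ramp_n, n)) / ramp_n)^2
  decay_from <- 2 / 3 * dur
  tail_idx <- t > decay_from
  env[tail_idx] <- env[tail_idx] * exp(-(t[tail_idx] - decay_from) / (dur / 9))
  env * sin(2 * pi * tailbeat_hz * t)
}

#' Simulate a tail-angle trace with ground-truth bout intervals
#'
#' Bouts are oscillatory tail-angle deflections of the stated amplitude and
#' duration (see the envelope description in the package vignette) on a
#' Gaussian baseline noise floor. The ground truth records each bout's
#' interval and its RMS angular velocity (the package's vigor measure),
#' computed from the noiseless waveform.
#'
#' @param duration_s recording length in seconds.
#' @param bout_rate_hz bout arrival rate (overlapping arrivals are dropped).
#' @param bout_amp_deg peak tail deflection in degrees.
#' @param bout_dur_ms bout duration in milliseconds.
#' @param noise_sd_deg baseline angle noise SD in degrees.
#' @param frame_rate frames per second (default 700).
#' @param tailbeat_hz tail-beat oscillation frequency (default 25).
#' @param seed integer seed.
#' @return list with `t`, `angle_deg`, `frame_rate` and `truth` (data.frame
#'   `start_s`, `end_s`, `vigor` in deg/s).
#' @export
simulate_tail_trace <- function(duration_s = 60,
                                bout_rate_hz = 0.5,
                                bout_amp_deg = 30,
                                bout_dur_ms = 200,
                                noise_sd_deg = 0.5,
                                frame_rate = 700,
                                tailbeat_hz = 25,
                                seed = 1L) {
  if (frame_rate <= 0) zp_stop("value_error", "frame_rate must be > 0")
  set.seed(child_seed(seed, "tail"))
  n <- round(duration_s * frame_rate)
  t <- (seq_len(n) - 1L) / frame_rate
  clean <- numeric(n)
  dur_s <- bout_dur_ms / 1000
  n_bout_frames <- round(dur_s * frame_rate)
  n_cand <- stats::rpois(1L, bout_rate_hz * duration_s)
  cand <- sort(stats::runif(n_cand, 0, duration_s - dur_s))
  starts <- numeric(0)
  prev_end <- -Inf
  for (s0 in cand) {
    if (s0 < prev_end + 0.1) next
    starts <- c(starts, s0)
    prev_end <- s0 + dur_s
  }
  truth <- data.frame(start_s = numeric(0), end_s = numeric(0), vigor = numeric(0))
  if (length(starts) > 0) {
    wf <- tail_bout_waveform(n_bout_frames, frame_rate, tailbeat_hz)
    dwf <- diff(c(0, wf, 0)) * frame_rate  # deg/s per unit amplitude
    vig_unit <- sqrt(mean(dwf[seq_len(n_bout_frames)]^2))
    for (s0 in starts) {
      i0 <- round(s0 * frame_rate) + 1L
      i1 <- min(i0 + n_bout_frames - 1L, n)
      clean[i0:i1] <- clean[i0:i1] + bout_amp_deg * wf[seq_len(i1 - i0 + 1L)]
    }
    truth <- data.frame(start_s = (round(starts * frame_rate)) / frame_rate,
                        end_s = (round(starts * frame_rate) + n_bout_frames) / frame_rate,
                        vigor = bout_amp_deg * vig_unit)
  }
  angle <- clean + stats::rnorm(n, 0, noise_sd_deg)
  list(t = t, angle_deg = angle, frame_rate = frame_rate, truth = truth)
}

#' Construct an OCR trace
#'
#' Oxygen-consumption series at a 5-minute cadence with the two injection
#' marks: `fccp_index` is the first measurement after the FCCP
#' (uncoupler) injection, `raa_index` the first after rotenone +
#' antimycin A.
#'
#' @param t_min measurement times in minutes.
#' @param ocr oxygen consumption values (any consistent positive unit).
#' @param fccp_index,raa_index 1-based injection indices with
#'   `0 < fccp_index < raa_index <= length(ocr)`; at least 3 points before
#'   FCCP, at least 1 between the injections, at least 2 after R+AA.
#' @return object of class `ocr_trace`.
#' @export
ocr_trace <- function(t_min, ocr, fccp_index, raa_index) {
  n <- length(ocr)
  if (length(t_min) != n) zp_stop("value_error", "t_min and ocr lengths differ")
  if (!(fccp_index > 1 && raa_index > fccp_index && raa_index <= n)) {
    zp_stop("format_error", "injection indices must satisfy 1 < fccp_index < raa_index <= n")
  }
  if (fccp_index - 1L < 3L) {
    zp_stop("format_error", "pre-FCCP phase needs >= 3 points, got %d", fccp_index - 1L)
  }
  if (raa_index - fccp_index < 1L) {
    zp_stop("format_error", "FCCP phase needs >= 1 point")
  }
  if (n - raa_index + 1L < 2L) {
    zp_stop("format_error", "post-R+AA phase needs >= 2 points, got %d", n - raa_index + 1L)
  }
  structure(list(t_min = as.numeric(t_min), ocr = as.numeric(ocr),
                 fccp_index = as.integer(fccp_index),
                 raa_index = as.integer(raa_index)),
            class = "ocr_trace")
}

#' @export
print.ocr_trace <- function(x, ...) {
  cat(sprintf("<ocr_trace>: %d points, FCCP after point %d, R+AA after point %d\n",
              length(x$ocr), x$fccp_index - 1L, x$raa_index - 1L))
  invisible(x)
}

#' Simulate a three-plateau OCR trace
#'
#' Pre-FCCP plateau at `basal_true + nonmito_true`; post-FCCP phase ramps
#' up and peaks at exactly `max_true + nonmito_true`; post-R+AA plateau at
#' `nonmito_true`. Additive Gaussian noise on every point. With zero
#' noise, [summarize_ocr()] recovers the three generator values exactly.
#'
#' @param basal_true,max_true,nonmito_true plateau parameters with
#'   `max_true >= basal_true >= nonmito_true >= 0`.
#' @param n_points_per_phase points per phase (scalar or length 3;
#'   minimum 3, 1, 2).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return an [ocr_trace()].
#' @export
simulate_ocr <- function(basal_true = 50, max_true = 120, nonmito_true = 10,
                         n_points_per_phase = 5L, noise_sd = 0, seed = 1L) {
  if (!(max_true >= basal_true && basal_true >= nonmito_true && nonmito_true >= 0)) {
    zp_stop("value_error",
            "need max_true >= basal_true >= nonmito_true >= 0 (got %g, %g, %g)",
            max_true, basal_true, nonmito_true)
  }
  np <- if (length(n_points_per_phase) == 1L) rep(n_points_per_phase, 3L) else n_points_per_phase
  stopifnot(length(np) == 3L, np[1] >= 3, np[2] >= 1, np[3] >= 2)
  set.seed(child_seed(seed, "ocr"))
  p1 <- rep(basal_true + nonmito_true, np[1])
  p2 <- seq(basal_true + nonmito_true, max_true + nonmito_true,
            length.out = np[2] + 1L)[-1L]
  p3 <- rep(nonmito_true, np[3])
  ocr <- c(p1, p2, p3) + stats::rnorm(sum(np), 0, noise_sd)
  ocr_trace(t_min = 5 * (seq_len(sum(np)) - 1L), ocr = ocr,
            fccp_index = np[1] + 1L, raa_index = np[1] + np[2] + 1L)
}

#' Simulate survival records on a twice-daily observation grid
#'
#' Event times are exponential with each group's hazard; deaths are
#' recorded at the next twice-daily check (ceiling to a 0.5-day grid) and
#' administratively censored at `censor_time`.
#'
#' @param group_hazards named numeric vector of per-day hazards (> 0,
#'   arbitrarily small allowed).
#' @param n_per_group subjects per group (scalar or one per group).
#' @param censor_time administrative censoring time in days.
#' @param grid_interval observation-grid spacing in days (default 0.5 =
#'   twice daily); 0 records the exact event times. The grid makes
#'   log-rank tests on the output slightly conservative; use 0 when
#'   calibrating the testing machinery itself.
#' @param seed integer seed.
#' @return data.frame `subject`, `group`, `time`, `event`.
#' @export
simulate_survival <- function(group_hazards, n_per_group, censor_time = 9,
                              grid_interval = 0.5, seed = 1L) {
  stopifnot(!is.null(names(group_hazards)), all(group_hazards > 0),
            grid_interval >= 0)
  k <- length(group_hazards)
  n <- if (length(n_per_group) == 1L) rep(n_per_group, k) else n_per_group
  stopifnot(length(n) == k)
  set.seed(child_seed(seed, "survival"))
  rows <- lapply(seq_len(k), function(g) {
    tt <- stats::rexp(n[g], group_hazards[g])
    obs <- if (grid_interval > 0) {
      ceiling(tt / grid_interval) * grid_interval  # next scheduled check
    } else {
      tt
    }
    event <- as.integer(obs <= censor_time)
    obs[event == 0L] <- censor_time
    data.frame(subject = sprintf("%s_%03d", names(group_hazards)[g], seq_len(n[g])),
               group = names(group_hazards)[g], time = obs, event = event)
  })
  do.call(rbind, rows)
}
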