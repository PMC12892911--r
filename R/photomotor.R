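# Light-flash response (LFR) metrics from actinteg traces.
#
# Simple protocol: after 5 min of dark acclimatization a 10-s light flash
# is delivered; the response is scored within the first 4 s of light (the
# larvae subsequently freeze, with movements near zero). Extended
# protocol: a 10-min dark window quantifies spontaneous activity, then 8
# cycles of (1 s light + 29 s dark) feed stimulus-triggered averages V1
# (first 2 s after each flash) and V2 (the following 28 s).

#' Count movement events in an actinteg vector
#'
#' An event is a maximal run of consecutive slices with actinteg at or
#' above `threshold`; runs separated by at most `merge_gap_slices`
#' sub-threshold slices are merged into one event.
#'
#' @param values numeric actinteg vector.
#' @param threshold positive event threshold (actinteg units).
#' @param merge_gap_slices non-negative integer merge gap.
#' @return integer event count.
#' @export
detect_events <- function(values, threshold, merge_gap_slices = 0L) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    zp_stop("value_error", "threshold must be a positive number")
  }
  above <- values >= threshold
  if (!any(above)) return(0L)
  r <- rle(above)
  if (merge_gap_slices > 0) {
    # sub-threshold runs short enough to merge become part of an event,
    # unless they sit at either edge of the trace
    inner <- seq_along(r$values)[-c(1L, length(r$values))]
    mergeable <- !r$values & r$lengths <= merge_gap_slices
    mergeable[c(1L, length(r$values))] <- FALSE
    r$values[mergeable] <- TRUE
    r <- rle(inverse.rle(r))
  }
  sum(r$values)
}

#' Default event threshold for a trace
#'
#' The movement-detection threshold is an analysis parameter, not a rig
#' constant. The documented default is 3 x the median of the nonzero
#' slice values recorded during the dark epochs of the protocol; `NULL`
#' is returned for an all-zero dark period (no data-driven threshold).
#'
#' @param trace an [activity_trace()].
#' @return numeric threshold or `NULL`.
#' @export
default_event_threshold <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  proto <- trace$protocol
  on_s <- epoch_onsets_s(proto)
  dark <- which(proto$epochs$kind == "dark")
  idx <- unlist(lapply(dark, function(e) {
    s0 <- seconds_to_slices(on_s[e]) + 1L
    s1 <- seconds_to_slices(on_s[e] + proto$epochs$duration_s[e])
    s0:s1
  }))
  v <- trace$values[idx]
  v <- v[v > 0]
  if (length(v) == 0) return(NULL)
  3 * stats::median(v)
}

#' Simple-protocol light-flash-response metrics
#'
#' Analyzes exactly the first 4 s (60 slices) of the light epoch:
#' `max_activity` is the maximum slice value in the window and `n_events`
#' the number of threshold events ([detect_events()]).
#'
#' @param trace an [activity_trace()] recorded under the simple protocol.
#' @param threshold event threshold; `NULL` uses
#'   [default_event_threshold()] (error if that is undefined).
#' @param merge_gap_slices passed to [detect_events()].
#' @return list `max_activity`, `n_events`, `window_s` (= 4), `threshold`.
#' @export
lfr_simple <- function(trace, threshold = NULL, merge_gap_slices = 0L) {
  stopifnot(inherits(trace, "activity_trace"))
  proto <- trace$protocol
  if (proto$name != "simple") {
    zp_stop("protocol_mismatch_error",
            "lfr_simple needs the simple protocol, got '%s'", proto$name)
  }
  if (is.null(threshold)) {
    threshold <- default_event_threshold(trace)
    if (is.null(threshold)) {
      zp_stop("value_error",
              "well %s: no nonzero dark activity to set a default threshold; pass `threshold`",
              trace$well_id)
    }
  }
  light_on <- flash_onsets(proto)[1L]
  s0 <- seconds_to_slices(light_on) + 1L
  window <- trace$values[s0:(s0 + 60L - 1L)]  # 4 s x 15 slices/s
  list(max_activity = max(window),
       n_events = detect_events(window, threshold, merge_gap_slices),
       window_s = 4,
       threshold = threshold)
}

#' Stimulus-triggered averages V1 and V2 over the 8-flash protocol
#'
#' For each flash onset, the per-flash V1 is the mean actinteg per second
#' over `[onset, onset + 2 s)` (light-on slices included) and the
#' per-flash V2 over `[onset + 2 s, onset + 30 s)`. `v1`/`v2` are the
#' unweighted means across flashes. Activity-per-second equals 15 x the
#' mean slice value.
#'
#' @param trace an [activity_trace()] under the extended protocol.
#' @param onsets flash onsets in seconds; defaults to the protocol's light
#'   epochs.
#' @return list `v1`, `v2` (actinteg/s) and `per_flash` (n x 2 matrix of
#'   per-flash values, columns `v1`, `v2`).
#' @export
triggered_average <- function(trace, onsets = NULL) {
  stopifnot(inherits(trace, "activity_trace"))
  proto <- trace$protocol
  if (is.null(onsets)) onsets <- flash_onsets(proto)
  if (length(onsets) == 0) zp_stop("value_error", "no flash onsets")
  n <- length(trace$values)
  per_flash <- t(vapply(onsets, function(o) {
    s0 <- seconds_to_slices(o) + 1L
    s_mid <- s0 + 30L   # + 2 s
    s_end <- s0 + 450L  # + 30 s
    if (s_end - 1L > n) {
      zp_stop("value_error",
              "flash at %g s: the 30-s window extends past the trace end", o)
    }
    c(v1 = mean(trace$values[s0:(s_mid - 1L)]) * 15,
      v2 = mean(trace$values[s_mid:(s_end - 1L)]) * 15)
  }, c(v1 = 0, v2 = 0)))
  list(v1 = mean(per_flash[, "v1"]), v2 = mean(per_flash[, "v2"]),
       per_flash = per_flash)
}

#' Spontaneous activity over the 10-minute dark window
#'
#' Mean actinteg per second across the designated 600-s spontaneous window
#' of the extended protocol (the first 300-s dark adaptation is excluded).
#'
#' @param trace an [activity_trace()] under the extended protocol.
#' @return mean actinteg per second (numeric scalar).
#' @export
spontaneous_activity <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  proto <- trace$protocol
  if (proto$name != "extended") {
    zp_stop("protocol_mismatch_error",
            "spontaneous_activity needs the extended protocol, got '%s'",
            proto$name)
  }
  s0 <- seconds_to_slices(300) + 1L
  s1 <- seconds_to_slices(900)
  mean(trace$values[s0:s1]) * 15
}

#' Per-well LFR metrics table for a plate of traces
#'
#' Applies [lfr_simple()] (simple protocol) or [triggered_average()] plus
#' [spontaneous_activity()] (extended protocol) to every trace.
#'
#' @param traces named list of [activity_trace()].
#' @param threshold event threshold for the simple-protocol metrics.
#' @param group_label group annotation recycled across wells.
#' @return a [tidy_result_table()].
#' @export
lfr_table <- function(traces, threshold = NULL, group_label = "all") {
  stopifnot(length(traces) > 0)
  proto_name <- traces[[1L]]$protocol$name
  rows <- lapply(traces, function(tr) {
    if (proto_name == "simple") {
      m <- lfr_simple(tr, threshold = threshold)
      tidy_result_table(tr$well_id, group_label,
                        c("max_activity", "n_events"),
                        c(m$max_activity, m$n_events),
                        c("actinteg", "count"))
    } else {
      ta <- triggered_average(tr)
      sa <- spontaneous_activity(tr)
      tidy_result_table(tr$well_id, group_label,
                        c("v1", "v2", "spontaneous_activity"),
                        c(ta$v1, ta$v2, sa),
                        "actinteg/s")
    }
  })
  do.call(rbind, rows)
}
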