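# Stimulus protocols for the activity-camera assays.
#
# Two named light/dark schedules are used throughout:
#   simple   — 5 min dark acclimatization, then 10 s light; the light-flash
#              response is scored in the first 4 s of the light epoch.
#   extended — 5 min dark adaptation, 10 min dark spontaneous-activity
#              window, then 8 cycles of (1 s light + 29 s dark) for
#              stimulus-triggered averaging.

#' Build a stimulus protocol from epochs
#'
#' @param epochs data.frame with columns `kind` (`"dark"` or `"light"`) and
#'   `duration_s` (whole protocol durations must map to an integer number of
#'   1/15-s slices).
#' @param name protocol name.
#' @return object of class `stimulus_protocol`.
#' @seealso [lfr_protocol()] for the two named schedules.
#' @export
stimulus_protocol <- function(epochs, name = "custom") {
  stopifnot(is.data.frame(epochs), all(c("kind", "duration_s") %in% names(epochs)))
  if (!all(epochs$kind %in% c("dark", "light"))) {
    zp_stop("value_error", "epoch kind must be 'dark' or 'light'")
  }
  if (!all(is.finite(epochs$duration_s)) || any(epochs$duration_s <= 0)) {
    zp_stop("value_error", "epoch durations must be positive and finite")
  }
  seconds_to_slices(epochs$duration_s)  # must be exact
  structure(
    list(name = name,
         epochs = data.frame(kind = as.character(epochs$kind),
                             duration_s = as.numeric(epochs$duration_s),
                             stringsAsFactors = FALSE)),
    class = "stimulus_protocol"
  )
}

#' The two named light-flash-response protocols
#'
#' `"simple"` is 300 s dark + 10 s light. `"extended"` is 300 s dark
#' adaptation + 600 s dark spontaneous window + 8 cycles alternating 1 s of
#' light and 29 s of dark.
#'
#' @param name `"simple"` or `"extended"`.
#' @return a [stimulus_protocol()].
#' @export
lfr_protocol <- function(name = c("simple", "extended")) {
  name <- match.arg(name)
  epochs <- if (name == "simple") {
    data.frame(kind = c("dark", "light"), duration_s = c(300, 10))
  } else {
    data.frame(
      kind = c("dark", "dark", rep(c("light", "dark"), 8L)),
      duration_s = c(300, 600, rep(c(1, 29), 8L))
    )
  }
  stimulus_protocol(epochs, name = name)
}

#' Total protocol duration in seconds
#' @param protocol a [stimulus_protocol()].
#' @return numeric seconds.
#' @export
protocol_duration_s <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  sum(protocol$epochs$duration_s)
}

#' Total protocol duration in 1/15-s slices
#' @param protocol a [stimulus_protocol()].
#' @return integer slice count.
#' @export
protocol_duration_slices <- function(protocol) {
  seconds_to_slices(protocol_duration_s(protocol))
}

#' Epoch start times in seconds
#' @param protocol a [stimulus_protocol()].
#' @return numeric vector, one start per epoch (first epoch starts at 0).
#' @export
epoch_onsets_s <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  cumsum(c(0, protocol$epochs$duration_s))[seq_len(nrow(protocol$epochs))]
}

#' Light-flash onset times of a protocol
#'
#' Onsets of every light epoch, in seconds from protocol start. For the
#' extended protocol these are the 8 flash onsets at 900, 930, ..., 1110 s.
#'
#' @param protocol a [stimulus_protocol()].
#' @return numeric vector of onset times in seconds.
#' @export
flash_onsets <- function(protocol) {
  on <- epoch_onsets_s(protocol)
  on[protocol$epochs$kind == "light"]
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol '%s'>: %d epochs, %g s total (%d slices)\n",
              x$name, nrow(x$epochs), protocol_duration_s(x),
              protocol_duration_slices(x)))
  n_light <- sum(x$epochs$kind == "light")
  if (n_light > 0) {
    cat(sprintf("  light epochs at: %s s\n",
                paste(flash_onsets(x), collapse = ", ")))
  }
  invisible(x)
}
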