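# Run configuration: shared experiment parameters and a flat key=value
# config file format.

#' Create a run configuration
#'
#' Holds the parameters shared across pipeline stages. The activity-camera
#' slice duration is fixed at exactly 1/15 s and stored as a rational
#' (numerator/denominator), never as a rounded float, so second-to-slice
#' conversion stays exact over thousands of slices.
#'
#' @param sampling_rate_behavior frames per second of the kinematics rig
#'   (tail/eye traces). Default 700.
#' @param rng_seed integer seed propagated to stochastic stages.
#' @param output_dir directory where the command-line driver writes results.
#' @param verbosity one of `"quiet"`, `"info"`, `"debug"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sampling_rate_behavior = 700,
                       rng_seed = 1L,
                       output_dir = ".",
                       verbosity = c("info", "quiet", "debug")) {
  verbosity <- match.arg(verbosity)
  if (!is.numeric(sampling_rate_behavior) || length(sampling_rate_behavior) != 1L ||
      !is.finite(sampling_rate_behavior) || sampling_rate_behavior <= 0) {
    zp_stop("value_error", "sampling_rate_behavior must be a positive number")
  }
  structure(
    list(
      sampling_rate_behavior = as.numeric(sampling_rate_behavior),
      slice_duration_lfr = c(numerator = 1L, denominator = 15L),
      rng_seed = as.integer(rng_seed),
      output_dir = output_dir,
      verbosity = verbosity
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  kinematics sampling rate : %g frames/s\n", x$sampling_rate_behavior))
  cat(sprintf("  activity slice duration  : %d/%d s\n",
              x$slice_duration_lfr[["numerator"]],
              x$slice_duration_lfr[["denominator"]]))
  cat(sprintf("  rng seed                 : %d\n", x$rng_seed))
  cat(sprintf("  output dir               : %s\n", x$output_dir))
  cat(sprintf("  verbosity                : %s\n", x$verbosity))
  invisible(x)
}

#' Convert whole seconds to activity slices exactly
#'
#' Uses the exact rational slice duration (1/15 s): `s` seconds correspond
#' to `s * 15` slices, which must be an integer.
#'
#' @param s duration in seconds.
#' @return integer number of slices.
#' @export
seconds_to_slices <- function(s) {
  n <- s * 15
  if (any(abs(n - round(n)) > 1e-9)) {
    zp_stop("value_error",
            "duration %g s is not an integer number of 1/15-s slices", s[1])
  }
  as.integer(round(n))
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers are returned numeric, everything else as character.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) zp_stop("format_error", "config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      zp_stop("format_error", "config line %d is not 'key = value': %s", i, lines[i])
    }
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key=value configuration file
#' @param config named list.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config_file <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, format(config[[k]], digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
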