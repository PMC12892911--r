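# Readers and writers for all tabular formats.
#
# One canonical CSV dialect everywhere: comma-separated, UTF-8, header row
# required, '.' decimal separator, no thousands separators. Readers reject
# malformed input with row/column provenance; they never repair it.

read_csv_strict <- function(path, required_cols) {
  if (!file.exists(path)) zp_stop("format_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    zp_stop("format_error", "%s: missing required column(s): %s",
            path, paste(missing, collapse = ", "))
  }
  df
}

#' Construct an activity trace
#'
#' A per-well activity time series at fixed 1/15-s slices; each value is the
#' camera's summed pixel change during that slice ("actinteg" units).
#'
#' @param well_id well identifier.
#' @param values non-negative numeric vector, one value per slice.
#' @param protocol the [stimulus_protocol()] the trace was recorded under.
#' @return object of class `activity_trace`.
#' @export
activity_trace <- function(well_id, values, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (any(!is.finite(values)) || any(values < 0)) {
    zp_stop("value_error", "well %s: actinteg values must be finite and >= 0",
            well_id)
  }
  n_expected <- protocol_duration_slices(protocol)
  if (length(values) != n_expected) {
    zp_stop("protocol_mismatch_error",
            "well %s: trace has %d slices but protocol '%s' spans %d",
            well_id, length(values), protocol$name, n_expected)
  }
  structure(list(well_id = as.character(well_id),
                 values = as.numeric(values),
                 protocol = protocol),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace well %s>: %d slices (%g s), protocol '%s', max %g\n",
              x$well_id, length(x$values), length(x$values) / 15,
              x$protocol$name, max(x$values)))
  invisible(x)
}

#' Read a long-format activity CSV
#'
#' Expected header `well,slice_index,actinteg` with 0-based, contiguous
#' `slice_index` per well. Gaps are an error, never silently filled; the
#' trace length must equal the protocol duration in slices.
#'
#' @param path CSV path.
#' @param protocol the [stimulus_protocol()] the plate was recorded under.
#' @return named list of [activity_trace()] objects, one per well, in order
#'   of first appearance.
#' @export
read_activity_csv <- function(path, protocol) {
  df <- read_csv_strict(path, c("well", "slice_index", "actinteg"))
  if (!is.numeric(df$actinteg)) {
    zp_stop("format_error", "%s: actinteg column is not numeric", path)
  }
  bad <- which(!is.finite(df$actinteg) | df$actinteg < 0)
  if (length(bad) > 0) {
    zp_stop("value_error", "%s: negative or non-finite actinteg at row %d",
            path, bad[1L] + 1L)  # +1 for the header line
  }
  wells <- unique(df$well)
  traces <- lapply(wells, function(w) {
    sub <- df[df$well == w, , drop = FALSE]
    idx <- sub$slice_index
    expect <- seq(0L, length.out = nrow(sub))
    if (!identical(as.integer(idx), as.integer(expect))) {
      jump <- which(idx != expect)[1L]
      zp_stop("gap_error",
              "%s: well %s has non-contiguous slice_index near index %d (got %d, expected %d)",
              path, w, idx[jump], idx[jump], expect[jump])
    }
    activity_trace(w, sub$actinteg, protocol)
  })
  names(traces) <- wells
  traces
}

#' Write activity traces to long-format CSV
#' @param traces list of [activity_trace()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(well = tr$well_id,
               slice_index = seq_along(tr$values) - 1L,
               actinteg = tr$values)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate and construct bout intervals
#'
#' Half-open `[start, end)` intervals in seconds, sorted and non-overlapping.
#'
#' @param start_s,end_s numeric vectors of equal length.
#' @return data.frame of class `bout_intervals` with columns `start_s`, `end_s`.
#' @export
bout_intervals <- function(start_s = numeric(), end_s = numeric()) {
  stopifnot(length(start_s) == length(end_s))
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s))
  if (nrow(df) > 0) {
    if (any(df$end_s <= df$start_s)) {
      zp_stop("validation_error", "bout intervals must satisfy start < end")
    }
    df <- df[order(df$start_s), , drop = FALSE]
    rownames(df) <- NULL
    if (nrow(df) > 1 && any(df$start_s[-1L] < df$end_s[-nrow(df)])) {
      i <- which(df$start_s[-1L] < df$end_s[-nrow(df)])[1L]
      zp_stop("validation_error",
              "overlapping bouts: [%g, %g) and [%g, %g)",
              df$start_s[i], df$end_s[i], df$start_s[i + 1L], df$end_s[i + 1L])
    }
  }
  class(df) <- c("bout_intervals", "data.frame")
  df
}

#' Read prey-capture tracking tables
#'
#' Three CSV files: rotifer counts (`t,count`), eye convergence
#' (`t,convergence_deg`), and swim-bout intervals (`bout_start,bout_end`).
#' Times are seconds; count/convergence timestamps must be strictly
#' increasing and bouts non-overlapping.
#'
#' @param counts_path,convergence_path,bouts_path file paths.
#' @return list with elements `counts` (data.frame `t`, `count`),
#'   `convergence` (data.frame `t`, `convergence_deg`) and `bouts`
#'   ([bout_intervals()]).
#' @export
read_tracking_tables <- function(counts_path, convergence_path, bouts_path) {
  counts <- read_csv_strict(counts_path, c("t", "count"))
  conv <- read_csv_strict(convergence_path, c("t", "convergence_deg"))
  for (nm in list(list(counts, counts_path), list(conv, convergence_path))) {
    tt <- nm[[1]]$t
    if (any(diff(tt) <= 0)) {
      zp_stop("validation_error", "%s: time column is not strictly increasing near row %d",
              nm[[2]], which(diff(tt) <= 0)[1L] + 1L)
    }
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    zp_stop("value_error", "%s: counts must be non-negative integers", counts_path)
  }
  if (any(!is.finite(conv$convergence_deg))) {
    zp_stop("value_error", "%s: convergence must be finite", convergence_path)
  }
  bouts_df <- read_csv_strict(bouts_path, c("bout_start", "bout_end"))
  list(counts = counts,
       convergence = conv,
       bouts = bout_intervals(bouts_df$bout_start, bouts_df$bout_end))
}

#' Write prey-capture tracking tables
#' @param session list as returned by [read_tracking_tables()] or
#'   [simulate_prey_session()] (elements `counts`, `convergence`, `bouts`).
#' @param counts_path,convergence_path,bouts_path output paths.
#' @return invisibly, the three paths.
#' @export
write_tracking_tables <- function(session, counts_path, convergence_path,
                                  bouts_path) {
  utils::write.csv(session$counts[, c("t", "count")], counts_path,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(session$convergence[, c("t", "convergence_deg")],
                   convergence_path, row.names = FALSE, quote = FALSE)
  b <- data.frame(bout_start = session$bouts$start_s,
                  bout_end = session$bouts$end_s)
  utils::write.csv(b, bouts_path, row.names = FALSE, quote = FALSE)
  invisible(c(counts_path, convergence_path, bouts_path))
}

#' Read a plate fluorescence CSV
#'
#' Header `well,fluorescence` with an optional `true_genotype` column
#' (values `wt`, `het`, `hom`).
#'
#' @param path CSV path.
#' @return a `plate_fluorescence` data.frame.
#' @export
read_plate_csv <- function(path) {
  df <- read_csv_strict(path, c("well", "fluorescence"))
  plate_fluorescence(df$well, df$fluorescence,
                     if ("true_genotype" %in% names(df)) df$true_genotype else NULL)
}

#' Construct a plate fluorescence table
#' @param well well identifiers (unique).
#' @param fluorescence finite numeric values.
#' @param true_genotype optional character vector in `{wt, het, hom}`
#'   (NA allowed).
#' @return data.frame of class `plate_fluorescence`.
#' @export
plate_fluorescence <- function(well, fluorescence, true_genotype = NULL) {
  well <- as.character(well)
  if (anyDuplicated(well)) {
    zp_stop("validation_error", "duplicate well id: %s", well[duplicated(well)][1L])
  }
  if (any(!is.finite(fluorescence))) {
    zp_stop("value_error", "fluorescence must be finite for every well")
  }
  df <- data.frame(well = well, fluorescence = as.numeric(fluorescence),
                   stringsAsFactors = FALSE)
  if (!is.null(true_genotype)) {
    g <- as.character(true_genotype)
    if (!all(g %in% c("wt", "het", "hom") | is.na(g))) {
      zp_stop("value_error", "true_genotype must be one of wt, het, hom")
    }
    df$true_genotype <- g
  }
  class(df) <- c("plate_fluorescence", "data.frame")
  df
}

#' Write a plate fluorescence CSV
#' @param plate a [plate_fluorescence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(as.data.frame(plate), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an oxygen-consumption-rate CSV with injection annotations
#'
#' Measurement table `well,t_min,ocr` plus a flat key=value injection config
#' holding `fccp_index` and `raa_index` (1-based index of the first
#' measurement after each injection, shared by all wells of the plate).
#'
#' @param path measurement CSV path.
#' @param injection_config_path config path (see [read_config_file()]).
#' @return named list of [ocr_trace()] objects, one per well.
#' @export
read_ocr_csv <- function(path, injection_config_path) {
  df <- read_csv_strict(path, c("well", "t_min", "ocr"))
  cfg <- read_config_file(injection_config_path)
  if (is.null(cfg$fccp_index) || is.null(cfg$raa_index)) {
    zp_stop("format_error", "%s: injection config needs fccp_index and raa_index",
            injection_config_path)
  }
  wells <- unique(df$well)
  out <- lapply(wells, function(w) {
    sub <- df[df$well == w, , drop = FALSE]
    ocr_trace(sub$t_min, sub$ocr, as.integer(cfg$fccp_index),
              as.integer(cfg$raa_index))
  })
  names(out) <- wells
  out
}

#' Write OCR traces and their injection config
#' @param traces named list of [ocr_trace()] (shared injection indices).
#' @param path measurement CSV path.
#' @param injection_config_path config output path.
#' @return `path`, invisibly.
#' @export
write_ocr_csv <- function(traces, path, injection_config_path) {
  rows <- lapply(names(traces), function(w) {
    tr <- traces[[w]]
    data.frame(well = w, t_min = tr$t_min, ocr = tr$ocr)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  tr1 <- traces[[1L]]
  write_config_file(list(fccp_index = tr1$fccp_index, raa_index = tr1$raa_index),
                    injection_config_path)
  invisible(path)
}

#' Read a survival records CSV
#'
#' Header `subject,group,time,event` with `event` in \{0, 1\} (1 = death or
#' terminal illness, 0 = censored) and `time >= 0`.
#'
#' @param path CSV path.
#' @return data.frame with those four columns.
#' @export
read_survival_csv <- function(path) {
  df <- read_csv_strict(path, c("subject", "group", "time", "event"))
  if (!all(df$event %in% c(0, 1))) {
    zp_stop("value_error", "%s: event must be 0 or 1 (row %d)",
            path, which(!df$event %in% c(0, 1))[1L] + 1L)
  }
  if (any(df$time < 0)) {
    zp_stop("value_error", "%s: negative survival time (row %d)",
            path, which(df$time < 0)[1L] + 1L)
  }
  df
}

#' Write a survival records CSV
#' @param records data.frame with `subject,group,time,event`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(records, path) {
  utils::write.csv(records[, c("subject", "group", "time", "event")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
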