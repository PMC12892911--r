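# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All validation failures in the package raise classed errors so callers
#' (and the command-line driver) can distinguish malformed input from
#' programming errors.
#'
#' @param class condition class suffix, e.g. "format_error".
#' @param ... passed to [sprintf()] to build the message.
#' @noRd
zp_stop <- function(class, ...) {
  msg <- sprintf(...)
  stop(structure(
    class = c(paste0("zebraphen_", class), "zebraphen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
zp_warn <- function(class, ...) {
  msg <- sprintf(...)
  warning(structure(
    class = c(paste0("zebraphen_", class), "zebraphen_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' Derive a reproducible child seed for a named sub-generator
#'
#' One user-facing seed governs a whole simulated session; each
#' sub-generator draws from its own stream derived from (seed, name) so
#' that adding a generator never perturbs another's stream. The derivation
#' is a small deterministic string hash folded into [0, 2^31 - 1).
#'
#' @param seed integer master seed.
#' @param name character stream label.
#' @return an integer usable with [set.seed()].
#' @export
#' @examples
#' child_seed(7L, "plate") != child_seed(7L, "ocr")
child_seed <- function(seed, name) {
  stopifnot(is_count(abs(seed)), is.character(name), length(name) == 1L)
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Build one row-per-subject-and-metric tidy result table
#'
#' The canonical output format of every pipeline stage: one row per
#' subject x metric, with a registered metric vocabulary.
#'
#' @param subject_id,group_label,metric_name,value,unit vectors recycled to
#'   a common length.
#' @return a `data.frame` with columns `subject_id`, `group_label`,
#'   `metric_name`, `value`, `unit`.
#' @export
tidy_result_table <- function(subject_id, group_label, metric_name, value,
                              unit = "") {
  bad <- setdiff(unique(metric_name), zp_metric_vocabulary())
  if (length(bad) > 0) {
    zp_stop("vocabulary_error", "unregistered metric name(s): %s",
            paste(bad, collapse = ", "))
  }
  out <- data.frame(
    subject_id = as.character(subject_id),
    group_label = as.character(group_label),
    metric_name = as.character(metric_name),
    value = as.numeric(value),
    unit = as.character(unit),
    stringsAsFactors = FALSE
  )
  key <- paste(out$subject_id, out$metric_name)
  if (anyDuplicated(key)) {
    zp_stop("vocabulary_error", "duplicate subject x metric row: %s",
            key[duplicated(key)][1L])
  }
  out
}

#' Registered metric vocabulary for tidy result tables
#' @return character vector of allowed `metric_name` values.
#' @export
zp_metric_vocabulary <- function() {
  c("max_activity", "n_events", "v1", "v2", "spontaneous_activity",
    "proportion_consumed_15min", "n_hunting_events", "mean_event_duration_s",
    "bout_frequency_per_min", "vigor_rms_deg_s",
    "basal_ocr", "maximal_ocr", "nonmito_ocr",
    "fluorescence", "predicted_genotype_code",
    "survival_time", "event")
}

#' Box-plot summary following the study's figure convention
#'
#' Center line at the median, box limits at the lower and upper quartiles,
#' whiskers at the most extreme observations within 1.5 x IQR of the box.
#'
#' @param x numeric vector.
#' @return named list: `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
box_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) zp_stop("value_error", "box_stats: no finite values")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- x[x >= lo & x <= hi]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(x[x < lo | x > hi]))
}
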