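# Decomposition of Seahorse-style oxygen-consumption traces into basal,
# maximal (uncoupled) and nonmitochondrial respiration.

#' Summarize an OCR trace into basal, maximal and nonmitochondrial rates
#'
#' Basal (raw) respiration is the average of the last 3 points measured
#' before the FCCP injection; maximal (raw) is the maximum value between
#' the FCCP and rotenone/antimycin-A injections; nonmitochondrial
#' respiration is the mean of the post-R+AA points (dropping the first,
#' transient, post-injection point when at least 3 are available) and is
#' deducted from both the basal and the maximal value. Negative corrected
#' values are reported, not clamped, with a QC warning (clamping would
#' hide injection failures).
#'
#' @param trace an [ocr_trace()].
#' @return list of class `ocr_summary`: `basal`, `maximal`, `nonmito`
#'   (same units as the input), plus `basal_raw`, `maximal_raw`.
#' @export
summarize_ocr <- function(trace) {
  stopifnot(inherits(trace, "ocr_trace"))
  x <- trace$ocr
  fccp <- trace$fccp_index
  raa <- trace$raa_index
  basal_raw <- mean(x[(fccp - 3L):(fccp - 1L)])
  maximal_raw <- max(x[fccp:(raa - 1L)])
  post <- x[raa:length(x)]
  nonmito <- if (length(post) >= 3L) mean(post[-1L]) else mean(post)
  basal <- basal_raw - nonmito
  maximal <- maximal_raw - nonmito
  if (basal < 0 || maximal < 0) {
    zp_warn("qc_warning",
            "negative corrected OCR (basal %.3g, maximal %.3g): check injections",
            basal, maximal)
  }
  structure(list(basal = basal, maximal = maximal, nonmito = nonmito,
                 basal_raw = basal_raw, maximal_raw = maximal_raw),
            class = "ocr_summary")
}

#' @export
print.ocr_summary <- function(x, ...) {
  cat(sprintf("<ocr_summary>: basal %.4g, maximal %.4g, nonmito %.4g\n",
              x$basal, x$maximal, x$nonmito))
  invisible(x)
}

#' Cohort table of OCR summaries with group labels
#'
#' One row per well; the rows are sorted by group then well so the table
#' content is independent of input order. Downstream group comparisons use
#' [anova_tukey()].
#'
#' @param traces_by_group named list of lists of [ocr_trace()] objects
#'   (names are group labels).
#' @return data.frame `well`, `group`, `basal`, `maximal`, `nonmito`.
#' @export
cohort_ocr_table <- function(traces_by_group) {
  stopifnot(is.list(traces_by_group), length(traces_by_group) >= 1,
            !is.null(names(traces_by_group)))
  rows <- lapply(names(traces_by_group), function(g) {
    traces <- traces_by_group[[g]]
    if (length(traces) < 1) zp_stop("value_error", "group %s has no traces", g)
    wells <- names(traces)
    if (is.null(wells)) wells <- sprintf("%s_%02d", g, seq_along(traces))
    do.call(rbind, lapply(seq_along(traces), function(i) {
      s <- summarize_ocr(traces[[i]])
      data.frame(well = wells[i], group = g, basal = s$basal,
                 maximal = s$maximal, nonmito = s$nonmito,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$well), , drop = FALSE]
  rownames(out) <- NULL
  out
}
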