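# Noninvasive quartile-based genotype sorting from plate fluorescence.
#
# Larvae from a heterozygous in-cross are incubated with a resazurin redox
# dye; homozygous mutants reduce more dye and fluoresce brighter. Wells
# strictly above the plate's 75th percentile (Q3) are sorted as predicted
# homozygous mutants, wells strictly below the 25th percentile (Q1) as
# predicted wild type; the middle is left unassigned.

#' Percentile threshold by linear interpolation of order statistics
#'
#' Isolated so the percentile convention can be swapped in one place;
#' the choice (type-7 linear interpolation, the common default in
#' scientific software) is pinned by a brute-force oracle test.
#' @noRd
plate_percentile <- function(x, p) {
  stats::quantile(x, p, names = FALSE, type = 7)
}

#' Classify a plate's wells by fluorescence quartiles
#'
#' Thresholds are the 25th (Q1) and 75th (Q3) percentiles of the plate's
#' fluorescence, computed per plate by linear interpolation of order
#' statistics. Wells strictly above Q3 are labeled `predicted_hom`, wells
#' strictly below Q1 `predicted_wt`; everything in `[Q1, Q3]` (including
#' ties exactly at a threshold) is `unassigned`.
#'
#' @param plate a [plate_fluorescence()] with at least 4 wells.
#' @return object of class `quartile_assignment`: list with
#'   `q1_threshold`, `q3_threshold` and `labels` (data.frame `well`,
#'   `label`).
#' @export
classify_plate <- function(plate) {
  stopifnot(inherits(plate, "plate_fluorescence"))
  if (nrow(plate) < 4) {
    zp_stop("insufficient_data_error",
            "quartile sorting needs >= 4 wells, got %d", nrow(plate))
  }
  q1 <- plate_percentile(plate$fluorescence, 0.25)
  q3 <- plate_percentile(plate$fluorescence, 0.75)
  label <- rep("unassigned", nrow(plate))
  label[plate$fluorescence > q3] <- "predicted_hom"
  label[plate$fluorescence < q1] <- "predicted_wt"
  structure(
    list(q1_threshold = q1, q3_threshold = q3,
         labels = data.frame(well = plate$well, label = label,
                             stringsAsFactors = FALSE)),
    class = "quartile_assignment"
  )
}

#' @export
print.quartile_assignment <- function(x, ...) {
  tab <- table(factor(x$labels$label,
                      levels = c("predicted_wt", "unassigned", "predicted_hom")))
  cat(sprintf("<quartile_assignment>: Q1 = %.4g, Q3 = %.4g\n",
              x$q1_threshold, x$q3_threshold))
  cat(sprintf("  predicted_wt %d | unassigned %d | predicted_hom %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Score a quartile assignment against true genotypes
#'
#' The false-positive rate of the selected mutant pool is the percentage
#' of `predicted_hom` wells whose true genotype is wt or het (contamination
#' of the top quartile). The false-negative rate is the percentage of true
#' homozygotes not labeled `predicted_hom`. A zero denominator yields `NA`
#' (undefined), never 0.
#'
#' @param assignment a `quartile_assignment` from [classify_plate()].
#' @param plate the same plate with `true_genotype` filled for every
#'   `predicted_hom` well.
#' @return list with `false_positive_rate_top` (%), `false_negative_rate`
#'   (%), `yield_top` (number of predicted homozygotes) and `composition`
#'   (label x genotype count table).
#' @export
confusion_metrics <- function(assignment, plate) {
  stopifnot(inherits(assignment, "quartile_assignment"),
            inherits(plate, "plate_fluorescence"))
  if (is.null(plate$true_genotype)) {
    zp_stop("value_error", "plate has no true_genotype column")
  }
  m <- merge(assignment$labels, as.data.frame(plate), by = "well")
  top <- m[m$label == "predicted_hom", , drop = FALSE]
  if (any(is.na(top$true_genotype))) {
    zp_stop("value_error", "predicted_hom well %s has no true genotype",
            top$well[is.na(top$true_genotype)][1L])
  }
  n_top <- nrow(top)
  fp <- if (n_top == 0) NA_real_ else 100 * sum(top$true_genotype != "hom") / n_top
  n_hom <- sum(m$true_genotype == "hom", na.rm = TRUE)
  fn <- if (n_hom == 0) NA_real_ else {
    100 * sum(m$true_genotype == "hom" & m$label != "predicted_hom", na.rm = TRUE) / n_hom
  }
  list(
    false_positive_rate_top = fp,
    false_negative_rate = fn,
    yield_top = n_top,
    composition = table(label = m$label,
                        genotype = factor(m$true_genotype,
                                          levels = c("wt", "het", "hom")))
  )
}

#' Monte-Carlo power curve of the quartile sorter
#'
#' Sweeps a grid of homozygote separations and spreads, simulating
#' `n_replicates` plates per cell and pooling the false-positive rate of
#' the predicted-mutant pool, with a normal-approximation 95% CI.
#'
#' @param separations vector of `mu_hom - mu_wt` offsets (wt/het mean
#'   fixed at 1).
#' @param sds vector of common fluorescence SDs applied to all genotypes.
#' @param n_wells plate size.
#' @param n_replicates plates per grid cell.
#' @param seed integer seed.
#' @return data.frame `separation`, `sd`, `n_wells`, `fp_rate` (%),
#'   `ci_lo`, `ci_hi`, `n_predicted`.
#' @export
sorting_power_curve <- function(separations = c(0, 0.4, 0.8, 1.6),
                                sds = c(0.1, 0.2),
                                n_wells = 94, n_replicates = 50, seed = 1L) {
  if (!is_count(n_replicates) || n_replicates < 1) {
    zp_stop("value_error", "n_replicates must be >= 1")
  }
  grid <- expand.grid(separation = separations, sd = sds)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sep <- grid$separation[i]; s <- grid$sd[i]
    fp_num <- 0L; fp_den <- 0L
    for (r in seq_len(n_replicates)) {
      plate <- simulate_plate(
        n_wells,
        mu_by_genotype = c(wt = 1, het = 1, hom = 1 + sep),
        sd_by_genotype = c(wt = s, het = s, hom = s),
        seed = child_seed(seed, sprintf("power_%d_%d", i, r))
      )
      cm <- confusion_metrics(classify_plate(plate), plate)
      if (cm$yield_top > 0) {
        fp_num <- fp_num + round(cm$false_positive_rate_top * cm$yield_top / 100)
        fp_den <- fp_den + cm$yield_top
      }
    }
    p <- fp_num / fp_den
    se <- sqrt(p * (1 - p) / fp_den)
    data.frame(separation = sep, sd = s, n_wells = n_wells,
               fp_rate = 100 * p,
               ci_lo = 100 * max(0, p - 1.96 * se),
               ci_hi = 100 * min(1, p + 1.96 * se),
               n_predicted = fp_den)
  })
  do.call(rbind, out)
}
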