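# Group-comparison procedures used by the phenotyping figures:
# Kruskal-Wallis with Dunn's pairwise test, one-way ANOVA with Tukey HSD,
# Fisher's exact test, and the Mann-Whitney U test. Omnibus statistics are
# delegated to the standard stats routines; Dunn's pairwise z test is
# implemented here (with midranks and tie correction) since base R does
# not provide it.

group_comparison <- function(test, statistic, p_value, pairwise, method) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 pairwise = pairwise, adjust_method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s>\n  statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$pairwise) && nrow(x$pairwise) > 0) {
    cat(sprintf("  pairwise (%s-adjusted):\n", x$adjust_method))
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

check_groups <- function(groups, min_groups = 2L, min_per_group = 1L) {
  if (!is.list(groups) || length(groups) < min_groups) {
    zp_stop("value_error", "need at least %d groups", min_groups)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < min_per_group)) {
    zp_stop("value_error", "every group needs >= %d observations", min_per_group)
  }
  groups
}

#' Tie-corrected Kruskal-Wallis H from values and integer group codes
#' @noRd
kw_h_stat <- function(x, g_int) {
  n_tot <- length(x)
  r <- rank(x)
  mean_rank <- tapply(r, g_int, mean)
  n_g <- tapply(r, g_int, length)
  h <- 12 / (n_tot * (n_tot + 1)) *
    sum(n_g * (mean_rank - (n_tot + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n_tot^3 - n_tot)
  h / corr
}

#' Exact permutation p for the H statistic (full enumeration)
#'
#' Enumerates every distinct assignment of the pooled observations to
#' groups of the observed sizes and counts assignments with H at least
#' the observed value.
#' @noRd
kw_exact_p <- function(x, sizes) {
  n_tot <- length(x)
  h_obs <- kw_h_stat(x, rep(seq_along(sizes), sizes))
  tot <- 0L; ge <- 0L
  assign <- integer(n_tot)
  recurse <- function(remaining, grp) {
    if (grp > length(sizes)) {
      tot <<- tot + 1L
      if (kw_h_stat(x, assign) >= h_obs - 1e-9) ge <<- ge + 1L
      return(invisible())
    }
    if (grp == length(sizes)) {
      assign[remaining] <<- grp
      recurse(integer(0), grp + 1L)
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[grp])
    for (j in seq_len(ncol(picks))) {
      assign[picks[, j]] <<- grp
      recurse(setdiff(remaining, picks[, j]), grp + 1L)
    }
  }
  recurse(seq_len(n_tot), 1L)
  ge / tot
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Omnibus H statistic with midrank tie correction. The omnibus p value
#' uses the chi-square approximation except for very small samples
#' (combined n at most `exact_n_max`), where the exact permutation null
#' of H is enumerated instead — the chi-square approximation is poor
#' there. Pairwise Dunn z statistics on the pooled midranks with the same
#' tie correction, adjusted for multiple comparisons (Bonferroni by
#' default, the study's stated adjustment).
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param adjust p-adjustment method passed to [stats::p.adjust()].
#' @param exact_n_max combined-sample-size cutoff for the exact
#'   permutation p (default 8).
#' @return a `group_comparison` object.
#' @export
kruskal_dunn <- function(groups, adjust = "bonferroni", exact_n_max = 8L) {
  groups <- check_groups(groups)
  x <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  pairs <- utils::combn(names(groups), 2L)
  if (length(unique(x)) == 1L) {
    pw <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                     z = 0, p_raw = 1, p_adjusted = 1)
    return(group_comparison("kruskal_dunn", 0, 1, pw, adjust))
  }
  kw <- stats::kruskal.test(x, g)
  if (length(x) <= exact_n_max) {
    kw$p.value <- kw_exact_p(x, lengths(groups))
  }
  n_tot <- length(x)
  r <- rank(x)  # midranks
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  var_base <- n_tot * (n_tot + 1) / 12 - tie_term
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt(var_base * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[j] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  pw <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                   z = z, p_raw = p_raw,
                   p_adjusted = stats::p.adjust(p_raw, adjust))
  group_comparison("kruskal_dunn", unname(kw$statistic), kw$p.value, pw, adjust)
}

#' One-way ANOVA with Tukey's HSD pairwise comparisons
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   observations).
#' @return a `group_comparison` object (pairwise p values are
#'   Tukey-adjusted).
#' @export
anova_tukey <- function(groups) {
  groups <- check_groups(groups, min_per_group = 2L)
  x <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  pairs <- utils::combn(names(groups), 2L)
  if (length(unique(x)) == 1L) {
    pw <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                     diff = 0, p_raw = 1, p_adjusted = 1)
    return(group_comparison("anova_tukey", 0, 1, pw, "tukey"))
  }
  df <- data.frame(x = x, g = g)
  fit <- stats::aov(x ~ g, data = df)
  tab <- summary(fit)[[1L]]
  fstat <- tab[["F value"]][1L]
  pval <- tab[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit)$g
  key <- paste(pairs[2L, ], pairs[1L, ], sep = "-")  # TukeyHSD's label order
  pw <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                   diff = -tk[key, "diff"],
                   p_raw = tk[key, "p adj"],
                   p_adjusted = tk[key, "p adj"])
  rownames(pw) <- NULL
  group_comparison("anova_tukey", fstat, pval, pw, "tukey")
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Conditional odds ratio and two-sided p value (the sum of hypergeometric
#' probabilities of tables, with the observed margins, no more probable
#' than the observed one). A zero margin makes the table degenerate and
#' returns p = 1 with an undefined odds ratio.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return list `odds_ratio`, `p_value`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    zp_stop("value_error", "need a 2 x 2 table of non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Mann-Whitney U test (two-tailed)
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. The returned U counts pairs where an `x`
#' observation exceeds a `y` observation (plus half-ties).
#'
#' @param x,y numeric samples (each >= 1 observation).
#' @return list `U`, `p_value`, `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    zp_stop("value_error", "both samples need >= 1 observation")
  }
  if (length(unique(c(x, y))) == 1L) {
    # fully tied samples: the normal approximation degenerates (zero
    # variance); there is no evidence against the null
    return(list(U = length(x) * length(y) / 2, p_value = 1,
                method = "normal"))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal")
}
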