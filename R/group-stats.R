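# Group-comparison statistics applied to per-participant densities:
# Levene's test for equality of variances, the pooled (equal-variance)
# two-sample t-test with Cohen's d, and Benjamini-Hochberg adjustment.

#' Levene's test for equality of variances
#'
#' One-way ANOVA on absolute deviations from the group centre. The classic
#' test uses the group mean as centre (default); `center = "median"` gives
#' the Brown-Forsythe variant.
#'
#' @param x,y numeric vectors, each with >= 2 observations
#' @param center `"mean"` (classic Levene) or `"median"` (Brown-Forsythe)
#' @return list with `statistic` (F), `df` (c(1, n1+n2-2)), `p_value`
#' @export
levene_test <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  cfun <- if (center == "mean") mean else stats::median
  z <- c(abs(x - cfun(x)), abs(y - cfun(y)))
  g <- factor(rep(1:2, c(length(x), length(y))))
  n <- length(z)
  zm <- tapply(z, g, mean)
  grand <- mean(z)
  ssb <- sum(tabulate(g) * (zm - grand)^2)
  ssw <- sum((z - zm[g])^2)
  df1 <- 1L
  df2 <- n - 2L
  if (ssw == 0) {
    stat <- if (ssb == 0) 0 else Inf
  } else {
    stat <- (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(stat)) 0 else pf(stat, df1, df2, lower.tail = FALSE)
  list(statistic = unname(stat), df = c(df1, df2), p_value = unname(p))
}

#' Pooled-variance two-sample t-test
#'
#' Equal-variance independent-samples t-test, two-sided, with df = n1+n2-2.
#' Accepts either raw vectors or summary statistics (n, mean, SD per group),
#' so printed group tables can be checked directly. Cohen's d uses the
#' pooled SD.
#'
#' @param x,y numeric vectors (raw mode), or `NULL` when using summaries
#' @param n1,mean1,sd1,n2,mean2,sd2 summary-statistic mode
#' @return list of class `group_comparison`: `n1`, `n2`, `mean1`, `mean2`,
#'   `sd1`, `sd2`, `levene_p` (raw mode only), `t_stat`, `df`, `p_value`,
#'   `cohens_d`
#' @export
t_test_equal_var <- function(x = NULL, y = NULL, n1 = NULL, mean1 = NULL,
                             sd1 = NULL, n2 = NULL, mean2 = NULL,
                             sd2 = NULL) {
  levene_p <- NA_real_
  if (!is.null(x)) {
    if (length(x) < 2 || length(y) < 2)
      stop("each group needs at least 2 observations")
    n1 <- length(x); mean1 <- mean(x); sd1 <- sd(x)
    n2 <- length(y); mean2 <- mean(y); sd2 <- sd(y)
    levene_p <- levene_test(x, y)$p_value
  }
  if (any(vapply(list(n1, mean1, sd1, n2, mean2, sd2), is.null, logical(1))))
    stop("provide raw vectors or all six summary statistics")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) stop("zero pooled variance")
  t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  structure(list(n1 = n1, n2 = n2, mean1 = mean1, mean2 = mean2,
                 sd1 = sd1, sd2 = sd2, levene_p = levene_p,
                 t_stat = t_stat, df = df, p_value = p,
                 cohens_d = (mean1 - mean2) / sqrt(sp2)),
            class = "group_comparison")
}

#' Cohen's d with pooled standard deviation
#'
#' d = (mean1 - mean2) / s_pooled with
#' s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2). Raw-vector and
#' summary-statistic modes as in [t_test_equal_var()].
#'
#' @inheritParams t_test_equal_var
#' @return Cohen's d (sign follows mean1 - mean2)
#' @export
cohens_d_pooled <- function(x = NULL, y = NULL, n1 = NULL, mean1 = NULL,
                            sd1 = NULL, n2 = NULL, mean2 = NULL,
                            sd2 = NULL) {
  t_test_equal_var(x, y, n1, mean1, sd1, n2, mean2, sd2)$cohens_d
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' input order is preserved in the output.
#'
#' @param p_values numeric vector of p-values in [0, 1]
#' @return adjusted p-values in the input order
#' @export
benjamini_hochberg <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Compare the two groups on every density column
#'
#' Runs the pooled t-test per column of per-participant densities and
#' adjusts the p-values with Benjamini-Hochberg.
#'
#' @param densities data frame with a `group` column and one numeric column
#'   per measure
#' @param measures column names to compare (default: all numeric columns)
#' @return data frame, one row per measure, with group means/SDs, Levene p,
#'   t, df, p, adjusted p and Cohen's d
#' @export
compare_groups <- function(densities, measures = NULL) {
  stopifnot("group" %in% names(densities))
  groups <- unique(densities$group)
  if (length(groups) != 2) stop("exactly two groups are required")
  if (is.null(measures))
    measures <- names(densities)[vapply(densities, is.numeric, logical(1))]
  rows <- lapply(measures, function(m) {
    x <- densities[[m]][densities$group == groups[1]]
    y <- densities[[m]][densities$group == groups[2]]
    ct <- t_test_equal_var(x, y)
    data.frame(measure = m, n1 = ct$n1, n2 = ct$n2, mean1 = ct$mean1,
               sd1 = ct$sd1, mean2 = ct$mean2, sd2 = ct$sd2,
               levene_p = ct$levene_p, t_stat = ct$t_stat, df = ct$df,
               p_value = ct$p_value, cohens_d = ct$cohens_d)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- benjamini_hochberg(out$p_value)
  out
}
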