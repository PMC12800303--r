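# Agreement and segmentation evaluation metrics: pixel-wise Dice / recall /
# precision / specificity, MAPE / MAE, Bland-Altman limits of agreement,
# two-way absolute-agreement ICC with F-based confidence intervals, and
# Pearson correlation with a Fisher-z interval.

as_binary_matrix <- function(m) {
  if (inherits(m, "segmentation_mask")) m <- m$data
  if (length(dim(m)) == 3) stop("per-class metrics need a single channel")
  m > 0
}

#' Pixel-wise confusion counts
#' @param pred,truth binary masks (matrix or `nerve_binary`
#'   [segmentation_mask()]); for one-hot masks pass a single channel
#' @return list with `tp`, `fp`, `fn`, `tn`
#' @export
pixel_confusion <- function(pred, truth) {
  p <- as_binary_matrix(pred)
  t <- as_binary_matrix(truth)
  if (!all(dim(p) == dim(t))) stop("mask shapes differ")
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
       tn = sum(!p & !t))
}

#' @rdname pixel_metrics
#' @export
dice <- function(pred, truth) {
  cm <- pixel_confusion(pred, truth)
  den <- 2 * cm$tp + cm$fp + cm$fn
  if (den == 0) return(1)         # both masks empty: perfect agreement on absence
  2 * cm$tp / den
}

#' Pixel-wise segmentation metrics
#'
#' Dice = 2TP/(2TP+FP+FN); recall = TP/(TP+FN); precision = TP/(TP+FP);
#' specificity = TN/(TN+FP). When both masks are empty, dice/recall/
#' precision are defined as 1 (perfect agreement on absence).
#'
#' @param pred,truth binary masks of equal shape
#' @return a fraction in [0, 1]
#' @name pixel_metrics
#' @export
recall <- function(pred, truth) {
  cm <- pixel_confusion(pred, truth)
  if (cm$tp + cm$fn == 0) return(1)
  cm$tp / (cm$tp + cm$fn)
}

#' @rdname pixel_metrics
#' @export
precision <- function(pred, truth) {
  cm <- pixel_confusion(pred, truth)
  if (cm$tp + cm$fp == 0) return(1)
  cm$tp / (cm$tp + cm$fp)
}

#' @rdname pixel_metrics
#' @export
specificity <- function(pred, truth) {
  cm <- pixel_confusion(pred, truth)
  if (cm$tn + cm$fp == 0) return(1)
  cm$tn / (cm$tn + cm$fp)
}

#' Mean absolute percentage error
#'
#' `100 * mean(|pred - truth| / |truth|)`. Pairs with zero truth are
#' excluded with a warning (the measurands here are positive).
#'
#' @param pred,truth equal-length numeric vectors
#' @return MAPE in percent
#' @export
mape <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("vector lengths differ")
  if (length(pred) < 1) stop("empty vectors")
  keep <- truth != 0
  if (!all(keep)) {
    warning(sum(!keep), " pair(s) with zero truth excluded from MAPE")
    if (!any(keep)) stop("no nonzero-truth pairs for MAPE")
  }
  100 * mean(abs(pred[keep] - truth[keep]) / abs(truth[keep]))
}

#' Mean absolute error
#' @inheritParams mape
#' @return MAE in the measurand's units
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("vector lengths differ")
  if (length(pred) < 1) stop("empty vectors")
  mean(abs(pred - truth))
}

#' Bland-Altman agreement statistics
#'
#' Differences d = a - b; bias = mean(d); sd_diff = sample SD (n-1
#' denominator); 95% limits of agreement = bias +/- 1.96 sd_diff.
#'
#' @param a,b paired measurements (e.g. automated and manual), length >= 2
#' @return list with `bias`, `sd_diff`, `loa_low`, `loa_high`
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("vector lengths differ")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Intraclass correlation between two raters
#'
#' Two-way model, absolute agreement. `type = "single"` is ICC(A,1) (the
#' reliability of a single measurement); `type = "average"` is ICC(A,k)
#' (the reliability of the k-rater average). Confidence intervals follow
#' the standard F-based construction with Satterthwaite degrees of freedom.
#'
#' @param a,b paired ratings, length >= 3
#' @param type `"single"` or `"average"`
#' @param conf confidence level
#' @return list with `icc`, `ci` (length-2 vector), `type`
#' @export
icc_agreement <- function(a, b, type = c("single", "average"), conf = 0.95) {
  type <- match.arg(type)
  if (length(a) != length(b)) stop("vector lengths differ")
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs")
  k <- 2
  x <- cbind(a, b)
  if (all(a == b)) return(list(icc = 1, ci = c(1, 1), type = type))
  if (var(as.vector(x)) == 0)
    stop("zero total variance with unequal columns")
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  grand <- mean(x)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  r1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  alpha <- 1 - conf
  # Satterthwaite df for the denominator of the A,1 interval
  aa <- k * r1 / (n * (1 - r1))
  bb <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
  v <- (aa * MSC + bb * MSE)^2 /
    ((aa * MSC)^2 / (k - 1) + (bb * MSE)^2 / ((n - 1) * (k - 1)))
  F1 <- qf(1 - alpha / 2, n - 1, v)
  F2 <- qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (MSR - F1 * MSE) /
    (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi1 <- n * (F2 * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
  if (type == "single") {
    list(icc = r1, ci = c(lo1, hi1), type = type)
  } else {
    sb <- function(r) k * r / (1 + (k - 1) * r)
    list(icc = sb(r1), ci = c(sb(lo1), sb(hi1)), type = type)
  }
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param a,b numeric vectors, length >= 3, nonzero variances
#' @param conf confidence level
#' @return list with `r` and `ci` (via `tanh(atanh(r) +/- z / sqrt(n - 3))`)
#' @export
pearson_ci <- function(a, b, conf = 0.95) {
  if (length(a) != length(b)) stop("vector lengths differ")
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs")
  if (var(a) == 0 || var(b) == 0) stop("zero variance input")
  r <- cor(a, b)
  z <- qnorm(1 - (1 - conf) / 2)
  if (abs(r) >= 1) return(list(r = r, ci = c(r, r)))
  ci <- tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
  list(r = r, ci = ci)
}

#' Paired-method agreement report
#'
#' Bundles the agreement statistics used to compare an automated and a
#' manual measurement series: Bland-Altman bias and limits, ICC, Pearson r,
#' MAPE and MAE.
#'
#' @param automated,manual paired measurements (length >= 3)
#' @param icc_type passed to [icc_agreement()]
#' @return list of class `agreement_report`
#' @export
agreement_report <- function(automated, manual, icc_type = "single") {
  ba <- bland_altman(automated, manual)
  icc <- icc_agreement(automated, manual, icc_type)
  pr <- pearson_ci(automated, manual)
  structure(c(ba, list(icc = icc$icc, icc_ci = icc$ci, icc_type = icc$type,
                       pearson_r = pr$r, pearson_ci = pr$ci,
                       mape = mape(automated, manual),
                       mae = mae(automated, manual), n = length(manual))),
            class = "agreement_report")
}
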