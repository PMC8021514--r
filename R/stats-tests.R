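#' Welch's two-sample t test
#'
#' Unequal-variance t test for the difference of two group means, the
#' primitive behind every differential-methylation screen in this package.
#' The statistic is \eqn{(\bar x - \bar y) / \sqrt{s_x^2/n_x + s_y^2/n_y}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' the t distribution.
#'
#' Degenerate inputs are handled explicitly rather than failing: when both
#' groups have zero variance and equal means the statistic is 0 and p = 1;
#' when both have zero variance and different means the statistic is signed
#' infinity and p = 0.
#'
#' @param x,y Numeric vectors of measurements, at least 2 finite values each.
#'   `NA`s are dropped.
#' @return An object of class `"pm_test"`: a list with `statistic`, `df`
#'   (possibly fractional), `p_raw`, and `p_adjusted` (`NA` here; filled in
#'   by screening code).
#' @examples
#' welch_t_test(c(0.10, 0.20, 0.30), c(0.60, 0.70, 0.80))
#' @seealso [differential_screen()] for the vectorised per-probe version.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    .pm_stop("each group needs at least 2 non-missing values",
             "pm_invalid_input")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  num <- mean(x) - mean(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    # both variances zero: identical constants -> no evidence; unequal
    # constants -> infinitely strong evidence
    if (num == 0)
      return(pm_test(statistic = 0, df = nx + ny - 2, p_raw = 1))
    return(pm_test(statistic = sign(num) * Inf, df = nx + ny - 2, p_raw = 0))
  }
  stat <- num / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  pm_test(statistic = stat, df = df,
          p_raw = 2 * stats::pt(-abs(stat), df))
}

pm_test <- function(statistic, df = NA_real_, p_raw, p_adjusted = NA_real_) {
  structure(list(statistic = statistic, df = df, p_raw = p_raw,
                 p_adjusted = p_adjusted),
            class = "pm_test")
}

#' @export
print.pm_test <- function(x, ...) {
  cat("statistic =", format(x$statistic, digits = 5),
      if (!is.na(x$df)) paste0("(df = ", format(x$df, digits = 5), ")"),
      " p =", format.pval(x$p_raw, digits = 4))
  if (!is.na(x$p_adjusted))
    cat("  adjusted p =", format.pval(x$p_adjusted, digits = 4))
  cat("\n")
  invisible(x)
}

#' Bonferroni adjustment of a p-value
#'
#' Family-wise correction used by the genome-wide screens: the adjusted
#' p-value is `min(1, m * p_raw)`.
#'
#' @param p_raw Raw p-value(s) in \[0, 1\] (vectorised).
#' @param m Number of tests in the family, a positive integer.
#' @return Adjusted p-value(s), capped at 1.
#' @examples
#' bonferroni_adjust(1e-7, 473457)
#' @export
bonferroni_adjust <- function(p_raw, m) {
  if (length(m) != 1L || is.na(m) || m < 1)
    .pm_stop("m must be a single integer >= 1", "pm_invalid_input")
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    .pm_stop("p_raw must lie in [0, 1]", "pm_invalid_input")
  pmin(1, p_raw * m)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test of association in a 2x2 contingency table, used for
#' cluster-versus-clinical-factor associations.  The two-sided p-value is
#' computed by the probability-mass rule: the sum of hypergeometric
#' probabilities of every table with the observed margins whose probability
#' does not exceed that of the observed table.  (Implementations of the
#' two-sided rule differ; this is the convention also used by base R's
#' `fisher.test`.)
#'
#' A table with a zero margin carries no information about association and
#' returns p = 1.
#'
#' @param tab A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` read row-wise.
#' @return A `"pm_test"` with `statistic` = hypergeometric probability of the
#'   observed table and `p_raw` = two-sided p.
#' @examples
#' fisher_exact_2x2(matrix(c(22, 0, 36, 24), nrow = 2))
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.matrix(tab)) {
    if (!all(dim(tab) == c(2L, 2L)))
      .pm_stop("table must be 2x2", "pm_invalid_input")
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  } else {
    if (length(tab) != 4L) .pm_stop("need 4 counts", "pm_invalid_input")
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
  }
  cnt <- c(a, b, c, d)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    .pm_stop("counts must be non-negative integers", "pm_invalid_input")
  if (sum(cnt) == 0) .pm_stop("empty table", "pm_invalid_input")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0)
    return(pm_test(statistic = 1, p_raw = 1))       # degenerate margin
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  # relative tolerance guards against FP noise when masses are tied
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  pm_test(statistic = p_obs, p_raw = min(1, p))
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation between two paired vectors; used to check
#' concordance between pyrosequencing and array methylation measurements.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.  Pairs with any `NA` are dropped.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y))
    .pm_stop("x and y must have equal length", "pm_invalid_input")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    .pm_stop("need at least 3 complete pairs", "pm_invalid_input")
  sx <- stats::var(x); sy <- stats::var(y)
  if (sx == 0 || sy == 0)
    .pm_stop("correlation undefined: zero variance", "pm_zero_variance")
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sqrt(sx * sy))
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity is the fraction of true positives among actual positives,
#' tp / (tp + fn); specificity is tn / (tn + fp).  These are the diagnostic
#' metrics reported for the early-recurrence marker panel.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @param percent Report on the percent scale, rounded to 1 decimal
#'   (default), or as raw fractions.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @examples
#' confusion_metrics(tp = 18, fp = 17, tn = 43, fn = 4)
#' @export
confusion_metrics <- function(tp, fp, tn, fn, percent = TRUE) {
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(cnt)) || any(cnt < 0))
    .pm_stop("counts must be non-negative", "pm_invalid_input")
  if (tp + fn == 0)
    .pm_stop("sensitivity undefined: no actual positives (tp + fn = 0)",
             "pm_undefined_metric")
  if (tn + fp == 0)
    .pm_stop("specificity undefined: no actual negatives (tn + fp = 0)",
             "pm_undefined_metric")
  out <- c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
  if (percent) round(100 * out, 1) else out
}
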