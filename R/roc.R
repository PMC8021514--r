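#' Empirical ROC curve for a directional marker
#'
#' Builds the empirical receiver-operating-characteristic curve of a single
#' continuous marker for discriminating a positive class (e.g. early
#' recurrence) from a negative class.  The marker direction is explicit:
#' `"positive-if-low"` calls a sample positive when its value is *below* a
#' threshold (hypomethylation marks the positive class),
#' `"positive-if-high"` when it is above.
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' pooled values, with `-Inf`/`Inf` sentinels, so that calls are stable
#' under small measurement jitter.  The AUC is computed by the trapezoid
#' rule over the resulting operating points, which equals the tie-corrected
#' rank statistic P(positive sample on the positive side) + 1/2 P(tie).
#'
#' @param pos Marker values of positive-class samples.
#' @param neg Marker values of negative-class samples.
#' @param direction `"positive-if-low"` or `"positive-if-high"`.
#' @return Object of class `"pm_roc"`: list with `thresholds`,
#'   `sensitivity`, `specificity` (parallel vectors), `auc`, `direction`,
#'   `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(10, 20), c(15, 25, 30), "positive-if-low")
#' @export
roc_curve <- function(pos, neg,
                      direction = c("positive-if-low", "positive-if-high")) {
  direction <- match.arg(direction)
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) == 0L || length(neg) == 0L)
    .pm_stop("both classes must be non-empty", "pm_invalid_input")
  v <- sort(unique(c(pos, neg)))
  thr <- c(-Inf, if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2, Inf)
  if (direction == "positive-if-low") {
    sens <- vapply(thr, function(t) mean(pos < t), 0)
    spec <- vapply(thr, function(t) mean(neg >= t), 0)
  } else {
    sens <- vapply(thr, function(t) mean(pos > t), 0)
    spec <- vapply(thr, function(t) mean(neg <= t), 0)
  }
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, direction = direction,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "pm_roc")
}

#' @export
print.pm_roc <- function(x, ...) {
  cat("Empirical ROC curve (", x$direction, "): ",
      x$n_pos, " positive vs ", x$n_neg, " negative samples\n",
      "AUC = ", format(x$auc, digits = 4), ", ",
      length(x$thresholds), " candidate thresholds\n", sep = "")
  invisible(x)
}

#' @export
plot.pm_roc <- function(x, ...) {
  fpr <- 1 - x$specificity
  ord <- order(fpr, x$sensitivity)
  graphics::plot(fpr[ord], x$sensitivity[ord], type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-index optimal cut-off
#'
#' Selects the threshold of an ROC curve maximising the Youden index
#' J = sensitivity + specificity - 1, the rule used to fix each marker
#' CpG's diagnostic cut-off.  Ties on J are broken in favour of higher
#' sensitivity, then in favour of the more permissive threshold (the one
#' admitting more positive calls).
#'
#' @param curve A `"pm_roc"` object from [roc_curve()].
#' @return List with `cutoff`, `sensitivity`, `specificity`, and `j` at the
#'   selected threshold.
#' @examples
#' youden_cutoff(roc_curve(c(10, 20), c(15, 25, 30), "positive-if-low"))
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "pm_roc"))
  j <- curve$sensitivity + curve$specificity - 1
  # permissiveness: larger thresholds admit more positives when low values
  # are positive, smaller thresholds when high values are positive
  perm <- if (curve$direction == "positive-if-low")
    curve$thresholds else -curve$thresholds
  ord <- order(-j, -curve$sensitivity, -perm)
  best <- ord[1L]
  list(cutoff = curve$thresholds[best],
       sensitivity = curve$sensitivity[best],
       specificity = curve$specificity[best],
       j = j[best])
}
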