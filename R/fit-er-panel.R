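#' Fit an early-recurrence marker panel
#'
#' The package's central model fit.  Given tumour beta values and clinical
#' records, it (1) assigns early-recurrence (ER) labels from the
#' recurrence window, (2) screens probes for ER-discriminating markers
#' (raw Welch p < `alpha`, |delta beta| > `delta_threshold`, then
#' AUC > `auc_min`), (3) fixes a directional Youden cut-off per surviving
#' marker, (4) keeps the top `n_markers` markers by AUC and assembles them
#' into a k-of-n voting panel with threshold `min_positive`, and
#' (5) evaluates the panel on the training cohort for every k.
#'
#' @param beta A `BetaMatrix` of tumour samples (fraction scale).
#' @param clinical Clinical table covering those samples, or a
#'   pre-computed label table from [assign_er_labels()].
#' @param er_window_days ER window in days (default 183 = 6 months).
#' @param alpha,delta_threshold,auc_min Screen thresholds (defaults 0.05,
#'   0.10, 0.70); see [screen_candidates()].
#' @param n_markers Panel size (default 3).
#' @param min_positive Voting threshold k (default 2).
#' @return Object of class `"er_panel"`: list with `rule` (a
#'   [panel_rule()]), `criteria`, `screen` (the `"er_screen"`),
#'   `er_labels`, `training_eval` (a `"panel_eval"`), `call`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_probes = 300, seed = 7))
#' tum <- sim$dataset$beta[, grep("^T", colnames(sim$dataset$beta$beta))]
#' fit <- fit_er_panel(tum, sim$dataset$clinical)
#' fit
#' @export
fit_er_panel <- function(beta, clinical, er_window_days = 183,
                         alpha = 0.05, delta_threshold = 0.10,
                         auc_min = 0.70, n_markers = 3L,
                         min_positive = 2L) {
  stopifnot(inherits(beta, "BetaMatrix"))
  lab <- if (!is.null(clinical$er)) clinical else
    assign_er_labels(clinical, er_window_days)
  lab <- lab[lab$sample_id %in% sample_ids(beta), , drop = FALSE]
  scr <- screen_candidates(beta, lab, alpha = alpha,
                           delta_threshold = delta_threshold,
                           auc_min = auc_min)
  if (nrow(scr$candidates) < 1L)
    .pm_stop("no marker survived the screen; cannot build a panel",
             "pm_empty_panel")
  top <- utils::head(scr$candidates$probe_id, n_markers)
  crit <- do.call(rbind, lapply(top, function(pid)
    build_criterion(scr$curves[[pid]], pid, scale = "fraction")))
  rule <- panel_rule(crit, min_positive = min(min_positive, nrow(crit)))
  vals <- convert_scale(t(beta$beta[top, lab$sample_id, drop = FALSE]),
                        to = "percent")
  ev <- evaluate_panel(vals, lab, crit, cohort = "training")
  structure(list(rule = rule, criteria = crit, screen = scr,
                 er_labels = lab, training_eval = ev,
                 n_markers = length(top), call = match.call()),
            class = "er_panel")
}

#' @export
print.er_panel <- function(x, ...) {
  cat("Early-recurrence marker panel (", x$n_markers, " CpGs, positive when >= ",
      x$rule$min_positive, " markers call ER)\n", sep = "")
  print(x$criteria, digits = 3, row.names = FALSE)
  k <- x$rule$min_positive
  row <- x$training_eval[x$training_eval$k == k, ]
  cat(sprintf("training (n = %d): sensitivity %.1f%%, specificity %.1f%% at k = %d\n",
              attr(x$training_eval, "n"), row$sensitivity_pct,
              row$specificity_pct, k))
  invisible(x)
}

#' @export
summary.er_panel <- function(object, ...) {
  cat("ER marker panel fit\n")
  cat("  screen:", object$screen$screen$counts["tested"], "probes tested;",
      object$screen$screen$counts["selected"],
      "passed stage 1 (raw p <", object$screen$screen$alpha,
      ", |delta beta| >", object$screen$screen$delta_threshold, ");",
      nrow(object$screen$candidates), "passed the AUC filter\n")
  cat("  cohort:", sum(object$er_labels$er), "ER /",
      sum(!object$er_labels$er), "non-ER samples\n\n")
  print(object$criteria, digits = 3, row.names = FALSE)
  cat("\n")
  print(object$training_eval)
  invisible(object)
}

#' Extract the panel criteria
#'
#' @param object An `"er_panel"` fit.
#' @param ... Ignored.
#' @return The criteria `data.frame` (probe, position, direction, percent
#'   cut-off, AUC) — the machine-readable form of the diagnostic table.
#' @export
coef.er_panel <- function(object, ...) object$criteria

#' Predict panel calls for new samples
#'
#' Applies the frozen panel — cut-offs and directions unchanged — to new
#' methylation measurements.
#'
#' @param object An `"er_panel"` fit.
#' @param newdata Samples x probes matrix of marker measurements covering
#'   all panel probes; percent scale unless `scale = "fraction"`.
#' @param k Voting threshold (default: the rule's `min_positive`).
#' @param type `"class"` for logical panel calls, `"votes"` for per-sample
#'   marker-positive counts.
#' @param scale Scale of `newdata`.
#' @param ... Ignored.
#' @return Named logical (or integer) vector over samples.
#' @export
predict.er_panel <- function(object, newdata, k = NULL,
                             type = c("class", "votes"),
                             scale = c("percent", "fraction"), ...) {
  type <- match.arg(type); scale <- match.arg(scale)
  if (inherits(newdata, "BetaMatrix"))
    newdata <- t(convert_scale(newdata, to = "percent")$beta)
  else if (scale == "fraction")
    newdata <- convert_scale(newdata, to = "percent")
  if (is.null(k)) k <- object$rule$min_positive
  votes <- .panel_votes(newdata, object$criteria)
  names(votes) <- rownames(newdata)
  if (type == "votes") votes else votes >= k
}

#' Plot the ROC curves of the fitted panel markers
#'
#' @param x An `"er_panel"` fit.
#' @param ... Passed to the underlying curve plots.
#' @export
plot.er_panel <- function(x, ...) {
  n <- x$n_markers
  op <- graphics::par(mfrow = c(1, n))
  on.exit(graphics::par(op))
  for (pid in x$criteria$probe_id) {
    plot(x$screen$curves[[pid]], ...)
    graphics::legend("bottomright", legend = pid, bty = "n")
  }
  invisible(x)
}
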