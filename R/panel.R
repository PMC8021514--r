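#' Screen candidate ER-marker CpGs
#'
#' Two-stage marker screen for discriminating the early-recurrence (ER)
#' group.  Stage 1 is a [differential_screen()] of ER versus non-ER
#' samples with *raw* p-values (no multiplicity correction — the marker
#' screen is deliberately more permissive than the genome-wide tissue
#' screens) and a delta-beta filter.  Stage 2 fits an empirical ROC curve
#' to each surviving probe, with the marker direction taken from the sign
#' of delta-beta (ER mean below non-ER mean means low values call ER),
#' and keeps probes with AUC above `auc_min`.
#'
#' @param beta A `BetaMatrix` of tumour samples (fraction scale).
#' @param er_labels Output of [assign_er_labels()] restricted to the
#'   samples of `beta`.
#' @param alpha Stage-1 significance level (default 0.05).
#' @param delta_threshold Stage-1 minimum |delta beta| (default 0.10).
#' @param auc_min Stage-2 AUC threshold (default 0.70, strict).
#' @return Object of class `"er_screen"`: list with `candidates` (a
#'   data.frame: `probe_id`, `delta_beta`, `p_raw`, `auc`, `direction`),
#'   `curves` (named list of `"pm_roc"`), `screen` (the stage-1
#'   `"dmp_screen"`), `n_er`, `n_non_er`.
#' @export
screen_candidates <- function(beta, er_labels, alpha = 0.05,
                              delta_threshold = 0.10, auc_min = 0.70) {
  stopifnot(inherits(beta, "BetaMatrix"))
  lab <- er_labels[match(sample_ids(beta), er_labels$sample_id), ]
  if (anyNA(lab$er))
    .pm_stop("every sample in beta needs an ER label", "pm_invalid_input")
  er_ids <- lab$sample_id[lab$er]
  non_ids <- lab$sample_id[!lab$er]
  if (length(er_ids) < 2L || length(non_ids) < 2L)
    .pm_stop("each class needs at least 2 samples", "pm_invalid_input")
  scr <- differential_screen(beta, er_ids, non_ids, alpha = alpha,
                             bonferroni = FALSE,
                             delta_threshold = delta_threshold)
  hits <- scr$results[scr$results$selected, , drop = FALSE]
  curves <- list()
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    pid <- hits$probe_id[i]
    dir <- if (hits$delta_beta[i] < 0) "positive-if-low" else
      "positive-if-high"
    cu <- roc_curve(beta$beta[pid, er_ids], beta$beta[pid, non_ids], dir)
    if (cu$auc > auc_min) {
      curves[[pid]] <- cu
      rows[[pid]] <- data.frame(probe_id = pid,
                                delta_beta = hits$delta_beta[i],
                                p_raw = hits$p_raw[i],
                                auc = cu$auc, direction = dir,
                                stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(), delta_beta = numeric(),
               p_raw = numeric(), auc = numeric(), direction = character())
  rownames(cand) <- NULL
  cand <- cand[order(-cand$auc, cand$probe_id), , drop = FALSE]
  structure(list(candidates = cand, curves = curves, screen = scr,
                 n_er = length(er_ids), n_non_er = length(non_ids)),
            class = "er_screen")
}

#' @export
print.er_screen <- function(x, ...) {
  cat("ER marker screen:", x$screen$counts["tested"], "probes tested,",
      x$screen$counts["selected"], "passed stage 1,",
      nrow(x$candidates), "passed the AUC filter\n")
  if (nrow(x$candidates))
    print(utils::head(x$candidates, 10), digits = 3)
  invisible(x)
}

#' Build a diagnostic criterion from an ROC curve
#'
#' Fixes a marker CpG's cut-off at the Youden-index optimum of its ROC
#' curve and records the call direction and AUC.  Cut-offs are stored on
#' the percent scale (the scale of the clinical pyrosequencing assay).
#'
#' @param curve A `"pm_roc"` from [roc_curve()].
#' @param probe_id Probe identifier.
#' @param position CpG position within the pyrosequencing amplicon
#'   (1 = the array probe site itself; neighbours numbered outward).
#' @param scale Scale of the values the curve was fitted on:
#'   `"fraction"` or `"percent"`.
#' @return A one-row `data.frame` of class `"marker_criterion"`: columns
#'   `probe_id`, `position`, `direction` (`"ER_below"`/`"ER_above"`),
#'   `cutoff_percent`, `auc`.
#' @export
build_criterion <- function(curve, probe_id, position = 1L,
                            scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  yj <- youden_cutoff(curve)
  cut <- if (scale == "fraction") 100 * yj$cutoff else yj$cutoff
  structure(data.frame(probe_id = probe_id, position = as.integer(position),
                       direction = if (curve$direction == "positive-if-low")
                         "ER_below" else "ER_above",
                       cutoff_percent = cut, auc = curve$auc,
                       stringsAsFactors = FALSE),
            class = c("marker_criterion", "data.frame"))
}

#' Call one marker CpG against its criterion
#'
#' A sample is marker-positive when its methylation level is strictly
#' below the cut-off for an `ER_below` criterion (hypomethylation marks
#' ER) or strictly above it for `ER_above`.  A value exactly at the
#' cut-off is *not* called positive.
#'
#' @param value Methylation level(s) in percent, in \[0, 100\].
#' @param criterion A one-row criterion ([build_criterion()]) or any list
#'   with `cutoff_percent` and `direction`.
#' @return Logical vector of calls.
#' @export
call_marker <- function(value, criterion) {
  if (any(!is.na(value) & (value < 0 | value > 100)))
    .pm_stop("marker values must be percentages in [0, 100]",
             "pm_validation_error")
  dir <- criterion$direction[1L]
  cut <- criterion$cutoff_percent[1L]
  if (dir == "ER_below") value < cut else value > cut
}

#' Construct a k-of-n panel rule
#'
#' @param criteria A criteria `data.frame` (rows from [build_criterion()]).
#' @param min_positive Minimum number of marker-positive CpGs for a
#'   panel-positive call (k), between 1 and the number of criteria.
#' @return Object of class `"panel_rule"`.
#' @export
panel_rule <- function(criteria, min_positive = 2L) {
  stopifnot(is.data.frame(criteria), nrow(criteria) >= 1L)
  k <- as.integer(min_positive)
  if (k < 1L || k > nrow(criteria))
    .pm_stop("min_positive must be between 1 and the number of criteria",
             "pm_invalid_input")
  structure(list(criteria = as.data.frame(criteria), min_positive = k),
            class = "panel_rule")
}

#' Apply a voting panel to one sample
#'
#' Panel-positive when at least `min_positive` of the rule's marker CpGs
#' individually call ER.  Missing marker values are an error — no silent
#' imputation.
#'
#' @param values Named numeric vector of percent methylation levels,
#'   covering every probe in the rule.
#' @param rule A [panel_rule()].
#' @return Logical: panel call.
#' @export
call_panel <- function(values, rule) {
  stopifnot(inherits(rule, "panel_rule"))
  pid <- rule$criteria$probe_id
  if (!all(pid %in% names(values)) || anyNA(values[pid]))
    .pm_stop(paste("missing marker value for:",
                   paste(pid[!(pid %in% names(values)) |
                               is.na(values[pid])], collapse = ", ")),
             "pm_missing_marker")
  calls <- vapply(seq_along(pid), function(i)
    call_marker(values[[pid[i]]], rule$criteria[i, ]), NA)
  sum(calls) >= rule$min_positive
}

# per-sample marker-positive counts for a criteria set; values is a
# samples x probes matrix in percent
.panel_votes <- function(values, criteria) {
  pid <- criteria$probe_id
  if (!all(pid %in% colnames(values)))
    .pm_stop(paste("missing marker value for:",
                   paste(setdiff(pid, colnames(values)), collapse = ", ")),
             "pm_missing_marker")
  if (anyNA(values[, pid]))
    .pm_stop("missing marker measurements", "pm_missing_marker")
  calls <- vapply(seq_len(nrow(criteria)), function(i)
    call_marker(values[, pid[i]], criteria[i, ]), logical(nrow(values)))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(values))
  rowSums(calls)
}

#' Evaluate a voting panel over a labelled cohort
#'
#' Computes confusion counts and sensitivity/specificity of the k-of-n
#' voting rule for every k from 1 to n.  By construction the family is
#' monotone: raising k can only lose sensitivity and gain specificity;
#' this invariant is re-checked after computation.
#'
#' @param values Samples x probes matrix of percent methylation levels
#'   (rownames = sample ids).
#' @param er Logical vector (or labelled data.frame from
#'   [assign_er_labels()]) aligned with the rows of `values`.
#' @param criteria Criteria `data.frame`.
#' @param cohort Label stored with the evaluation (default `"initial"`).
#' @return Object of class `"panel_eval"`: data.frame with one row per k:
#'   `k`, `tp`, `fp`, `tn`, `fn`, `sensitivity_pct`, `specificity_pct`,
#'   plus attributes `cohort` and `n`.
#' @export
evaluate_panel <- function(values, er, criteria, cohort = "initial") {
  if (is.data.frame(er)) {
    er <- er$er[match(rownames(values), er$sample_id)]
  }
  er <- as.logical(er)
  if (length(er) != nrow(values) || anyNA(er))
    .pm_stop("every sample needs an ER label", "pm_invalid_input")
  if (!any(er) || all(er))
    .pm_stop("both ER and non-ER samples are required",
             "pm_undefined_metric")
  votes <- .panel_votes(values, criteria)
  ks <- seq_len(nrow(criteria))
  rows <- lapply(ks, function(k) {
    pos <- votes >= k
    tp <- sum(pos & er); fp <- sum(pos & !er)
    fn <- sum(!pos & er); tn <- sum(!pos & !er)
    m <- confusion_metrics(tp, fp, tn, fn)
    data.frame(k = k, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity_pct = m["sensitivity"],
               specificity_pct = m["specificity"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(all(diff(out$sensitivity_pct) <= 0),
            all(diff(out$specificity_pct) >= 0))
  structure(out, cohort = cohort, n = nrow(values),
            class = c("panel_eval", "data.frame"))
}

#' @export
print.panel_eval <- function(x, ...) {
  cat("Panel evaluation (", attr(x, "cohort"), " cohort, n = ",
      attr(x, "n"), "):\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Apply a frozen panel to an independent validation cohort
#'
#' Applies the criteria unchanged — cut-offs, directions and the voting
#' threshold are never refitted — and reports the evaluation labelled as
#' validation.
#'
#' @param rule A [panel_rule()] fitted on the discovery cohort.
#' @param values Samples x probes percent matrix of the validation cohort.
#' @param er ER labels of the validation cohort.
#' @param cohort Evaluation label (default `"validation"`).
#' @return A `"panel_eval"` (see [evaluate_panel()]).
#' @export
transfer_panel <- function(rule, values, er, cohort = "validation") {
  stopifnot(inherits(rule, "panel_rule"))
  evaluate_panel(values, er, rule$criteria, cohort = cohort)
}
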