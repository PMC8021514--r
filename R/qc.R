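#' Per-probe detection call proportions
#'
#' A probe is "called" in a sample when its detection p-value (probability
#' that the signal is background noise) is below `detection_alpha`.  The
#' call proportion is the fraction of samples in which the probe is
#' called; probes called in fewer than 90% of samples are conventionally
#' removed, since persistently weak signal often reflects polymorphism at
#' the probe CpG.
#'
#' @param beta A `BetaMatrix` carrying detection p-values.
#' @param detection_alpha Detection significance level (default 0.01).
#' @return Named numeric vector of call proportions, one per probe.
#' @export
compute_call_proportions <- function(beta, detection_alpha = 0.01) {
  stopifnot(inherits(beta, "BetaMatrix"))
  if (is.null(beta$detection_p))
    .pm_stop("detection p-values are not available for this matrix",
             "pm_unavailable_data")
  rowMeans(beta$detection_p < detection_alpha, na.rm = TRUE)
}

#' Probe quality filtering
#'
#' Removes probes in two ordered passes: first those with call proportion
#' below `call_prop_min` (low-call probes), then any remaining probes
#' annotated on chromosome X or Y (to avoid sex-specific methylation
#' bias).  Each probe is counted under the first rule it trips, so the
#' exclusion reasons never double-count.
#'
#' @param beta A `BetaMatrix`.
#' @param annotation Probe annotation covering every probe in `beta`.
#' @param call_prop_min Minimum call proportion to retain a probe
#'   (default 0.90).  Set to 0 (or provide no detection p-values with
#'   `require_detection = FALSE`) to skip the detection filter.
#' @param drop_sex Drop chromosome X/Y probes (default `TRUE`).
#' @param detection_alpha Detection significance level (default 0.01).
#' @param require_detection When `FALSE`, a matrix without detection
#'   p-values skips the low-call pass instead of failing.
#' @return List with `beta` (the filtered `BetaMatrix`, sample order
#'   preserved) and `report`, a list with per-probe `excluded_by`
#'   (`"none"`, `"low_call"`, `"sex_chromosome"`), `call_proportion`, and
#'   a `totals` count per reason.
#' @export
filter_probes <- function(beta, annotation, call_prop_min = 0.90,
                          drop_sex = TRUE, detection_alpha = 0.01,
                          require_detection = TRUE) {
  stopifnot(inherits(beta, "BetaMatrix"))
  pid <- probe_ids(beta)
  miss <- setdiff(pid, annotation$probe_id)
  if (length(miss))
    .pm_stop(paste("annotation missing for", length(miss), "probes"),
             "pm_invalid_input")
  ann <- annotation[match(pid, annotation$probe_id), ]
  excluded <- rep("none", length(pid))
  cp <- rep(NA_real_, length(pid))
  if (call_prop_min > 0 &&
      (!is.null(beta$detection_p) || require_detection)) {
    cp <- compute_call_proportions(beta, detection_alpha)
    excluded[cp < call_prop_min] <- "low_call"
  }
  if (drop_sex)
    excluded[excluded == "none" & ann$chromosome %in% c("X", "Y")] <-
      "sex_chromosome"
  keep <- excluded == "none"
  if (!any(keep))
    .pm_stop("all probes excluded by QC; nothing to analyse", "pm_qc_empty")
  report <- list(
    excluded_by = stats::setNames(excluded, pid),
    call_proportion = stats::setNames(cp, pid),
    totals = c(retained = sum(keep),
               low_call = sum(excluded == "low_call"),
               sex_chromosome = sum(excluded == "sex_chromosome")))
  list(beta = beta[keep, ], report = report)
}

# vectorised per-row Welch t statistics; identical formulas to
# welch_t_test(), computed over matrix rows with pairwise NA handling
.row_welch <- function(m, idx_a, idx_b) {
  xa <- m[, idx_a, drop = FALSE]; xb <- m[, idx_b, drop = FALSE]
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  va <- rowSums((xa - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((xb - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  se2 <- va / na + vb / nb
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  # degenerate rows: both variances zero
  zero <- se2 == 0
  stat[zero] <- ifelse(ma[zero] == mb[zero], 0,
                       sign(ma[zero] - mb[zero]) * Inf)
  df[zero] <- (na + nb - 2)[zero]
  p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  list(n_a = na, n_b = nb, mean_a = ma, mean_b = mb,
       statistic = stat, df = df, p_raw = p)
}

#' Two-group differential methylation screen
#'
#' Per-probe Welch's t test of group A versus group B beta values,
#' combined with a delta-beta effect-size filter.  A probe is *selected*
#' when its (optionally Bonferroni-adjusted) p-value is below `alpha` and
#' its absolute group-mean difference exceeds `delta_threshold`; selected
#' probes are classified `hyper` (group A mean higher) or `hypo`.  The
#' Bonferroni family size is the number of probes actually tested in this
#' screen.
#'
#' Probes with fewer than 2 non-missing values in either group are skipped
#' (reported with `tested = FALSE`), not failed.
#'
#' @param beta A `BetaMatrix` (fraction scale).
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Apply Bonferroni correction across tested probes
#'   (default `TRUE`; the genome-wide tissue screens use it, the
#'   early-recurrence screen does not).
#' @param delta_threshold Minimum absolute delta-beta (default 0.10).
#' @return Object of class `"dmp_screen"`: a list with `results` (a
#'   data.frame: `probe_id`, `mean_a`, `mean_b`, `delta_beta`, `statistic`,
#'   `df`, `p_raw`, `p_adjusted`, `selected`, `direction`, `tested`),
#'   `counts` (`selected`, `hyper`, `hypo`, `tested`), and the screen
#'   settings.
#' @export
differential_screen <- function(beta, group_a, group_b, alpha = 0.05,
                                bonferroni = TRUE, delta_threshold = 0.10) {
  stopifnot(inherits(beta, "BetaMatrix"))
  if (length(intersect(group_a, group_b)))
    .pm_stop("groups overlap", "pm_invalid_input")
  sid <- sample_ids(beta)
  if (!all(c(group_a, group_b) %in% sid))
    .pm_stop("unknown sample id in group definition", "pm_invalid_input")
  if (length(group_a) < 2L || length(group_b) < 2L)
    .pm_stop("each group needs at least 2 samples", "pm_invalid_input")
  # fixed sample order inside each group so results are order-invariant
  ia <- match(sort(group_a), sid); ib <- match(sort(group_b), sid)
  w <- .row_welch(beta$beta, ia, ib)
  tested <- w$n_a >= 2 & w$n_b >= 2
  m <- sum(tested)
  if (m == 0) .pm_stop("no testable probes", "pm_invalid_input")
  p_adj <- rep(NA_real_, length(tested))
  p_adj[tested] <- bonferroni_adjust(w$p_raw[tested], m)
  p_use <- if (bonferroni) p_adj else w$p_raw
  delta <- w$mean_a - w$mean_b
  selected <- tested & p_use < alpha & abs(delta) > delta_threshold
  direction <- rep("none", length(tested))
  direction[selected] <- ifelse(delta[selected] > 0, "hyper", "hypo")
  res <- data.frame(probe_id = probe_ids(beta),
                    mean_a = w$mean_a, mean_b = w$mean_b,
                    delta_beta = delta,
                    statistic = w$statistic, df = w$df,
                    p_raw = w$p_raw, p_adjusted = p_adj,
                    selected = selected, direction = direction,
                    tested = tested,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(list(results = res,
                 counts = c(selected = sum(selected),
                            hyper = sum(direction == "hyper"),
                            hypo = sum(direction == "hypo"),
                            tested = m),
                 alpha = alpha, bonferroni = bonferroni,
                 delta_threshold = delta_threshold),
            class = "dmp_screen")
}

#' @export
print.dmp_screen <- function(x, ...) {
  cat("Differential methylation screen:", x$counts["tested"],
      "probes tested,", x$counts["selected"], "selected (",
      x$counts["hyper"], "hyper /", x$counts["hypo"], "hypo )\n")
  cat("  criteria:", if (x$bonferroni) "Bonferroni-adjusted" else "raw",
      "p <", x$alpha, "and |delta beta| >", x$delta_threshold, "\n")
  invisible(x)
}
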