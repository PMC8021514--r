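#' Assign early-recurrence labels
#'
#' Early recurrence (ER) is relapse within a fixed window after surgery,
#' by default 183 days (6 months).  A tumour patient is ER when
#' `recurrence` is `TRUE` and `rfs_days <= er_window_days`; patients who
#' relapse later, or never, are non-ER.  Patients with no recurrence whose
#' follow-up is shorter than the window cannot be classified with
#' certainty; they are counted non-ER but flagged `indeterminate`.
#'
#' @param clinical Clinical `data.frame` ([read_sample_sheet()]); only
#'   tissue-group `"T"` rows are labelled.
#' @param er_window_days ER window in days (default 183).
#' @return `data.frame` with `sample_id`, `patient_id`, `er` (logical),
#'   `basis` (`"recurrence_within_window"`, `"recurrence_after_window"`,
#'   `"no_recurrence"`), `indeterminate` (logical).
#' @export
assign_er_labels <- function(clinical, er_window_days = 183) {
  tt <- clinical[clinical$tissue_group == "T", , drop = FALSE]
  if (nrow(tt) == 0L)
    .pm_stop("no tumour (T) samples in the clinical table",
             "pm_invalid_input")
  if (anyNA(tt$recurrence))
    .pm_stop("recurrence status missing for tumour sample(s)",
             "pm_validation_error")
  if (any(tt$recurrence & is.na(tt$rfs_days)))
    .pm_stop("recurrence = TRUE requires rfs_days", "pm_validation_error")
  er <- tt$recurrence & tt$rfs_days <= er_window_days
  er[is.na(er)] <- FALSE
  basis <- ifelse(er, "recurrence_within_window",
                  ifelse(tt$recurrence, "recurrence_after_window",
                         "no_recurrence"))
  fup <- ifelse(is.na(tt$rfs_days), tt$os_days, tt$rfs_days)
  indet <- !tt$recurrence & (!is.na(fup) & fup < er_window_days |
                               is.na(fup))
  data.frame(sample_id = tt$sample_id, patient_id = tt$patient_id,
             er = er, basis = basis, indeterminate = indet,
             stringsAsFactors = FALSE)
}

#' Compare survival between the ER and non-ER groups
#'
#' Kaplan-Meier estimates of overall survival for the early-recurrence and
#' non-early-recurrence groups, with a log-rank test of their difference.
#'
#' @param er_labels Output of [assign_er_labels()] (or any data.frame with
#'   `sample_id` and logical `er`).
#' @param clinical Clinical table with `sample_id`, `os_days`, `dead`.
#' @return Object of class `"pm_survcomp"`: list with `km_er`, `km_non_er`
#'   ([km_estimate()] fits), `test` (log-rank `"pm_test"`), `n`.
#' @export
compare_survival <- function(er_labels, clinical) {
  d <- merge(er_labels[, c("sample_id", "er")],
             clinical[, c("sample_id", "os_days", "dead")],
             by = "sample_id")
  d <- d[!is.na(d$os_days) & !is.na(d$dead), ]
  if (!any(d$er) || !all(d$er))
    if (sum(d$er) == 0 || sum(!d$er) == 0)
      .pm_stop("both ER and non-ER groups must be represented",
               "pm_invalid_input")
  a <- d[d$er, ]; b <- d[!d$er, ]
  structure(list(km_er = km_estimate(a$os_days, a$dead),
                 km_non_er = km_estimate(b$os_days, b$dead),
                 test = log_rank_test(a$os_days, a$dead,
                                      b$os_days, b$dead),
                 n = c(er = nrow(a), non_er = nrow(b))),
            class = "pm_survcomp")
}

#' @export
print.pm_survcomp <- function(x, ...) {
  cat("Overall survival, ER (n =", x$n["er"], ") vs non-ER (n =",
      x$n["non_er"], ")\n")
  cat("  median OS: ER",
      if (is.na(x$km_er$median)) "not reached" else x$km_er$median,
      "days; non-ER",
      if (is.na(x$km_non_er$median)) "not reached" else x$km_non_er$median,
      "days\n")
  cat("  log-rank chi-square =", format(x$test$statistic, digits = 4),
      ", p =", format.pval(x$test$p_raw, digits = 3), "\n")
  invisible(x)
}

#' @export
plot.pm_survcomp <- function(x, ...) {
  plot(x$km_non_er, col = "black",
       main = sprintf("log-rank p = %.2g", x$test$p_raw), ...)
  plot(x$km_er, add = TRUE, col = "red")
  graphics::legend("bottomleft", c("non-ER", "ER"), col = c("black", "red"),
                   lty = 1, bty = "n")
  invisible(x)
}
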