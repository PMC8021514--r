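#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survivor function S(t) from right-censored times, e.g.
#' overall or recurrence-free survival after pancreatectomy.  The median is
#' the smallest observed event time at which S(t) drops to 0.5 or below;
#' it is `NA` when the curve never reaches 0.5.
#'
#' @param time Non-negative follow-up times (days).
#' @param event Logical (or 0/1): `TRUE` when the event (death, relapse)
#'   was observed, `FALSE` when censored.
#' @return Object of class `"pm_km"`: list with `time` (distinct event
#'   times), `n_risk`, `n_event`, `surv` (S immediately after each event
#'   time), `median`, and `n`.
#' @examples
#' km_estimate(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
#' @export
km_estimate <- function(time, event) {
  event <- as.logical(event)
  if (length(time) == 0L) .pm_stop("no samples", "pm_invalid_input")
  if (length(time) != length(event) || anyNA(time) || anyNA(event))
    .pm_stop("time and event must be complete and of equal length",
             "pm_invalid_input")
  if (any(time < 0)) .pm_stop("negative survival time", "pm_invalid_input")
  et <- sort(unique(time[event]))
  n_risk <- vapply(et, function(t) sum(time >= t), 0)
  n_event <- vapply(et, function(t) sum(time == t & event), 0)
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) et[which(surv <= 0.5)[1L]] else NA_real_
  structure(list(time = et, n_risk = n_risk, n_event = n_event,
                 surv = surv, median = med, n = length(time)),
            class = "pm_km")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param fit A `"pm_km"` object.
#' @param t Times at which to evaluate S(t).
#' @return Survival probabilities; S(t) = 1 before the first event.
#' @export
km_surv_at <- function(fit, t) {
  stopifnot(inherits(fit, "pm_km"))
  vapply(t, function(ti) {
    i <- which(fit$time <= ti)
    if (length(i) == 0L) 1 else fit$surv[max(i)]
  }, 0)
}

#' @export
print.pm_km <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, ",",
      sum(x$n_event), "events\n")
  cat("median survival:",
      if (is.na(x$median)) "not reached" else format(x$median), "\n")
  invisible(x)
}

#' @export
plot.pm_km <- function(x, add = FALSE, ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[-2 * length(x$surv)])
  if (add) graphics::lines(tt, ss, ...)
  else graphics::plot(tt, ss, type = "l", ylim = c(0, 1),
                      xlab = "time (days)", ylab = "S(t)", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Compares the survival experience of two groups (e.g. early-recurrence vs
#' non-early-recurrence patients) by the standard log-rank chi-square on
#' 1 degree of freedom: observed minus expected events in group A summed
#' over the pooled distinct event times, scaled by the hypergeometric
#' variance.
#'
#' @param time_a,event_a Times and event indicators of group A.
#' @param time_b,event_b Times and event indicators of group B.
#' @return A `"pm_test"` with the chi-square `statistic`, `df` = 1, and
#'   `p_raw`.  Symmetric in the two groups.
#' @export
log_rank_test <- function(time_a, event_a, time_b, event_b) {
  event_a <- as.logical(event_a); event_b <- as.logical(event_b)
  if (length(time_a) == 0L || length(time_b) == 0L)
    .pm_stop("both groups must be non-empty", "pm_invalid_input")
  if (any(c(time_a, time_b) < 0))
    .pm_stop("negative survival time", "pm_invalid_input")
  if (!any(event_a) && !any(event_b))
    .pm_stop("log-rank test undefined: no events in either group",
             "pm_undefined_test")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  et <- sort(unique(time[event]))
  o_a <- e_a <- v <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & grp_a)
    d <- sum(time == t & event)
    d_a <- sum(time == t & event & grp_a)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  if (v == 0)
    return(pm_test(statistic = 0, df = 1, p_raw = 1))
  chisq <- (o_a - e_a)^2 / v
  pm_test(statistic = chisq, df = 1,
          p_raw = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}
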