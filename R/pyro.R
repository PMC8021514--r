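#' Merge duplicate/triplicate pyrosequencing measurements
#'
#' Pyrosequencing is run in duplicate; the mean of the two measurements is
#' the quantitative value.  When the two differ by more than
#' `discordance_threshold` percentage points, a third replicate is
#' required and the mean of the three is used instead.
#'
#' @param values 2 or 3 replicate measurements in percent (\[0, 100\]).
#' @param discordance_threshold Maximum tolerated absolute difference of a
#'   duplicate pair, in percentage points (default 10).
#' @return List of class `"pyro_merge"`: `value` (the merged percent, or
#'   `NA` while a third replicate is still needed), `needs_third`
#'   (logical), `n_used`.
#' @examples
#' merge_replicates(c(30, 32))          # 31
#' merge_replicates(c(30, 45))          # needs a third replicate
#' merge_replicates(c(30, 45, 33))      # 36
#' @export
merge_replicates <- function(values, discordance_threshold = 10) {
  values <- values[!is.na(values)]
  if (length(values) < 2L || length(values) > 3L)
    .pm_stop("need 2 or 3 replicate measurements", "pm_invalid_input")
  if (any(values < 0 | values > 100))
    .pm_stop("replicates must be percentages in [0, 100]",
             "pm_invalid_input")
  if (length(values) == 2L && abs(values[1] - values[2]) >
      discordance_threshold)
    return(structure(list(value = NA_real_, needs_third = TRUE,
                          n_used = 2L), class = "pyro_merge"))
  structure(list(value = mean(values), needs_third = FALSE,
                 n_used = length(values)),
            class = "pyro_merge")
}

#' @export
print.pyro_merge <- function(x, ...) {
  if (x$needs_third)
    cat("discordant duplicate: third replicate required\n")
  else
    cat("merged value:", x$value, "(mean of", x$n_used, "replicates)\n")
  invisible(x)
}

#' Merge a table of simulated or measured pyro replicates
#'
#' Applies [merge_replicates()] row-wise to a replicate table (columns
#' `rep1`, `rep2`, optional `rep3`).
#'
#' @param tab `data.frame` as from [simulate_pyro_replicates()].
#' @param discordance_threshold Passed to [merge_replicates()].
#' @return Numeric vector of merged values (`NA` where a needed third
#'   replicate is absent).
#' @export
merge_replicate_table <- function(tab, discordance_threshold = 10) {
  vapply(seq_len(nrow(tab)), function(i) {
    v <- c(tab$rep1[i], tab$rep2[i],
           if ("rep3" %in% names(tab)) tab$rep3[i])
    merge_replicates(v, discordance_threshold)$value
  }, 0)
}

#' Platform concordance between pyrosequencing and array measurements
#'
#' Pearson correlation between pyrosequencing percentages and
#' percent-scaled array beta values for one probe over paired samples;
#' used to verify that array screening results hold up on the
#' quantitative platform.
#'
#' @param pyro Pyro percentages, named by sample id or aligned.
#' @param beta_values Array beta values of the same samples (fraction
#'   scale unless `beta_scale = "percent"`).
#' @param probe_id Probe label carried in the result.
#' @param beta_scale Scale of `beta_values`.
#' @return List with `probe_id`, `pearson_r`, `n`.
#' @export
concordance_check <- function(pyro, beta_values, probe_id = NA_character_,
                              beta_scale = c("fraction", "percent")) {
  beta_scale <- match.arg(beta_scale)
  b <- convert_scale(beta_values, to = "percent", from = beta_scale)
  ok <- !(is.na(pyro) | is.na(b))
  r <- pearson_correlation(pyro[ok], b[ok])
  list(probe_id = probe_id, pearson_r = r, n = sum(ok))
}

#' Check calibration linearity of a pyrosequencing assay
#'
#' Fits the least-squares line through measurements of fully unmethylated,
#' half-methylated and fully methylated control DNA (nominal 0 / 50 / 100
#' percent) and reports the slope, intercept and the largest absolute
#' residual.  The assay is considered linear when the slope is within
#' `slope_tol` of 1 and no residual exceeds `max_dev`.
#'
#' @param measured Measured percentages at the control inputs.
#' @param nominal Nominal control inputs (default `c(0, 50, 100)`).
#' @param slope_tol Allowed deviation of the slope from 1 (default 0.2).
#' @param max_dev Allowed absolute residual in points (default 10).
#' @return List with `slope`, `intercept`, `max_abs_residual`, `ok`.
#' @export
calibration_linearity <- function(measured, nominal = c(0, 50, 100),
                                  slope_tol = 0.2, max_dev = 10) {
  if (length(measured) != length(nominal) || length(measured) < 3L)
    .pm_stop("need one measurement per control input (>= 3)",
             "pm_invalid_input")
  fit <- stats::lm(measured ~ nominal)
  slope <- unname(stats::coef(fit)[2])
  icpt <- unname(stats::coef(fit)[1])
  mdev <- max(abs(stats::resid(fit)))
  list(slope = slope, intercept = icpt, max_abs_residual = mdev,
       ok = abs(slope - 1) <= slope_tol && mdev <= max_dev)
}
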