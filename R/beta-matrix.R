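#' Construct a beta-value matrix
#'
#' Container for Infinium-style methylation data: a probes x samples matrix
#' of beta values (methylated signal over total signal, in \[0, 1\]) with an
#' optional aligned matrix of detection p-values.  Missing betas are
#' allowed; the screening code excludes them pairwise.
#'
#' @param beta Numeric matrix, probes in rows, samples in columns; must
#'   carry unique rownames (probe ids) and colnames (sample ids).
#' @param detection_p Optional matrix of detection p-values with identical
#'   dimnames, giving the probability that a probe's signal is background
#'   noise in a given sample.
#' @param scale `"fraction"` (values in \[0,1\], the canonical internal
#'   scale) or `"percent"`.
#' @return Object of class `"BetaMatrix"`.
#' @export
beta_matrix <- function(beta, detection_p = NULL,
                        scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  if (!is.matrix(beta)) beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  pid <- rownames(beta); sid <- colnames(beta)
  if (is.null(pid) || is.null(sid))
    .pm_stop("beta must have probe rownames and sample colnames",
             "pm_invalid_input")
  if (anyDuplicated(pid))
    .pm_stop("duplicate probe ids", "pm_invalid_input")
  if (anyDuplicated(sid))
    .pm_stop("duplicate sample ids", "pm_invalid_input")
  hi <- if (scale == "fraction") 1 else 100
  bad <- which(!is.na(beta) & (beta < -1e-9 | beta > hi + 1e-9))
  if (length(bad))
    .pm_stop(sprintf("beta value out of [0, %g] at %d cell(s), first: %s / %s",
                     hi, length(bad),
                     pid[(bad[1] - 1) %% nrow(beta) + 1],
                     sid[(bad[1] - 1) %/% nrow(beta) + 1]),
             "pm_format_error")
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(beta)) ||
        !identical(dimnames(detection_p), dimnames(beta)))
      .pm_stop("detection_p must have the same shape and dimnames as beta",
               "pm_invalid_input")
    if (any(!is.na(detection_p) &
            (detection_p < 0 | detection_p > 1)))
      .pm_stop("detection p-values must lie in [0, 1]", "pm_format_error")
  }
  structure(list(beta = beta, detection_p = detection_p, scale = scale),
            class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat("BetaMatrix:", nrow(x$beta), "probes x", ncol(x$beta), "samples",
      sprintf("(%s scale)", x$scale),
      if (is.null(x$detection_p)) "without" else "with",
      "detection p-values\n")
  invisible(x)
}

#' @export
dim.BetaMatrix <- function(x) dim(x$beta)

#' Subset a BetaMatrix by probes and/or samples
#'
#' @param x A `BetaMatrix`.
#' @param i Probe ids or indices (missing = all).
#' @param j Sample ids or indices (missing = all).
#' @param ... Ignored.
#' @return A `BetaMatrix` restricted to the requested probes/samples.
#' @export
`[.BetaMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$beta))
  if (missing(j)) j <- seq_len(ncol(x$beta))
  beta_matrix(x$beta[i, j, drop = FALSE],
              if (!is.null(x$detection_p))
                x$detection_p[i, j, drop = FALSE],
              scale = x$scale)
}

probe_ids  <- function(x) rownames(x$beta)
sample_ids <- function(x) colnames(x$beta)

#' Convert methylation values between fraction and percent scales
#'
#' Beta values are fractions in \[0, 1\] internally; pyrosequencing data and
#' published cut-offs are percentages.  This converts a scalar, vector,
#' matrix or `BetaMatrix` between the two scales (a factor of 100) and is
#' idempotent when the value is already on the target scale.
#'
#' @param x Numeric values or a `BetaMatrix`.
#' @param to Target scale, `"fraction"` or `"percent"`.
#' @param from Current scale; for a `BetaMatrix` the default is its own
#'   declared scale, otherwise `"fraction"`.
#' @return Same shape as the input, on the target scale.
#' @examples
#' convert_scale(0.235, to = "percent")  # 23.5
#' @export
convert_scale <- function(x, to = c("fraction", "percent"), from = NULL) {
  to <- match.arg(to)
  if (inherits(x, "BetaMatrix")) {
    from <- if (is.null(from)) x$scale else match.arg(from, c("fraction", "percent"))
    if (from == to) return(x)
    f <- if (to == "percent") 100 else 0.01
    return(beta_matrix(x$beta * f, x$detection_p, scale = to))
  }
  from <- if (is.null(from)) "fraction" else match.arg(from, c("fraction", "percent"))
  if (from == to) return(x)
  if (to == "percent") x * 100 else x / 100
}
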