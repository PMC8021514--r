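#' Principal component analysis of samples over a probe subset
#'
#' Projects samples onto principal components of their methylation
#' profiles restricted to a probe subset (typically the aberrantly
#' methylated probes from a differential screen).  Probes are mean-centred
#' but not variance-scaled, since beta values share a common \[0, 1\]
#' scale.  Component signs are fixed by making the largest-magnitude
#' loading of each component positive, so projections are reproducible
#' across runs and platforms.
#'
#' @param beta A `BetaMatrix`.
#' @param probes Probe ids to use (default: all).
#' @param n_components Number of components to return (default
#'   `min(n_samples - 1, n_probes)`).
#' @return Object of class `"pm_pca"`: list with `scores` (samples x
#'   components), `loadings`, `explained` (variance fractions,
#'   non-increasing), `center`.
#' @export
pca_project <- function(beta, probes = NULL, n_components = NULL) {
  stopifnot(inherits(beta, "BetaMatrix"))
  if (is.null(probes)) probes <- probe_ids(beta)
  if (length(probes) == 0L)
    .pm_stop("empty probe subset", "pm_invalid_input")
  if (!all(probes %in% probe_ids(beta)))
    .pm_stop("unknown probe id in subset", "pm_invalid_input")
  x <- t(beta$beta[probes, , drop = FALSE])   # samples x probes
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp || n_components < 1L)
    .pm_stop(sprintf("n_components must be in 1..%d", max_comp),
             "pm_invalid_input")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- pc$rotation[, k, drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  flip <- vapply(k, function(j) {
    l <- rot[, j]; sign(l[which.max(abs(l))])
  }, 0)
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(pc$x[, k, drop = FALSE], 2, flip, `*`)
  total_var <- sum(pc$sdev^2)
  structure(list(scores = scores, loadings = rot,
                 explained = pc$sdev[k]^2 / total_var,
                 center = pc$center),
            class = "pm_pca")
}

#' @export
print.pm_pca <- function(x, ...) {
  cat("PCA projection:", nrow(x$scores), "samples,",
      ncol(x$scores), "components\n")
  cat("explained variance:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
             collapse = ", "),
      if (length(x$explained) > 5) "...", "\n")
  invisible(x)
}

#' @export
plot.pm_pca <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$scores[, 1], x$scores[, 2], col = col,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  invisible(x)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of samples by Ward's minimum-variance
#' objective on Euclidean distances between methylation profiles (the
#' "Ward on Euclidean distances" convention, `hclust` method `ward.D2`),
#' cut to exactly `k` clusters.  Samples are processed in sorted
#' sample-id order, so the partition and its labels do not depend on the
#' input column order; clusters are numbered 1..k by first appearance in
#' that order.
#'
#' @param beta A `BetaMatrix`.
#' @param probes Probe ids to cluster on (default: all).
#' @param k Number of clusters (default 4).
#' @return Object of class `"pm_clusters"`: list with `cluster` (named
#'   integer vector, sample id to label), `k`, `merge`, `height` (the
#'   agglomeration history), `method`.
#' @export
ward_cluster <- function(beta, probes = NULL, k = 4L) {
  stopifnot(inherits(beta, "BetaMatrix"))
  if (is.null(probes)) probes <- probe_ids(beta)
  if (!all(probes %in% probe_ids(beta)))
    .pm_stop("unknown probe id in subset", "pm_invalid_input")
  sid <- sort(sample_ids(beta))
  if (k > length(sid) || k < 1L)
    .pm_stop("k must be between 1 and the number of samples",
             "pm_invalid_input")
  x <- t(beta$beta[probes, sid, drop = FALSE])
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  # canonical labels: order of first appearance over sorted sample ids
  lab <- match(raw, unique(raw))
  names(lab) <- sid
  structure(list(cluster = lab, k = as.integer(k),
                 merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels,
                 method = "ward.D2 on Euclidean distances"),
            class = "pm_clusters")
}

#' @export
print.pm_clusters <- function(x, ...) {
  cat("Ward clustering (", x$method, "): k =", x$k, "\n")
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Cluster-versus-clinical-factor association
#'
#' Tests whether a binary grouping of samples (e.g. a post-hoc merge of
#' epigenotype clusters into two super-groups) is associated with a binary
#' clinical factor (e.g. early recurrence), by Fisher's exact test on the
#' 2x2 table.  Also reports the factor incidence within each group as a
#' percentage to 1 decimal.
#'
#' @param group Binary grouping: logical vector, or a factor/character
#'   with exactly 2 levels, named by or aligned with `factor_pos`.
#' @param factor_pos Binary clinical factor (logical).
#' @return List with `table` (2x2: group levels x factor yes/no), `test`
#'   (a `"pm_test"` from [fisher_exact_2x2()]), and `incidence_pct`
#'   (named, per group level).
#' @export
associate_clusters <- function(group, factor_pos) {
  if (is.logical(group)) group <- ifelse(group, "group1", "group2")
  group <- as.factor(group)
  if (nlevels(group) != 2L)
    .pm_stop("grouping must have exactly 2 levels", "pm_invalid_input")
  factor_pos <- as.logical(factor_pos)
  if (length(group) != length(factor_pos) || anyNA(factor_pos) ||
      anyNA(group))
    .pm_stop("group and factor must be complete and aligned",
             "pm_invalid_input")
  tab <- table(group, factor = factor(factor_pos, c(TRUE, FALSE),
                                      c("yes", "no")))
  inc <- round(100 * tab[, "yes"] / rowSums(tab), 1)
  list(table = tab,
       test = fisher_exact_2x2(matrix(as.integer(tab), 2)),
       incidence_pct = stats::setNames(as.numeric(inc), rownames(tab)))
}

#' Merge cluster labels into super-groups
#'
#' Convenience for the post-hoc combination of clusters with similar
#' clinical tendencies, e.g. `merge_clusters(cl, list(AB3 = c(1, 4),
#' B1B2 = c(2, 3)))`.
#'
#' @param clusters A `"pm_clusters"` object or named integer vector.
#' @param mapping Named list: super-group name -> cluster labels.
#' @return Named character vector of super-group labels per sample.
#' @export
merge_clusters <- function(clusters, mapping) {
  cl <- if (inherits(clusters, "pm_clusters")) clusters$cluster else clusters
  out <- rep(NA_character_, length(cl))
  for (nm in names(mapping)) out[cl %in% mapping[[nm]]] <- nm
  if (anyNA(out))
    .pm_stop("mapping does not cover every cluster label",
             "pm_invalid_input")
  stats::setNames(out, names(cl))
}
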