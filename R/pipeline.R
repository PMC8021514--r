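#' Pipeline configuration
#'
#' Collects the thresholds and paths of a full analysis run.  Defaults
#' mirror the published analysis settings: detection p < 0.01, 90% call
#' proportion, Bonferroni-corrected p < 0.05 with |delta beta| > 0.1 for
#' the tissue screens, a raw-p marker screen with AUC > 0.7, a 183-day
#' early-recurrence window, 4 epigenotype clusters, and a 2-of-3 voting
#' panel.
#'
#' @param beta,detection_p,manifest,samples Optional input file paths; when
#'   all are `NULL` the pipeline runs on a simulated cohort.
#' @param outdir Output directory (default `tempfile("pdacmeth_run")`).
#' @param detection_alpha,call_prop_min QC thresholds.
#' @param alpha,delta Screen thresholds.
#' @param auc_min Marker AUC threshold.
#' @param er_window_days ER window.
#' @param k Number of epigenotype clusters.
#' @param panel_min_positive Voting threshold of the panel.
#' @param n_markers Panel size.
#' @param seed Seed for simulated inputs.
#' @param sim Simulation settings ([sim_config()]) used when no input
#'   files are given.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(beta = NULL, detection_p = NULL,
                            manifest = NULL, samples = NULL,
                            outdir = tempfile("pdacmeth_run"),
                            detection_alpha = 0.01, call_prop_min = 0.90,
                            alpha = 0.05, delta = 0.10, auc_min = 0.70,
                            er_window_days = 183, k = 4L,
                            panel_min_positive = 2L, n_markers = 3L,
                            seed = 1L, sim = NULL) {
  stopifnot(detection_alpha > 0, detection_alpha <= 1,
            call_prop_min >= 0, call_prop_min <= 1,
            alpha > 0, alpha <= 1, delta >= 0, delta < 1,
            auc_min >= 0, auc_min < 1, er_window_days > 0, k >= 1,
            panel_min_positive >= 1)
  structure(list(beta = beta, detection_p = detection_p,
                 manifest = manifest, samples = samples, outdir = outdir,
                 detection_alpha = detection_alpha,
                 call_prop_min = call_prop_min, alpha = alpha,
                 delta = delta, auc_min = auc_min,
                 er_window_days = er_window_days, k = as.integer(k),
                 panel_min_positive = as.integer(panel_min_positive),
                 n_markers = as.integer(n_markers),
                 seed = as.integer(seed),
                 sim = if (is.null(sim)) sim_config(seed = seed) else sim),
            class = "pipeline_config")
}

#' Run the full methylation analysis pipeline
#'
#' Chains every stage on a cohort: probe QC, the tumour-versus-control and
#' tumour-versus-non-cancerous differential screens, PCA, Ward clustering
#' of tumours with cluster-versus-ER association, ER survival comparison,
#' and the marker-panel fit.  When the configuration names no input files
#' the stages run on a simulated cohort with planted truth, which makes
#' the pipeline exercisable end-to-end without external data.
#'
#' Artifacts (QC report, screen tables, cluster assignment, panel
#' criteria and evaluation, and a JSON run manifest with the
#' configuration echo, package version, seed and input checksums) are
#' written under `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results: `dataset`, `qc`,
#'   `screen_TvsC`, `screen_TvsN`, `pca`, `clusters`, `association`,
#'   `survival`, `panel`, and `truth` (simulated inputs only).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (is.null(config$beta)) {
    sim <- simulate_cohort(config$sim)
    ds <- sim$dataset; truth <- sim$truth
  } else {
    bm <- read_beta_matrix(config$beta,
                           detection_p_path = config$detection_p)
    ds <- cohort_dataset(bm, read_probe_annotation(config$manifest),
                         read_sample_sheet(config$samples))
  }
  qc <- filter_probes(ds$beta, ds$annotation,
                      call_prop_min = config$call_prop_min,
                      detection_alpha = config$detection_alpha,
                      require_detection = !is.null(ds$beta$detection_p))
  cl <- ds$clinical
  ids <- split(cl$sample_id, cl$tissue_group)
  s_tc <- differential_screen(qc$beta, ids$T, ids$C, alpha = config$alpha,
                              bonferroni = TRUE,
                              delta_threshold = config$delta)
  s_tn <- differential_screen(qc$beta, ids$T, ids$N, alpha = config$alpha,
                              bonferroni = TRUE,
                              delta_threshold = config$delta)
  aberrant_tc <- s_tc$results$probe_id[s_tc$results$selected]
  aberrant_tn <- s_tn$results$probe_id[s_tn$results$selected]
  pca <- if (length(aberrant_tc) >= 2)
    pca_project(qc$beta, aberrant_tc,
                n_components = min(10L, length(aberrant_tc),
                                   ncol(qc$beta$beta) - 1L)) else NULL
  tum <- qc$beta[, ids$T]
  clus <- if (length(aberrant_tn) >= 2)
    ward_cluster(tum, aberrant_tn, k = config$k) else NULL
  er <- assign_er_labels(cl, config$er_window_days)
  assoc <- NULL
  if (!is.null(clus)) {
    er_by_cluster <- tapply(er$er[match(names(clus$cluster),
                                        er$sample_id)], clus$cluster, mean)
    hi <- as.integer(names(sort(er_by_cluster, decreasing = TRUE)))
    grp <- merge_clusters(clus, list(
      high_er = hi[seq_len(ceiling(clus$k / 2))],
      low_er = hi[-seq_len(ceiling(clus$k / 2))]))
    assoc <- associate_clusters(grp,
                                er$er[match(names(grp), er$sample_id)])
  }
  surv <- compare_survival(er, cl)
  panel <- tryCatch(
    fit_er_panel(tum, er, alpha = config$alpha,
                 delta_threshold = config$delta,
                 auc_min = config$auc_min,
                 n_markers = config$n_markers,
                 min_positive = config$panel_min_positive),
    pm_empty_panel = function(e) NULL)

  # artifacts
  qc_df <- data.frame(probe_id = names(qc$report$excluded_by),
                      call_proportion = qc$report$call_proportion,
                      excluded_by = qc$report$excluded_by)
  write_results_table(qc_df, file.path(config$outdir, "qc_report.tsv"))
  write_results_table(s_tc$results,
                      file.path(config$outdir, "screen_T_vs_C.tsv"))
  write_results_table(s_tn$results,
                      file.path(config$outdir, "screen_T_vs_N.tsv"))
  if (!is.null(clus))
    write_results_table(data.frame(sample_id = names(clus$cluster),
                                   cluster = clus$cluster),
                        file.path(config$outdir, "clusters.tsv"))
  if (!is.null(panel)) {
    write_results_table(panel$criteria,
                        file.path(config$outdir, "panel_criteria.tsv"))
    write_results_table(as.data.frame(panel$training_eval),
                        file.path(config$outdir, "panel_eval.tsv"))
  }
  inputs <- unlist(config[c("beta", "detection_p", "manifest", "samples")])
  manifest <- list(
    package = "pdacmeth",
    version = as.character(utils::packageVersion("pdacmeth")),
    seed = config$seed,
    config = unclass(config[setdiff(names(config), "sim")]),
    sim = if (is.null(config$beta)) unclass(config$sim),
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(dataset = ds, qc = qc, screen_TvsC = s_tc,
                 screen_TvsN = s_tn, pca = pca, clusters = clus,
                 association = assoc, survival = surv, panel = panel,
                 truth = truth))
}
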