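#' Simulation configuration
#'
#' Parameters of the synthetic methylation cohort.  Defaults mirror the
#' design of the tissue study the pipeline targets: 17 normal-control (C),
#' 34 non-cancerous (N) and 82 tumour (T) samples, with 22 of the 82
#' tumour patients relapsing early (recurrence within the 6-month window).
#'
#' Background betas are drawn per probe from a two-component Beta mixture
#' (a hypomethylated and a hypermethylated mode) so values live natively in
#' \[0, 1\] and show the bimodality typical of 450K arrays.  Planted
#' differential probes shift the *mean* of the affected group through the
#' Beta shape parameters at fixed concentration, rather than by additive
#' offset, which avoids probability mass piling up at the clip boundaries.
#'
#' @param n_C,n_N,n_T Samples per tissue group.
#' @param n_probes Total probes on the synthetic array.
#' @param n_planted_TvsC,n_planted_TvsN Probes with a planted T-group mean
#'   shift of `delta_planted` (half hyper-, half hypomethylated in T).
#' @param n_planted_ER Probes whose T-sample mean differs by `delta_ER`
#'   between early-recurrence and non-early-recurrence patients.
#' @param delta_planted Planted group-mean beta difference for the
#'   tissue-level screens (default 0.30).
#' @param delta_ER Planted ER-marker effect size (default 0.15).
#' @param er_fraction Fraction of T patients with early recurrence
#'   (default 22/82); the realised count is `round(er_fraction * n_T)`.
#' @param beta_shape_low,beta_shape_high Shape parameters of the background
#'   mixture components Beta(low, high) (unmethylated mode, mean
#'   low/(low+high)) and Beta(high, low) (methylated mode).  The defaults
#'   give modes at 0.2 and 0.8 with a per-group SD of about 0.07 at
#'   mid-range betas, typical inter-sample variability on 450K arrays.
#' @param qc_fail_fraction Fraction of probes planted as detection
#'   failures (detection p above 0.01 in well over 10% of samples).
#' @param sex_probe_fraction Fraction of probes annotated on chromosome
#'   X or Y.
#' @param seed Integer seed; fixes every byte of the simulated cohort.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n_C = 17L, n_N = 34L, n_T = 82L,
                       n_probes = 5000L,
                       n_planted_TvsC = 100L, n_planted_TvsN = 100L,
                       n_planted_ER = 3L,
                       delta_planted = 0.30, delta_ER = 0.15,
                       er_fraction = 22 / 82,
                       beta_shape_low = 7.2, beta_shape_high = 28.8,
                       qc_fail_fraction = 0.01,
                       sex_probe_fraction = 0.02,
                       seed = 1L) {
  cfg <- list(n_C = as.integer(n_C), n_N = as.integer(n_N),
              n_T = as.integer(n_T), n_probes = as.integer(n_probes),
              n_planted_TvsC = as.integer(n_planted_TvsC),
              n_planted_TvsN = as.integer(n_planted_TvsN),
              n_planted_ER = as.integer(n_planted_ER),
              delta_planted = delta_planted, delta_ER = delta_ER,
              er_fraction = er_fraction,
              beta_shape_low = beta_shape_low,
              beta_shape_high = beta_shape_high,
              qc_fail_fraction = qc_fail_fraction,
              sex_probe_fraction = sex_probe_fraction,
              seed = as.integer(seed))
  n_special <- cfg$n_planted_TvsC + cfg$n_planted_TvsN + cfg$n_planted_ER +
    round(cfg$qc_fail_fraction * cfg$n_probes) +
    round(cfg$sex_probe_fraction * cfg$n_probes)
  if (n_special > cfg$n_probes)
    .pm_stop("infeasible config: planted + QC-fail + sex probes exceed n_probes",
             "pm_invalid_config")
  if (any(unlist(cfg[c("delta_planted", "delta_ER", "er_fraction",
                       "qc_fail_fraction", "sex_probe_fraction")]) < 0))
    .pm_stop("fractions must be non-negative", "pm_invalid_config")
  structure(cfg, class = "sim_config")
}

# shift a Beta(a, b) mean by delta at constant concentration a + b,
# clamping the target mean away from the boundary; planted probes are
# assigned to the background component with headroom, so the clamp is a
# safety net rather than the norm and realized deltas are unbiased
.shift_shapes <- function(a, b, delta) {
  nu <- a + b
  mu <- min(max(a / nu + delta, 0.02), 0.98)
  c(mu * nu, (1 - mu) * nu)
}

#' Simulate a methylation cohort with planted ground truth
#'
#' Draws a full synthetic dataset under `config`: a beta matrix with
#' detection p-values, an annotation table, and a clinical sheet, together
#' with the per-probe/per-sample planted truth needed for recovery tests.
#'
#' Probe roles (disjoint): `hyper_TvsC`/`hypo_TvsC` probes shift the
#' T-group mean by +/- `delta_planted`; `hyper_TvsN`/`hypo_TvsN` likewise
#' (both sets shift T relative to the C and N background); `er_low`/
#' `er_high` probes shift the mean of early-recurrence T samples by
#' -/+ `delta_ER`; `qc_fail` probes receive detection p-values above 0.01
#' in roughly 30% of samples (at least 10% + 1 enforced); `sex_chromosome`
#' probes are annotated on X or Y; all remaining probes are null.
#'
#' Clinical records: ER patients relapse at 60-180 days and die at
#' RFS + 100-400 days; non-ER patients either relapse late (200-1500 days)
#' or are censored without recurrence, with overall survival always at or
#' after relapse.  C/N samples carry no recurrence data.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a [cohort_dataset()]) and `truth` (list:
#'   `probe_label` named character vector, `er` named logical vector over
#'   T sample ids, `config`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_probes
  n_qc <- round(config$qc_fail_fraction * np)
  n_sex <- round(config$sex_probe_fraction * np)

  # disjoint probe-role blocks, then shuffled so roles are not positional
  lab <- rep("null", np)
  i <- 0L
  take <- function(n) { r <- i + seq_len(n); i <<- i + n; r }
  tvc <- take(config$n_planted_TvsC)
  lab[tvc] <- rep(c("hyper_TvsC", "hypo_TvsC"), length.out = length(tvc))
  tvn <- take(config$n_planted_TvsN)
  lab[tvn] <- rep(c("hyper_TvsN", "hypo_TvsN"), length.out = length(tvn))
  er <- take(config$n_planted_ER)
  lab[er] <- ifelse(seq_along(er) %% 6 == 0, "er_high", "er_low")
  lab[take(n_qc)] <- "qc_fail"
  lab[take(n_sex)] <- "sex_chromosome"
  lab <- sample(lab)
  probe_id <- sprintf("cgs%07d", seq_len(np))
  names(lab) <- probe_id

  sid_C <- sprintf("C%02d", seq_len(config$n_C))
  sid_N <- sprintf("N%02d", seq_len(config$n_N))
  sid_T <- sprintf("T%02d", seq_len(config$n_T))
  sid <- c(sid_C, sid_N, sid_T)
  ns <- length(sid)

  n_er <- round(config$er_fraction * config$n_T)
  er_status <- sample(rep(c(TRUE, FALSE), c(n_er, config$n_T - n_er)))
  names(er_status) <- sid_T

  # background mixture component per probe; planted probes start in the
  # component with headroom for their shift (hypermethylation is planted
  # on unmethylated-mode probes and vice versa), so realized group-mean
  # differences match the configured delta without boundary clipping
  a_lo <- config$beta_shape_low; a_hi <- config$beta_shape_high
  comp_hi <- stats::runif(np) < 0.5
  comp_hi[lab %in% c("hyper_TvsC", "hyper_TvsN", "er_high")] <- FALSE
  comp_hi[lab %in% c("hypo_TvsC", "hypo_TvsN", "er_low")] <- TRUE
  base_a <- ifelse(comp_hi, a_hi, a_lo)
  base_b <- ifelse(comp_hi, a_lo, a_hi)

  idx_T <- match(sid_T, sid)
  idx_er <- idx_T[er_status]
  beta <- matrix(NA_real_, np, ns, dimnames = list(probe_id, sid))
  for (p in seq_len(np)) {
    a <- base_a[p]; b <- base_b[p]
    row <- stats::rbeta(ns, a, b)
    l <- lab[p]
    if (l %in% c("hyper_TvsC", "hypo_TvsC", "hyper_TvsN", "hypo_TvsN")) {
      d <- if (startsWith(l, "hyper")) config$delta_planted else
        -config$delta_planted
      sh <- .shift_shapes(a, b, d)
      row[idx_T] <- stats::rbeta(length(idx_T), sh[1], sh[2])
    } else if (l %in% c("er_low", "er_high")) {
      d <- if (l == "er_high") config$delta_ER else -config$delta_ER
      sh <- .shift_shapes(a, b, d)
      row[idx_er] <- stats::rbeta(length(idx_er), sh[1], sh[2])
    }
    beta[p, ] <- row
  }

  # detection p-values: clean probes essentially always called; qc_fail
  # probes fail (p > 0.01) in ~30% of samples, never fewer than 10% + 1
  det <- matrix(stats::runif(np * ns, 0, 0.005), np, ns,
                dimnames = list(probe_id, sid))
  for (p in which(lab == "qc_fail")) {
    nf <- max(stats::rbinom(1, ns, 0.3), floor(0.1 * ns) + 1L)
    fs <- sample(ns, nf)
    det[p, fs] <- stats::runif(nf, 0.02, 0.6)
  }

  chrom <- sample(as.character(1:22), np, replace = TRUE)
  chrom[lab == "sex_chromosome"] <-
    sample(c("X", "Y"), sum(lab == "sex_chromosome"), replace = TRUE,
           prob = c(0.85, 0.15))
  has_gene <- stats::runif(np) < 0.75
  ann <- data.frame(
    probe_id = probe_id,
    chromosome = chrom,
    position = sample(1e4:1e8, np),
    gene_symbol = ifelse(has_gene, sprintf("GENE%04d",
                                           sample(3000L, np, TRUE)), NA),
    cpg_type = sample(.cpg_types, np, TRUE,
                      prob = c(0.30, 0.11, 0.11, 0.05, 0.05, 0.38)),
    gene_region = sample(.gene_regions, np, TRUE,
                         prob = c(0.12, 0.09, 0.08, 0.06, 0.06, 0.35, 0.24)),
    stringsAsFactors = FALSE)
  ann$gene_region[is.na(ann$gene_symbol)] <- "Intergenic"

  # clinical sheet; N samples share patients with the first n_N T patients
  pat_T <- sprintf("PT%03d", seq_len(config$n_T))
  rfs <- os <- rep(NA_real_, config$n_T)
  recur <- rep(FALSE, config$n_T)
  dead <- rep(FALSE, config$n_T)
  e <- er_status
  recur[e] <- TRUE
  rfs[e] <- round(stats::runif(sum(e), 60, 180))
  os[e] <- rfs[e] + round(stats::runif(sum(e), 100, 400))
  dead[e] <- TRUE
  late <- !e & stats::runif(config$n_T) < 49 / 60   # most non-ER still relapse
  recur[late] <- TRUE
  rfs[late] <- round(stats::runif(sum(late), 200, 1500))
  os[late] <- rfs[late] + round(stats::runif(sum(late), 400, 1200))
  dead[late] <- stats::runif(sum(late)) < 0.6
  none <- !e & !late
  os[none] <- round(stats::runif(sum(none), 600, 2000))

  clinical <- rbind(
    data.frame(sample_id = sid_C, patient_id = sprintf("PC%03d",
                                                       seq_len(config$n_C)),
               tissue_group = "C", recurrence = FALSE,
               rfs_days = NA_real_, os_days = NA_real_, dead = NA),
    data.frame(sample_id = sid_N, patient_id = pat_T[seq_len(config$n_N)],
               tissue_group = "N", recurrence = FALSE,
               rfs_days = NA_real_, os_days = NA_real_, dead = NA),
    data.frame(sample_id = sid_T, patient_id = pat_T, tissue_group = "T",
               recurrence = recur, rfs_days = rfs, os_days = os,
               dead = dead))
  rownames(clinical) <- NULL

  ds <- cohort_dataset(beta_matrix(beta, det), ann, clinical)
  list(dataset = ds,
       truth = list(probe_label = lab, er = er_status,
                    base_mean = stats::setNames(base_a / (base_a + base_b),
                                                probe_id),
                    config = config))
}

#' Simulate an independent validation cohort on the same array
#'
#' Draws a fresh set of tumour samples from the *same* generative model as
#' an existing simulated cohort — identical probe roles and background
#' means, new patients — emulating an independent validation series
#' profiled on the same platform.  Only tumour samples are generated
#' (validation cohorts are typically tumour-only).
#'
#' @param truth The `truth` component of a [simulate_cohort()] result.
#' @param n_T Number of validation tumour samples (default 36).
#' @param er_fraction Fraction of early-recurrence patients (default
#'   9/36); the realised count is rounded.
#' @param seed Integer seed (independent of the discovery seed).
#' @return List with `dataset` (a [cohort_dataset()] of T samples, no
#'   detection p-values) and `er` (named logical truth).
#' @export
simulate_validation_cohort <- function(truth, n_T = 36L,
                                       er_fraction = 9 / 36, seed = 2L) {
  set.seed(seed)
  cfg <- truth$config
  lab <- truth$probe_label
  mu <- truth$base_mean
  np <- length(lab)
  nu <- cfg$beta_shape_low + cfg$beta_shape_high
  sid <- sprintf("V%02d", seq_len(n_T))
  n_er <- round(er_fraction * n_T)
  er <- sample(rep(c(TRUE, FALSE), c(n_er, n_T - n_er)))
  names(er) <- sid
  beta <- matrix(NA_real_, np, n_T, dimnames = list(names(lab), sid))
  for (p in seq_len(np)) {
    a <- mu[p] * nu; b <- (1 - mu[p]) * nu
    row <- stats::rbeta(n_T, a, b)
    l <- lab[p]
    if (l %in% c("hyper_TvsC", "hyper_TvsN", "hypo_TvsC", "hypo_TvsN")) {
      d <- if (startsWith(l, "hyper")) cfg$delta_planted else
        -cfg$delta_planted
      sh <- .shift_shapes(a, b, d)
      row <- stats::rbeta(n_T, sh[1], sh[2])
    } else if (l %in% c("er_low", "er_high")) {
      d <- if (l == "er_high") cfg$delta_ER else -cfg$delta_ER
      sh <- .shift_shapes(a, b, d)
      row[er] <- stats::rbeta(sum(er), sh[1], sh[2])
    }
    beta[p, ] <- row
  }
  rfs <- os <- rep(NA_real_, n_T)
  recur <- rep(FALSE, n_T); dead <- rep(FALSE, n_T)
  recur[er] <- TRUE
  rfs[er] <- round(stats::runif(sum(er), 60, 180))
  os[er] <- rfs[er] + round(stats::runif(sum(er), 100, 400))
  dead[er] <- TRUE
  late <- !er & stats::runif(n_T) < 0.5
  recur[late] <- TRUE
  rfs[late] <- round(stats::runif(sum(late), 200, 900))
  os[late] <- rfs[late] + round(stats::runif(sum(late), 100, 600))
  none <- !er & !late
  os[none] <- round(stats::runif(sum(none), 90, 900))
  clinical <- data.frame(sample_id = sid,
                         patient_id = sprintf("PV%03d", seq_len(n_T)),
                         tissue_group = "T", recurrence = recur,
                         rfs_days = rfs, os_days = os, dead = dead)
  ann <- data.frame(probe_id = names(lab),
                    chromosome = ifelse(lab == "sex_chromosome", "X", "1"),
                    position = seq_len(np), gene_symbol = NA_character_,
                    cpg_type = "OpenSea", gene_region = "Intergenic",
                    stringsAsFactors = FALSE)
  list(dataset = cohort_dataset(beta_matrix(beta), ann, clinical),
       er = er)
}

#' Simulate pyrosequencing replicate measurements
#'
#' Emulates the duplicate-measurement protocol: every site is measured
#' twice with Gaussian noise (clipped to \[0, 100\]); a configurable
#' fraction of pairs is forced discordant (more than
#' `discordance_threshold` percentage points apart), and discordant pairs
#' receive a third replicate.
#'
#' @param true_levels True methylation percentages in \[0, 100\].
#' @param noise_sd Measurement noise SD in percentage points.
#' @param discordance_rate Fraction of sites forced discordant.
#' @param discordance_threshold Discordance cut-off in points (default 10).
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `site`, `truth`, `rep1`, `rep2`,
#'   `rep3` (`NA` unless the pair was discordant).
#' @export
simulate_pyro_replicates <- function(true_levels, noise_sd = 2,
                                     discordance_rate = 0,
                                     discordance_threshold = 10,
                                     seed = NULL) {
  if (noise_sd < 0) .pm_stop("noise_sd must be >= 0", "pm_invalid_config")
  if (any(true_levels < 0 | true_levels > 100))
    .pm_stop("true levels must lie in [0, 100]", "pm_invalid_input")
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_levels)
  meas <- function() pmin(100, pmax(0, true_levels +
                                      stats::rnorm(n, 0, noise_sd)))
  r1 <- meas(); r2 <- meas()
  forced <- stats::runif(n) < discordance_rate
  # push the second replicate just past the discordance threshold
  r2[forced] <- pmin(100, pmax(0, r1[forced] +
                                 sign(50 - r1[forced]) *
                                 (discordance_threshold + 2 +
                                    abs(stats::rnorm(sum(forced), 0,
                                                     noise_sd)))))
  disc <- abs(r1 - r2) > discordance_threshold
  r3 <- rep(NA_real_, n)
  r3[disc] <- pmin(100, pmax(0, true_levels[disc] +
                               stats::rnorm(sum(disc), 0, noise_sd)))
  data.frame(site = seq_len(n), truth = true_levels,
             rep1 = r1, rep2 = r2, rep3 = r3)
}

#' Write a simulated cohort to disk as a plain-text fixture bundle
#'
#' Emits five files in `dir`: `beta.tsv` and `detection_p.tsv` (plain-tsv
#' beta-matrix layout), `manifest.csv` (Illumina-manifest-style
#' annotation), `samples.csv` (clinical sheet) and `truth.json` (planted
#' truth).  Reading the bundle back reproduces the dataset.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    .pm_stop(paste("cannot create directory", dir), "pm_io_error")
  ds <- sim$dataset
  paths <- c(beta = file.path(dir, "beta.tsv"),
             detection_p = file.path(dir, "detection_p.tsv"),
             manifest = file.path(dir, "manifest.csv"),
             samples = file.path(dir, "samples.csv"),
             truth = file.path(dir, "truth.json"))
  write_beta_matrix(ds$beta, paths["beta"], "beta")
  write_beta_matrix(ds$beta, paths["detection_p"], "detection_p")
  man <- data.frame(IlmnID = ds$annotation$probe_id,
                    CHR = ds$annotation$chromosome,
                    MAPINFO = ds$annotation$position,
                    UCSC_RefGene_Name = ifelse(is.na(ds$annotation$gene_symbol),
                                               "", ds$annotation$gene_symbol),
                    Relation_to_UCSC_CpG_Island = ds$annotation$cpg_type,
                    UCSC_RefGene_Group = ds$annotation$gene_region)
  utils::write.csv(man, paths["manifest"], row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$clinical, paths["samples"], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(probe_label = as.list(sim$truth$probe_label),
         er = as.list(sim$truth$er),
         config = unclass(sim$truth$config)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Bundle directory.
#' @return List with `dataset` and `truth`, mirroring [simulate_cohort()].
#' @export
read_fixture_bundle <- function(dir) {
  bm <- read_beta_matrix(file.path(dir, "beta.tsv"),
                         detection_p_path = file.path(dir, "detection_p.tsv"))
  ann <- read_probe_annotation(file.path(dir, "manifest.csv"))
  cl <- read_sample_sheet(file.path(dir, "samples.csv"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  truth <- list(probe_label = unlist(tr$probe_label),
                er = unlist(tr$er),
                config = do.call(sim_config, tr$config))
  list(dataset = cohort_dataset(bm, ann, cl), truth = truth)
}
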