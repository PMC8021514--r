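make_det_beta <- function(det) {
  nprobe <- nrow(det); nsample <- ncol(det)
  dimnames(det) <- list(sprintf("cg%03d", seq_len(nprobe)),
                        sprintf("S%02d", seq_len(nsample)))
  m <- matrix(0.5, nprobe, nsample, dimnames = dimnames(det))
  beta_matrix(m, det)
}

test_that("call proportions count samples called at detection p < alpha", {
  # fully detected; 119 of 133 detected (just under the 90% bar); never
  # detected
  det <- rbind(rep(0.001, 133),
               c(rep(0.001, 119), rep(0.5, 14)),
               rep(0.5, 133))
  bm <- make_det_beta(det)
  cp <- compute_call_proportions(bm)
  expect_equal(unname(cp), c(1, 119 / 133, 0))
  expect_lt(cp[2], 0.90)

  no_dp <- beta_matrix(bm$beta)
  expect_error(compute_call_proportions(no_dp),
               class = "pm_unavailable_data")
})

test_that("probe filtering applies low-call then sex-chromosome exclusion", {
  sim <- simulate_cohort(sim_config(n_probes = 100, n_planted_TvsC = 0,
                                    n_planted_TvsN = 0, n_planted_ER = 0,
                                    qc_fail_fraction = 0.10,
                                    sex_probe_fraction = 0.05, seed = 9))
  ds <- sim$dataset
  fl <- filter_probes(ds$beta, ds$annotation)
  expect_equal(unname(fl$report$totals),
               c(85, 10, 5))
  expect_equal(nrow(fl$beta$beta), 85L)
  # sample order preserved
  expect_identical(colnames(fl$beta$beta), colnames(ds$beta$beta))
  # planted truth recovered exactly
  lab <- sim$truth$probe_label
  expect_setequal(names(fl$report$excluded_by)[
    fl$report$excluded_by == "low_call"], names(lab)[lab == "qc_fail"])

  # identity filter
  fl0 <- filter_probes(ds$beta, ds$annotation, call_prop_min = 0,
                       drop_sex = FALSE)
  expect_equal(nrow(fl0$beta$beta), 100L)
})

test_that("a probe failing both criteria is counted once, as low_call", {
  # probe 1 fails detection and sits on X; probe 2 fails detection only;
  # probe 3 is clean
  det <- rbind(rep(0.5, 10), rep(0.5, 10), rep(0.001, 10))
  bm <- make_det_beta(det)
  ann <- tiny_annotation(rownames(bm$beta), chromosome = c("X", "1", "1"))
  fl <- filter_probes(bm, ann, call_prop_min = 0.9)
  # probe 1 is on X *and* low-call: precedence assigns low_call
  expect_equal(unname(fl$report$excluded_by["cg001"]), "low_call")
  expect_equal(unname(fl$report$totals["sex_chromosome"]), 0)
})

test_that("differential screen selects planted probes and respects symmetry", {
  sim <- cached_sim()
  ds <- sim$dataset; lab <- sim$truth$probe_label
  cl <- ds$clinical
  ids <- split(cl$sample_id, cl$tissue_group)
  scr <- differential_screen(ds$beta, ids$T, ids$C)
  res <- scr$results
  # partition invariant
  expect_equal(unname(scr$counts["selected"]),
               unname(scr$counts["hyper"] + scr$counts["hypo"]))
  # planted T-vs-C probes selected with the right direction
  hyper <- names(lab)[lab == "hyper_TvsC"]
  hypo <- names(lab)[lab == "hypo_TvsC"]
  expect_true(all(res$selected[res$probe_id %in% c(hyper, hypo)]))
  expect_true(all(res$direction[res$probe_id %in% hyper] == "hyper"))
  expect_true(all(res$direction[res$probe_id %in% hypo] == "hypo"))
  # no null probe selected under Bonferroni at this effect size
  nulls <- names(lab)[lab == "null"]
  expect_equal(sum(res$selected[res$probe_id %in% nulls]), 0L)

  # swapping the groups negates delta and swaps hyper/hypo
  scr2 <- differential_screen(ds$beta, ids$C, ids$T)
  expect_equal(scr2$results$delta_beta, -res$delta_beta)
  expect_equal(unname(scr2$counts["hyper"]), unname(scr$counts["hypo"]))
  expect_equal(unname(scr2$counts["hypo"]), unname(scr$counts["hyper"]))

  # selection invariant under sample and probe order permutation
  set.seed(31)
  perm <- ds$beta[sample(nrow(ds$beta$beta)), sample(ncol(ds$beta$beta))]
  scr3 <- differential_screen(perm, sample(ids$T), sample(ids$C))
  r3 <- scr3$results[match(res$probe_id, scr3$results$probe_id), ]
  expect_equal(r3$selected, res$selected)
  expect_equal(r3$p_raw, res$p_raw, tolerance = 1e-12)

  expect_error(differential_screen(ds$beta, ids$T, c(ids$C[1], ids$T[1])),
               class = "pm_invalid_input")
})

test_that("with no correction and no delta filter the screen reduces to raw Welch", {
  sim <- cached_sim()
  ds <- sim$dataset
  cl <- ds$clinical
  ids <- split(cl$sample_id, cl$tissue_group)
  scr <- differential_screen(ds$beta, ids$T, ids$N, bonferroni = FALSE,
                             delta_threshold = 0)
  res <- scr$results
  expect_equal(res$selected, res$tested & res$p_raw < 0.05)
})

test_that("the null screen controls the family-wise error rate", {
  # two groups drawn from one distribution: Bonferroni keeps FWER low
  set.seed(2024)
  hits <- vapply(1:12, function(i) {
    m <- matrix(rbeta(2000 * 20, 5, 5), 2000, 20,
                dimnames = list(sprintf("p%04d", 1:2000),
                                sprintf("s%02d", 1:20)))
    scr <- differential_screen(beta_matrix(m), sprintf("s%02d", 1:10),
                               sprintf("s%02d", 11:20))
    unname(scr$counts["selected"])
  }, 0)
  expect_gte(mean(hits == 0), 0.95)
})

test_that("probes with missing values are tested pairwise or skipped", {
  set.seed(4)
  m <- matrix(rbeta(40, 2, 2), 4, 10,
              dimnames = list(paste0("cg", 1:4), paste0("s", 1:10)))
  m[1, 1:2] <- NA          # 3 values left in group A: still tested
  m[2, 1:4] <- NA          # 1 value left in group A: skipped
  scr <- differential_screen(beta_matrix(m), paste0("s", 1:5),
                             paste0("s", 6:10), delta_threshold = 0)
  expect_true(scr$results$tested[1])
  expect_false(scr$results$tested[2])
  expect_equal(unname(scr$counts["tested"]), 3)
  # Bonferroni family size is the number actually tested
  expect_equal(scr$results$p_adjusted[1],
               min(1, scr$results$p_raw[1] * 3))
})
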