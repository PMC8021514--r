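test_that("simulation is fully reproducible for a fixed seed", {
  cfg <- sim_config(n_probes = 300, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$dataset$beta$beta, b$dataset$beta$beta)
  expect_identical(a$dataset$beta$detection_p, b$dataset$beta$detection_p)
  expect_identical(a$dataset$clinical, b$dataset$clinical)
  expect_identical(a$truth$probe_label, b$truth$probe_label)
  # different seed, different data
  c <- simulate_cohort(sim_config(n_probes = 300, seed = 43))
  expect_false(identical(a$dataset$beta$beta, c$dataset$beta$beta))
})

test_that("simulated cohorts respect the declared structure", {
  sim <- cached_sim()
  ds <- sim$dataset; cfg <- sim$truth$config
  expect_true(all(ds$beta$beta >= 0 & ds$beta$beta <= 1))
  cl <- ds$clinical
  expect_equal(as.vector(table(cl$tissue_group)[c("C", "N", "T")]),
               c(cfg$n_C, cfg$n_N, cfg$n_T))
  both <- !is.na(cl$rfs_days) & !is.na(cl$os_days)
  expect_true(all(cl$rfs_days[both] <= cl$os_days[both]))
  expect_equal(sum(sim$truth$er), round(cfg$er_fraction * cfg$n_T))
  # planted label counts match the configuration
  lab <- sim$truth$probe_label
  expect_equal(sum(grepl("TvsC", lab)), cfg$n_planted_TvsC)
  expect_equal(sum(grepl("TvsN", lab)), cfg$n_planted_TvsN)
  expect_equal(sum(lab %in% c("er_low", "er_high")), cfg$n_planted_ER)
  # qc_fail probes exceed detection alpha in > 10% of samples
  qcf <- names(lab)[lab == "qc_fail"]
  fail_frac <- rowMeans(ds$beta$detection_p[qcf, , drop = FALSE] >= 0.01)
  expect_true(all(fail_frac > 0.10))
  # sex probes are the X/Y-annotated ones
  expect_setequal(ds$annotation$probe_id[ds$annotation$chromosome
                                         %in% c("X", "Y")],
                  names(lab)[lab == "sex_chromosome"])
})

test_that("planted group-mean differences are unbiased across seeds", {
  deltas <- vapply(1:15, function(s) {
    sim <- simulate_cohort(sim_config(n_probes = 120, n_planted_TvsC = 30,
                                      n_planted_TvsN = 0, n_planted_ER = 0,
                                      seed = s))
    lab <- sim$truth$probe_label
    b <- sim$dataset$beta$beta
    tc <- grep("^T", colnames(b)); cc <- grep("^C", colnames(b))
    d <- rowMeans(b[, tc]) - rowMeans(b[, cc])
    mean(abs(d[names(lab)[lab %in% c("hyper_TvsC", "hypo_TvsC")]]))
  }, 0)
  expect_lt(abs(mean(deltas) - 0.30), 0.02)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_probes = 10, n_planted_TvsC = 20),
               class = "pm_invalid_config")
})

test_that("fixture bundles round trip through disk", {
  dir <- withr::local_tempdir()
  small <- sim_config(n_probes = 120, n_planted_TvsC = 10,
                      n_planted_TvsN = 10, seed = 5)
  sim <- simulate_cohort(small)
  paths <- write_fixture_bundle(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_fixture_bundle(dir)
  expect_equal(back$dataset$beta$beta, sim$dataset$beta$beta,
               tolerance = 1e-12)
  expect_equal(back$dataset$clinical$rfs_days,
               sim$dataset$clinical$rfs_days)
  expect_identical(back$truth$probe_label, sim$truth$probe_label)
  # truth lists exactly the planted ER probes
  expect_equal(sum(back$truth$probe_label %in% c("er_low", "er_high")),
               sim$truth$config$n_planted_ER)
  # rewriting with the same seed is byte-identical
  dir2 <- withr::local_tempdir()
  write_fixture_bundle(simulate_cohort(small), dir2)
  for (f in basename(paths))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})

test_that("pyro replicate simulation honours noise and discordance settings", {
  # zero noise: replicates equal the truth and merge returns it
  tab0 <- simulate_pyro_replicates(c(10, 50, 90), noise_sd = 0, seed = 1)
  expect_equal(tab0$rep1, tab0$truth)
  expect_equal(merge_replicate_table(tab0), tab0$truth)

  # forced discordance: every pair gets a third replicate
  tab1 <- simulate_pyro_replicates(runif(50, 10, 90), noise_sd = 1,
                                   discordance_rate = 1, seed = 2)
  expect_true(all(!is.na(tab1$rep3)))
  expect_true(all(abs(tab1$rep1 - tab1$rep2) > 10))

  # at noise_sd = 2 a duplicate mean has SD 2/sqrt(2), so the normal
  # tail puts P(|error| <= 3) at 2*pnorm(3/sqrt(2)) - 1 ~ 0.966; the
  # simulation agrees, and virtually all sites stay within 3 SDs
  tab2 <- simulate_pyro_replicates(runif(1000, 5, 95), noise_sd = 2,
                                   seed = 3)
  merged <- merge_replicate_table(tab2)
  within3 <- mean(abs(merged - tab2$truth) <= 3, na.rm = TRUE)
  expect_equal(within3, 2 * pnorm(3 / sqrt(2)) - 1, tolerance = 0.02)
  expect_gte(mean(abs(merged - tab2$truth) <= 3 * sqrt(2), na.rm = TRUE),
             0.99)

  expect_error(simulate_pyro_replicates(50, noise_sd = -1),
               class = "pm_invalid_config")
  expect_error(simulate_pyro_replicates(150), class = "pm_invalid_input")
})
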