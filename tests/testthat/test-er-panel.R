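er_label_sheet <- function(rfs, recur, os = rfs + 500) {
  data.frame(sample_id = sprintf("T%02d", seq_along(rfs)),
             patient_id = sprintf("P%02d", seq_along(rfs)),
             tissue_group = "T", recurrence = recur,
             rfs_days = rfs, os_days = os, dead = FALSE)
}

test_that("ER labels follow the 6-month recurrence window", {
  cl <- er_label_sheet(rfs = c(120, 400, NA, 183, 184),
                       recur = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                       os = c(620, 900, 800, 683, 684))
  lab <- assign_er_labels(cl)
  expect_equal(lab$er, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(lab$basis[2], "recurrence_after_window")
  expect_equal(lab$basis[3], "no_recurrence")
  # boundary: day 183 is within the window, day 184 is not
  expect_true(lab$er[4]); expect_false(lab$er[5])
  expect_false(any(lab$indeterminate))

  # short follow-up without recurrence: counted non-ER but flagged
  cl2 <- er_label_sheet(rfs = c(NA, NA), recur = c(FALSE, FALSE),
                        os = c(90, 800))
  lab2 <- assign_er_labels(cl2)
  expect_equal(lab2$er, c(FALSE, FALSE))
  expect_equal(lab2$indeterminate, c(TRUE, FALSE))

  cl3 <- er_label_sheet(rfs = 100, recur = NA)
  expect_error(assign_er_labels(cl3), class = "pm_validation_error")
})

test_that("marker calls use strict directional cut-offs", {
  below <- data.frame(probe_id = "cg17206555", position = 1L,
                      direction = "ER_below", cutoff_percent = 23.5,
                      auc = 0.811)
  above <- data.frame(probe_id = "cg02192855", position = 1L,
                      direction = "ER_above", cutoff_percent = 13.1,
                      auc = 0.720)
  expect_true(call_marker(20.0, below))
  expect_false(call_marker(23.5, below))   # boundary is negative
  expect_false(call_marker(25.0, below))
  expect_true(call_marker(15.0, above))
  expect_false(call_marker(13.1, above))
  expect_error(call_marker(120, below), class = "pm_validation_error")
  # monotone: lowering a value never loses an ER_below positive
  v <- sort(runif(50, 0, 100))
  calls <- call_marker(v, below)
  expect_true(all(diff(as.integer(calls)) <= 0))
})

test_that("criteria are built from Youden cut-offs on the percent scale", {
  cu <- roc_curve(c(10, 20) / 100, c(15, 25, 30) / 100, "positive-if-low")
  cr <- build_criterion(cu, "cgX", scale = "fraction")
  expect_equal(cr$cutoff_percent, 22.5)
  expect_equal(cr$direction, "ER_below")
  expect_equal(cr$auc, 5 / 6, tolerance = 1e-12)

  cu2 <- roc_curve(c(8, 9), c(1, 2), "positive-if-high")
  cr2 <- build_criterion(cu2, "cgY", scale = "percent")
  expect_equal(cr2$direction, "ER_above")
  expect_equal(cr2$cutoff_percent, 5)
})

test_that("panel voting follows the k-of-n rule without imputation", {
  crit <- data.frame(probe_id = c("m1", "m2", "m3"), position = 1L,
                     direction = "ER_below",
                     cutoff_percent = c(50, 50, 50), auc = 0.8)
  rule <- panel_rule(crit, min_positive = 2)
  expect_true(call_panel(c(m1 = 40, m2 = 40, m3 = 60), rule))
  expect_false(call_panel(c(m1 = 40, m2 = 60, m3 = 60), rule))
  expect_false(call_panel(c(m1 = 60, m2 = 60, m3 = 60),
                          panel_rule(crit, 1)))
  # k = 1 positive whenever k = 2 positive
  set.seed(14)
  for (i in 1:20) {
    v <- stats::setNames(runif(3, 0, 100), c("m1", "m2", "m3"))
    if (call_panel(v, rule)) expect_true(call_panel(v, panel_rule(crit, 1)))
  }
  expect_error(call_panel(c(m1 = 40, m2 = 40), rule),
               class = "pm_missing_marker")
  expect_error(panel_rule(crit, 4), class = "pm_invalid_input")
})

test_that("panel evaluation reproduces the printed metrics and is monotone", {
  # reconstruct a cohort of 22 ER / 60 non-ER with vote counts chosen to
  # give the printed 2-of-3 row: tp = 18, fn = 4, tn = 43, fp = 17
  crit <- data.frame(probe_id = c("m1", "m2", "m3"), position = 1L,
                     direction = "ER_below",
                     cutoff_percent = c(50, 50, 50), auc = 0.8)
  votes_er <- rep(c(3, 2, 1, 0), c(10, 8, 4, 0))     # >=2 in 18 of 22
  votes_non <- rep(c(3, 2, 1, 0), c(5, 12, 11, 32))  # >=2 in 17 of 60
  mk <- function(v) t(vapply(v, function(k)
    c(m1 = if (k >= 1) 40 else 60, m2 = if (k >= 2) 40 else 60,
      m3 = if (k >= 3) 40 else 60), c(m1 = 0, m2 = 0, m3 = 0)))
  vals <- rbind(mk(votes_er), mk(votes_non))
  rownames(vals) <- sprintf("S%02d", seq_len(nrow(vals)))
  er <- rep(c(TRUE, FALSE), c(22, 60))
  ev <- evaluate_panel(vals, er, crit)
  row2 <- ev[ev$k == 2, ]
  expect_equal(row2$tp, 18); expect_equal(row2$fn, 4)
  expect_equal(row2$tn, 43); expect_equal(row2$fp, 17)
  expect_equal(row2$sensitivity_pct, 81.8)
  expect_equal(row2$specificity_pct, 71.7)
  # voting monotonicity across k
  expect_true(all(diff(ev$sensitivity_pct) <= 0))
  expect_true(all(diff(ev$specificity_pct) >= 0))

  # a panel positive for everyone
  all_pos <- matrix(10, 4, 3, dimnames = list(paste0("S", 1:4),
                                              c("m1", "m2", "m3")))
  ev2 <- evaluate_panel(all_pos, c(TRUE, TRUE, FALSE, FALSE), crit)
  expect_equal(ev2$sensitivity_pct[ev2$k == 1], 100)
  expect_equal(ev2$specificity_pct[ev2$k == 1], 0)

  expect_error(evaluate_panel(all_pos, rep(TRUE, 4), crit),
               class = "pm_undefined_metric")
})

test_that("a frozen panel transfers without refitting", {
  crit <- data.frame(probe_id = c("m1", "m2"), position = 1L,
                     direction = c("ER_below", "ER_above"),
                     cutoff_percent = c(30, 70), auc = 0.8)
  rule <- panel_rule(crit, 1)
  vals <- cbind(m1 = c(20, 40, 25, 80), m2 = c(80, 60, 50, 90))
  rownames(vals) <- paste0("V", 1:4)
  ev <- transfer_panel(rule, vals, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(attr(ev, "cohort"), "validation")
  expect_s3_class(ev, "panel_eval")
  # missing probe in the validation data
  expect_error(transfer_panel(rule, vals[, 1, drop = FALSE],
                              c(TRUE, FALSE, TRUE, FALSE)),
               class = "pm_missing_marker")
})

test_that("replicate merging follows the duplicate/triplicate rule", {
  expect_equal(merge_replicates(c(30, 32))$value, 31)
  expect_equal(merge_replicates(c(50, 50))$value, 50)
  m <- merge_replicates(c(30, 45))
  expect_true(m$needs_third)
  expect_true(is.na(m$value))
  expect_equal(merge_replicates(c(30, 45, 33))$value, 36)
  # difference of exactly the threshold is still concordant
  expect_equal(merge_replicates(c(30, 40))$value, 35)
  expect_error(merge_replicates(50), class = "pm_invalid_input")
  expect_error(merge_replicates(c(30, 150)), class = "pm_invalid_input")
  # merged value always lies within [min, max] of the inputs
  set.seed(6)
  for (i in 1:30) {
    v <- runif(sample(2:3, 1), 0, 100)
    r <- merge_replicates(v)
    if (!r$needs_third)
      expect_true(r$value >= min(v) && r$value <= max(v))
  }
})

test_that("platform concordance and calibration behave on exact data", {
  b <- runif(10, 0.1, 0.9)
  cc <- concordance_check(100 * b, b, probe_id = "cgZ")
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$n, 10)
  expect_equal(concordance_check(100 * (1 - b), b)$pearson_r, -1)
  # noisy identity at n = 50 stays strongly concordant
  set.seed(44)
  b2 <- runif(50, 0.1, 0.9)
  noisy <- pmin(100, pmax(0, 100 * b2 + rnorm(50, 0, 2)))
  expect_gt(concordance_check(noisy, b2)$pearson_r, 0.95)

  lin <- calibration_linearity(c(0, 50, 100))
  expect_equal(lin$slope, 1); expect_equal(lin$intercept, 0)
  expect_equal(lin$max_abs_residual, 0)
  expect_true(lin$ok)
  # closed-form least squares through (0,2), (50,51), (100,97)
  lin2 <- calibration_linearity(c(2, 51, 97))
  expect_equal(lin2$slope, 0.95, tolerance = 1e-12)
  expect_equal(lin2$intercept, 2.5, tolerance = 1e-12)
  expect_true(lin2$ok)
  lin3 <- calibration_linearity(c(0, 0, 0))
  expect_equal(lin3$slope, 0)
  expect_false(lin3$ok)
})

test_that("survival comparison separates ER and non-ER outcomes", {
  cl <- er_label_sheet(rfs = c(rep(100, 10), rep(600, 10)),
                       recur = TRUE,
                       os = c(rep(c(300, 320, 340, 360, 380), 2),
                              rep(c(1500, 1600, 1700, 1800, 1900), 2)))
  cl$dead <- TRUE
  lab <- assign_er_labels(cl)
  sc <- compare_survival(lab, cl)
  expect_lt(sc$test$p_raw, 0.001)
  expect_lt(sc$km_er$median, sc$km_non_er$median)

  # degenerate: no usable samples in one group
  cl2 <- cl; cl2$os_days[1:10] <- NA
  expect_error(compare_survival(assign_er_labels(cl2), cl2),
               class = "pm_invalid_input")
})
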