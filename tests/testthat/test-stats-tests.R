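test_that("Welch t test matches hand-worked values and is symmetric", {
  # identical groups: no evidence
  r0 <- welch_t_test(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)

  # frozen from the textbook Welch-Satterthwaite formulas:
  # equal variances 0.01, diff -0.5, se = sqrt(0.02/3), df = 4
  r <- welch_t_test(c(0.10, 0.20, 0.30), c(0.60, 0.70, 0.80))
  expect_equal(r$statistic, -0.5 / sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(r$statistic, -6.123724, tolerance = 1e-6)
  expect_equal(r$df, 4)

  # swapping groups flips the sign, p unchanged
  rs <- welch_t_test(c(0.60, 0.70, 0.80), c(0.10, 0.20, 0.30))
  expect_equal(rs$statistic, -r$statistic)
  expect_equal(rs$p_raw, r$p_raw)

  # cross-check against the base-R implementation on random draws
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), sd = 2)
    ref <- t.test(x, y)
    got <- welch_t_test(x, y)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p_raw, ref$p.value, tolerance = 1e-10)
  }

  expect_error(welch_t_test(1, c(1, 2)), class = "pm_invalid_input")
  # both constant, unequal: infinitely strong evidence, not a crash
  rc <- welch_t_test(c(1, 1), c(2, 2))
  expect_equal(rc$p_raw, 0)
})

test_that("Welch p-values are uniform under the null", {
  set.seed(20240701)
  n <- 8000
  x <- matrix(rnorm(n * 20), n, 20)
  w <- pdacmeth:::.row_welch(x, 1:10, 11:20)
  d <- suppressWarnings(ks.test(w$p_raw, "punif"))$statistic
  expect_lt(unname(d), 0.05)
})

test_that("row-wise Welch equals the scalar implementation, with NAs", {
  set.seed(7)
  m <- matrix(rnorm(50 * 12), 50, 12)
  m[sample(length(m), 40)] <- NA
  w <- pdacmeth:::.row_welch(m, 1:6, 7:12)
  for (i in c(1, 13, 27, 50)) {
    x <- m[i, 1:6]; y <- m[i, 7:12]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) next
    ref <- welch_t_test(x, y)
    expect_equal(w$statistic[i], ref$statistic, tolerance = 1e-12)
    expect_equal(w$p_raw[i], ref$p_raw, tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment is capped, monotone, and exact", {
  expect_equal(bonferroni_adjust(0.5, 1), 0.5)
  # family size of the post-QC autosomal probe set
  expect_equal(bonferroni_adjust(1e-7, 473457), 0.0473457)
  expect_equal(bonferroni_adjust(0.01, 200), 1.0)
  expect_error(bonferroni_adjust(0.5, 0), class = "pm_invalid_input")
  expect_error(bonferroni_adjust(1.5, 10), class = "pm_invalid_input")
  # monotone in p and in m, never above 1
  p <- seq(0, 1, by = 0.05)
  for (m in c(1, 3, 473457)) {
    adj <- bonferroni_adjust(p, m)
    expect_true(all(diff(adj) >= 0))
    expect_true(all(adj <= 1 & adj >= p))
  }
  expect_true(all(diff(vapply(c(1, 2, 10, 1e5),
                              function(m) bonferroni_adjust(1e-4, m),
                              0)) >= 0))
})

test_that("Fisher exact matches enumeration and the reconstructed cluster table", {
  # balanced table: no association
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_raw, 1)
  # full enumeration over margins (3,3)/(3,3): two perfect tables of
  # probability 1/20 each
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_raw, 0.1,
               tolerance = 1e-12)
  # early-recurrence by cluster super-group: 22/58 ER in one group,
  # 0/24 in the other, printed as P = 0.0002
  p <- fisher_exact_2x2(matrix(c(22, 0, 36, 24), 2))$p_raw
  expect_equal(p, 0.0002, tolerance = 0.05)
  expect_equal(p, fisher.test(matrix(c(22, 0, 36, 24), 2))$p.value,
               tolerance = 1e-9)
  # degenerate margin
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))$p_raw, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               class = "pm_invalid_input")
  # random tables vs base R (probability-mass convention shared)
  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_raw,
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -2 * x + 7), -1)
  # hand-worked: cov = 5.5/3, ss_x = 5, ss_y = 8.75
  expect_equal(pearson_correlation(x, c(1, 3, 2, 5)),
               5.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(2, 4)),
               class = "pm_zero_variance")
  expect_error(pearson_correlation(1:2, 1:2), class = "pm_invalid_input")
})

test_that("confusion metrics reproduce the printed panel percentages", {
  m <- confusion_metrics(tp = 18, fp = 17, tn = 43, fn = 4)
  expect_equal(unname(m["sensitivity"]), 81.8)
  expect_equal(unname(m["specificity"]), 71.7)
  expect_equal(unname(confusion_metrics(0, 1, 1, 5)["sensitivity"]), 0)
  expect_error(confusion_metrics(0, 1, 1, 0), class = "pm_undefined_metric")
  expect_error(confusion_metrics(1, 0, 0, 1), class = "pm_undefined_metric")
})
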