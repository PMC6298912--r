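test_that("summary-based Welch reproduces the headline follicle comparison", {
  res <- welch_from_summary(0.659, 0.07, 10, 0.170, 0.05, 10)
  expect_lt(res$p_value, 0.001)
  expect_true(res$significant)
  expect_gt(res$t_stat, 0)
})

test_that("identical groups give t = 0 and p = 1", {
  res <- welch_from_summary(5, 1.2, 8, 5, 1.2, 8)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  x <- c(1.2, 3.4, 2.2, 5.1)
  same <- welch_from_samples(x, x)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
})

test_that("swapping groups negates t and preserves p exactly", {
  a <- welch_from_summary(10, 2, 9, 7, 3, 12)
  b <- welch_from_summary(7, 3, 12, 10, 2, 9)
  expect_equal(b$t_stat, -a$t_stat)
  expect_identical(b$p_value, a$p_value)
  expect_identical(b$df, a$df)
})

test_that("sample and summary routes agree with each other and with t.test", {
  set.seed(19)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    via_samples <- welch_from_samples(x, y)
    via_summary <- welch_from_summary(mean(x), sd(x), length(x),
                                      mean(y), sd(y), length(y))
    expect_equal(via_samples$p_value, via_summary$p_value, tolerance = 1e-12)
    expect_equal(via_samples$t_stat, via_summary$t_stat, tolerance = 1e-12)

    ref <- t.test(x, y)   # Welch by default: the independent reference
    expect_equal(via_samples$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(via_samples$df, unname(ref$parameter), tolerance = 1e-12)
  }
})

test_that("a clear location shift is detected", {
  res <- welch_from_samples(c(1, 2, 3), c(11, 12, 13))
  expect_lt(res$p_value, 0.01)
})

test_that("Welch p-values agree with a permutation test on moderate samples", {
  set.seed(23)
  for (i in 1:5) {
    x <- rnorm(20)
    y <- rnorm(20, mean = 0.6)
    pw <- welch_from_samples(x, y)$p_value
    pp <- oracle_permutation_p(x, y, n_perm = 1e4, seed = i)
    expect_lt(abs(pw - pp), 0.02 + 3 * sqrt(pp * (1 - pp) / 1e4))
  }
})

test_that("degenerate and undersized comparisons are rejected", {
  expect_error(welch_from_summary(5, 0, 10, 6, 0, 10), "zero variance")
  expect_error(welch_from_summary(5, 1, 1, 6, 1, 10), "n >= 2")
  expect_error(welch_from_samples(1, c(1, 2)), "at least 2")
  expect_error(welch_from_samples(c(1, NA, 3), c(1, 2, 3)), "finite")
})

test_that("compare_study produces one tested cell per parameter x timepoint", {
  st <- simulate_study(study_config(n_per_group = 6, seed = 2))
  cmp <- compare_study(st)
  expect_equal(nrow(cmp), 11 * 3)
  expect_true(all(!is.na(cmp$p_value)))
  expect_equal(unique(cmp$n_treated), 6)
  # flags are consistent with the p-values at alpha = 0.05
  expect_identical(cmp$significant, cmp$p_value < 0.05)

  one <- compare_study(st[st$timepoint == "day0", ], parameters = "pe")
  expect_equal(nrow(one), 1)
})

test_that("a missing arm yields an NA cell, not an abort", {
  st <- simulate_study(study_config(n_per_group = 4, timepoints = "day0",
                                    seed = 7))
  broken <- st[!(st$arm == "control" & st$timepoint == "day0"), ]
  cmp <- compare_study(broken, parameters = "pe")
  expect_equal(nrow(cmp), 1)
  expect_true(is.na(cmp$p_value))
  expect_equal(cmp$n_control, 0)
})

test_that("the optional BH adjustment only makes calls more conservative", {
  st <- simulate_study(study_config(n_per_group = 8, seed = 15))
  raw <- compare_study(st)
  adj <- compare_study(st, adjust = "BH")
  expect_true(all(adj$p_adjusted >= adj$p_value - 1e-15))
  expect_true(all(which(adj$significant) %in% which(raw$significant)))
})
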