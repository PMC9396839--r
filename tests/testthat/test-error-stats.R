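test_that("absolute errors and residuals are elementwise and order-preserving", {
  expect_equal(absolute_errors(activity_pairs(c(1, 2), c(1, 2))), c(0, 0))
  expect_equal(absolute_errors(activity_pairs(c(1, 2), c(1.5, 1.5))),
               c(0.5, 0.5))
  expect_equal(signed_residuals(activity_pairs(c(2, 2), c(1, 3))),
               c(1, -1))
  set.seed(11)
  p <- random_pairs(30)
  expect_equal(absolute_errors(p),
               vapply(seq_len(30), function(i) abs(p$y_exp[i] - p$y_pred[i]),
                      numeric(1)))
  expect_equal(sum(signed_residuals(p)),
               30 * (mean(p$y_exp) - mean(p$y_pred)), tolerance = 1e-10)
})

test_that("error summary reports mean, sample SD and bins that sum to one", {
  s <- error_summary(c(0, 0, 0))
  expect_equal(s$aae, 0)
  expect_equal(s$sd, 0)
  expect_equal(unname(s$bins), c(1, 0, 0))
  s <- error_summary(c(0.1, 0.2, 0.3))
  expect_equal(s$aae, 0.2)
  expect_equal(s$sd, 0.1)
  sp <- error_summary(c(0.1, 0.2, 0.3), sd_type = "population")
  expect_equal(sp$sd, 0.1 * sqrt(2 / 3))
  expect_error(error_summary(numeric(0)),
               class = "qsarval_error_insufficient")
  set.seed(12)
  aes <- abs(rnorm(200, 0, 0.3))
  s <- error_summary(aes)
  expect_equal(sum(s$bins), 1, tolerance = 1e-9)
  expect_gte(s$aae, min(aes))
  expect_lte(s$aae, max(aes))
})

test_that("frequency bins use a closed middle interval", {
  expect_equal(unname(frequency_bins(c(0.05, 0.15, 0.25, 0.30))),
               c(0.25, 0.25, 0.5))
  # boundary values 0.1 and 0.2 belong to the middle subgroup
  expect_equal(unname(frequency_bins(c(0.1, 0.2))), c(0, 1, 0))
  expect_error(frequency_bins(numeric(0)),
               class = "qsarval_error_insufficient")
})

test_that("error comparison is a two-sided independent t-test", {
  same <- compare_errors(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1.0)
  # zero variance in both groups
  z <- compare_errors(c(0.2, 0.2), c(0.2, 0.2))
  expect_equal(z$p_value, 1.0)
  expect_error(compare_errors(0.1, c(0.1, 0.2)),
               class = "qsarval_error_insufficient")
  # swapping groups negates t, preserves p
  set.seed(13)
  a <- abs(rnorm(12, 0.2, 0.1)); b <- abs(rnorm(9, 0.35, 0.1))
  f <- compare_errors(a, b); r <- compare_errors(b, a)
  expect_equal(f$t_statistic, -r$t_statistic)
  expect_equal(f$p_value, r$p_value)
  # welch differs from student for unequal variances
  w <- compare_errors(a, b, variant = "welch")
  expect_false(identical(w$df, f$df))
})

test_that("student p-values agree with the t distribution at df = 10", {
  set.seed(14)
  a <- rnorm(6, 0.2, 0.08); b <- rnorm(6, 0.3, 0.12)
  res <- compare_errors(a, b, variant = "student")
  expect_equal(res$df, 10)
  expect_equal(res$p_value, 2 * pt(-abs(res$t_statistic), df = 10),
               tolerance = 1e-10)
})

test_that("student p-value tracks the exhaustive permutation oracle", {
  set.seed(15)
  a <- round(abs(rnorm(6, 0.20, 0.05)), 3)
  b <- round(abs(rnorm(6, 0.32, 0.05)), 3)
  p_t <- compare_errors(a, b, variant = "student")$p_value
  p_perm <- oracle_perm_pvalue(a, b)
  expect_lt(abs(p_t - p_perm), 0.05)
})

test_that("AAE of half-normal errors converges to sigma * sqrt(2/pi)", {
  sigma <- 0.3
  d <- synth_dataset(n_train = 100, n_test = 10000, noise_sd = sigma,
                     seed = 77)
  s <- error_summary(absolute_errors(d$test))
  target <- sigma * sqrt(2 / pi)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(10000)
  expect_lt(abs(s$aae - target), 3 * se)
})
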