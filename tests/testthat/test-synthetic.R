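test_that("generation is seed-deterministic and leaves the RNG state alone", {
  d1 <- synth_dataset(seed = 123, noise_sd = 0.2, bias = 0.1,
                      outlier_fraction = 0.1, outlier_shift = 1)
  d2 <- synth_dataset(seed = 123, noise_sd = 0.2, bias = 0.1,
                      outlier_fraction = 0.1, outlier_shift = 1)
  expect_identical(d1$train$y_exp, d2$train$y_exp)
  expect_identical(d1$test$y_pred, d2$test$y_pred)
  d3 <- synth_dataset(seed = 124, noise_sd = 0.2)
  expect_false(identical(d1$train$y_exp, d3$train$y_exp))
  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(synth_dataset(seed = 1))
  expect_identical(rnorm(3), before)
})

test_that("a zero-noise spec yields a perfect model", {
  d <- synth_dataset(noise_sd = 0, seed = 8)
  expect_equal(d$test$y_pred, d$test$y_exp)
  expect_equal(qsar_metrics(d$test)$rm2, 1.0)
})

test_that("invalid specs are rejected", {
  expect_error(synth_dataset(n_train = 2), class = "qsarval_error_usage")
  expect_error(synth_dataset(activity_range = c(5, 2)),
               class = "qsarval_error_usage")
  expect_error(synth_dataset(noise_sd = -1), class = "qsarval_error_usage")
  expect_error(synth_dataset(outlier_fraction = 1),
               class = "qsarval_error_usage")
  expect_error(synth_grid("bias", numeric(0)),
               class = "qsarval_error_usage")
  expect_error(synth_grid("nonsense", 1:3),
               class = "qsarval_error_usage")
})

test_that("training range approaches the activity span as n grows", {
  d <- synth_dataset(n_train = 5000, n_test = 10, activity_range = c(2, 6),
                     seed = 44)
  expect_equal(diff(range(d$train$y_exp)), 4, tolerance = 0.01)
})

test_that("a single-point grid reproduces the base dataset", {
  g <- synth_grid("bias", 0.3, noise_sd = 0.1, seed = 17)
  base <- synth_dataset(bias = 0.3, noise_sd = 0.1, seed = 17)
  expect_equal(g[[1]]$train$y_exp, base$train$y_exp)
  expect_equal(g[[1]]$test$y_pred, base$test$y_pred)
})

test_that("growing bias degrades CCC but not r2 across a grid", {
  g <- synth_grid("bias", c(0, 0.5, 1.0), noise_sd = 0.1,
                  n_train = 200, n_test = 200, seed = 51)
  cccs <- sapply(g, function(d) ccc(d$test))
  r2s <- sapply(g, function(d) as.numeric(pearson_r2(d$test)))
  expect_true(all(diff(cccs) < 0))
  expect_lt(max(abs(r2s - r2s[1])), 0.05)
})

test_that("outlier contamination inflates the test error SD", {
  g <- synth_grid("outlier_fraction", c(0, 0.1), noise_sd = 0.1,
                  outlier_shift = 2, n_test = 200, seed = 61)
  sds <- sapply(g, function(d) error_summary(absolute_errors(d$test))$sd)
  expect_gt(sds[2], sds[1])
})

test_that("with pure bias the forward slope matches its population value", {
  # bias b shifts predictions; k = E[y(y+b)] / E[(y+b)^2] at noise 0
  b <- 1
  d <- synth_dataset(n_train = 10, n_test = 5000, bias = b, noise_sd = 0,
                     activity_range = c(2, 6), seed = 71)
  y <- d$test$y_exp
  expect_equal(rto_slopes(d$test)$k, sum(y * (y + b)) / sum((y + b)^2),
               tolerance = 1e-12)
  expect_lt(rto_slopes(d$test)$k, 1)
  cccs <- sapply(c(0, 0.5, 1, 2), function(bb)
    ccc(synth_dataset(n_test = 500, bias = bb, noise_sd = 0,
                      seed = 72)$test))
  expect_true(all(diff(cccs) < 0))
})

test_that("test-only contamination trips the error t-test more than balanced", {
  n_flag <- function(split) {
    flags <- vapply(1:200, function(i) {
      d <- synth_dataset(n_train = 40, n_test = 20, noise_sd = 0.1,
                         outlier_fraction = 0.2, outlier_shift = 1.5,
                         outlier_split = split, seed = 1000 + i)
      compare_errors(absolute_errors(d$train),
                     absolute_errors(d$test))$p_value <= 0.05
    }, logical(1))
    sum(flags)
  }
  expect_gt(n_flag("test"), n_flag("both"))
})

test_that("heavy-tailed noise produces more extreme errors at equal scale", {
  dg <- synth_dataset(n_test = 2000, noise_sd = 0.2, noise = "gaussian",
                      seed = 81)
  dt <- synth_dataset(n_test = 2000, noise_sd = 0.2, noise = "t",
                      seed = 81)
  expect_gt(max(absolute_errors(dt$test)), max(absolute_errors(dg$test)))
})
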