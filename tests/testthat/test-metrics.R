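test_that("squared correlation matches direct formula and handles degeneracy", {
  expect_equal(as.numeric(pearson_r2(activity_pairs(1:3, 1:3))), 1.0)
  # anti-correlated predictions square to 1 but carry a negative sign flag
  r2 <- pearson_r2(activity_pairs(c(1, 2, 3), c(5, 3, 1)))
  expect_equal(as.numeric(r2), 1.0)
  expect_equal(attr(r2, "sign"), -1)
  p <- activity_pairs(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(as.numeric(pearson_r2(p)),
               oracle_r2(p$y_exp, p$y_pred), tolerance = 1e-12)
  # symmetric in its arguments
  expect_equal(as.numeric(pearson_r2(activity_pairs(p$y_pred, p$y_exp))),
               as.numeric(pearson_r2(p)))
  expect_error(pearson_r2(activity_pairs(c(2, 2, 2), c(1, 2, 3))),
               class = "qsarval_error_degenerate")
  expect_error(pearson_r2(activity_pairs(1:2, 2:3)),
               class = "qsarval_error_insufficient")
})

test_that("through-origin slopes follow the closed form", {
  s <- rto_slopes(activity_pairs(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(s$k, 1.0)
  expect_equal(s$k_prime, 1.0)
  s <- rto_slopes(activity_pairs(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(s$k, 0.5)
  expect_equal(s$k_prime, 2.0)
  expect_error(rto_slopes(activity_pairs(c(0, 0), c(1, 2))),
               class = "qsarval_error_degenerate")
})

test_that("forward through-origin determination coefficient matches an independent solver", {
  expect_equal(r0sq(activity_pairs(1:3, 1:3)), 1.0)
  expect_equal(r0sq(activity_pairs(c(1, 2, 3), c(2, 4, 6))), 1.0)
  p <- activity_pairs(c(1, 2, 3, 4), c(1.5, 1.8, 3.5, 3.7))
  expect_equal(r0sq(p), oracle_r0_forward(p$y_exp, p$y_pred),
               tolerance = 1e-8)
})

test_that("reverse through-origin coefficient honours all three conventions", {
  ident <- activity_pairs(c(1.2, 2.5, 3.1), c(1.2, 2.5, 3.1))
  for (cv in c("reverse_centered", "literal", "uncentered"))
    expect_equal(r0sq_reverse(ident, cv), 1.0)
  prop <- activity_pairs(c(1, 2, 3), c(2, 4, 6))
  # literal form: k' = 2, residuals (-3, -6, -9), SStot = 2
  expect_equal(r0sq_reverse(prop, "literal"), -62.0)
  expect_equal(r0sq_reverse(prop, "reverse_centered"), 1.0)
  expect_error(r0sq_reverse(prop, "nonsense"))
})

test_that("uncentered through-origin coefficient is the squared uncentered correlation", {
  expect_equal(r0sq_uncentered(activity_pairs(1:3, 1:3)), 1.0)
  expect_equal(r0sq_uncentered(activity_pairs(c(1, 2, 3), c(2, 4, 6))), 1.0)
  expect_equal(r0sq_uncentered(activity_pairs(c(1, 0), c(0, 1))), 0.0)
})

test_that("rm2 reproduces published worked values and the ND sentinel", {
  expect_equal(rm2(0.9, 0.9), 0.9)
  # benchmark models 9 and 4: inputs from the summary table, printed outputs
  expect_equal(round(rm2(0.834, 0.823), 2), 0.75)
  expect_equal(round(rm2(0.725, 0.310), 2), 0.26)
  # benchmark model 13: r2 < r0sq, not determinable
  expect_true(is.na(rm2(0.372, 0.376)))
  expect_false(is.nan(rm2(0.372, 0.376)))
  expect_error(rm2(1.2, 0.5), class = "qsarval_error_usage")
})

test_that("CCC matches hand arithmetic and punishes bias", {
  y <- c(1.1, 2.4, 3.2, 4.0)
  expect_equal(ccc(activity_pairs(y, y)), 1.0)
  expect_equal(ccc(activity_pairs(c(1, 2, 3), c(2, 3, 4))), 4 / 7)
  expect_error(ccc(activity_pairs(c(1, 1, 1), c(2, 2, 2))),
               class = "qsarval_error_degenerate")
})

test_that("every metric agrees with its independent oracle on random vectors", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(3:50, 1)
    p <- random_pairs(n)
    e <- p$y_exp; y <- p$y_pred
    expect_equal(as.numeric(pearson_r2(p)), oracle_r2(e, y),
                 tolerance = 1e-10)
    s <- rto_slopes(p)
    os <- oracle_slopes(e, y)
    expect_equal(s$k, os[["k"]], tolerance = 1e-12)
    expect_equal(s$k_prime, os[["k_prime"]], tolerance = 1e-12)
    expect_equal(r0sq(p), oracle_r0_forward(e, y), tolerance = 1e-6)
    expect_equal(r0sq_uncentered(p), oracle_r0_uncentered(e, y),
                 tolerance = 1e-12)
    expect_equal(ccc(p), oracle_ccc(e, y), tolerance = 1e-12)
  }
})

test_that("algebraic invariants hold across seeded random inputs", {
  set.seed(202)
  for (rep in 1:200) {
    p <- random_pairs(sample(3:40, 1))
    s <- rto_slopes(p)
    # k * k' equals the uncentered squared correlation
    expect_equal(s$k * s$k_prime, r0sq_uncentered(p),
                 tolerance = 1e-12 * max(1, abs(s$k * s$k_prime)))
    # through-origin fit can never beat the intercept model
    expect_lte(r0sq(p), as.numeric(pearson_r2(p)) + 1e-12)
    # uncentered form is direction-symmetric
    swapped <- activity_pairs(p$y_pred, p$y_exp)
    expect_equal(r0sq_uncentered(swapped), r0sq_uncentered(p),
                 tolerance = 1e-12)
    # |CCC| bounded by |r|
    expect_lte(abs(ccc(p)), sqrt(as.numeric(pearson_r2(p))) + 1e-12)
  }
})

test_that("constant bias leaves r2 alone and drags CCC towards zero", {
  set.seed(303)
  p <- random_pairs(25)
  base_r2 <- as.numeric(pearson_r2(p))
  cccs <- sapply(c(0, 0.5, 1, 2, 5), function(b) {
    shifted <- activity_pairs(p$y_exp, p$y_pred + b)
    expect_equal(as.numeric(pearson_r2(shifted)), base_r2,
                 tolerance = 1e-12)
    ccc(shifted)
  })
  expect_true(all(diff(cccs) < 0))
  expect_lt(cccs[5], cccs[1] / 2)
})

test_that("rm2 is monotone in the r2 - r0 gap and equals r2 at zero gap", {
  for (r2v in c(0.4, 0.7, 0.95)) {
    gaps <- seq(0, r2v, length.out = 8)
    vals <- sapply(gaps, function(g) rm2(r2v, r2v - g))
    expect_equal(vals[1], r2v)
    expect_true(all(diff(vals) <= 0))
    expect_true(all(vals <= r2v))
  }
})
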