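# The five criterion families and their verdict objects.

new_verdict <- function(method, outcome, checks) {
  structure(list(method = method, outcome = outcome, checks = checks),
            class = "qsar_verdict")
}

check_rec <- function(pass, value, op, threshold, note = NULL) {
  list(pass = pass, value = value, op = op, threshold = threshold,
       note = note)
}

#' @export
print.qsar_verdict <- function(x, ...) {
  cat(sprintf("[%s] %s\n", x$method, toupper(x$outcome)))
  for (nm in names(x$checks)) {
    ck <- x$checks[[nm]]
    if (is.null(ck$pass)) {
      cat(sprintf("  %-12s unavailable (%s)\n", nm, ck$note))
    } else {
      cat(sprintf("  %-12s %-5s %s %s %s%s\n", nm,
                  ifelse(ck$pass, "pass", "FAIL"),
                  fmt_num(ck$value, 3), ck$op, fmt_num(ck$threshold, 3),
                  if (is.null(ck$note)) "" else paste0("  (", ck$note, ")")))
    }
  }
  invisible(x)
}

#' Golbraikh-Tropsha rules (method 1)
#'
#' A model is valid when all three rules hold:
#' 1. `r2 > 0.6`;
#' 2. at least one through-origin slope lies strictly inside
#'    (0.85, 1.15);
#' 3. at least one of the relative gaps `(r2 - r0sq) / r2` and
#'    `(r2 - r0prime_sq) / r2` is below 0.1.  A negative gap (through-origin
#'    coefficient exceeding r2, which some conventions produce) satisfies
#'    the rule.
#'
#' @param r2 squared correlation of the test split (must be positive).
#' @param k,k_prime through-origin slopes, see [rto_slopes()].
#' @param r0sq,r0prime_sq forward and reverse through-origin determination
#'   coefficients.
#' @return A `qsar_verdict` with outcome `"valid"` or `"invalid"` and one
#'   recorded subcheck per rule.
#' @export
gt_rules <- function(r2, k, k_prime, r0sq, r0prime_sq) {
  if (!all(is.finite(c(r2, k, k_prime, r0sq, r0prime_sq))))
    stop_usage("gt_rules expects finite inputs")
  if (r2 == 0)
    stop_degenerate("r2 = 0: relative gap rule undefined")
  ratio_f <- (r2 - r0sq) / r2
  ratio_r <- (r2 - r0prime_sq) / r2
  c1 <- r2 > 0.6
  c2k  <- k > 0.85 && k < 1.15
  c2kp <- k_prime > 0.85 && k_prime < 1.15
  c3f <- ratio_f < 0.1
  c3r <- ratio_r < 0.1
  checks <- list(
    r2_rule    = check_rec(c1, r2, ">", 0.6),
    slope_rule = check_rec(c2k || c2kp, if (c2k) k else k_prime,
                           "in", NA_real_,
                           note = sprintf("k = %.3f, k' = %.3f vs (0.85, 1.15)",
                                          k, k_prime)),
    ratio_rule = check_rec(c3f || c3r, min(ratio_f, ratio_r), "<", 0.1,
                           note = sprintf("gaps %.3f / %.3f", ratio_f, ratio_r)))
  ok <- c1 && (c2k || c2kp) && (c3f || c3r)
  new_verdict("golbraikh_tropsha", if (ok) "valid" else "invalid", checks)
}

#' rm2 criterion (method 2)
#'
#' Valid when Roy's rm2 is determinable and strictly exceeds 0.5.
#'
#' @param rm2 value from [rm2()]; `NA` means not determinable.
#' @return A `qsar_verdict`.
#' @export
rm2_rule <- function(rm2) {
  if (is.na(rm2)) {
    return(new_verdict("rm2", "invalid",
      list(rm2_rule = check_rec(FALSE, NA_real_, ">", 0.5,
                                note = "not determinable: r2 < r0sq"))))
  }
  new_verdict("rm2", if (rm2 > 0.5) "valid" else "invalid",
              list(rm2_rule = check_rec(rm2 > 0.5, rm2, ">", 0.5)))
}

#' Concordance criterion (method 3)
#'
#' Valid when CCC strictly exceeds 0.8.  When the supplied CCC is a value
#' rounded for printing (summary-level inputs), set `printed_precision` to
#' the number of decimals it carries: the comparison then allows half an
#' ulp of that precision, so a printed 0.80 -- whose unrounded value may lie
#' on either side of the threshold -- is not spuriously failed.
#'
#' @param ccc concordance correlation coefficient in \[-1, 1\].
#' @param printed_precision `NULL` for exact values (default), or an
#'   integer digit count for rounded inputs.
#' @return A `qsar_verdict`.
#' @export
ccc_rule <- function(ccc, printed_precision = NULL) {
  if (!is.finite(ccc) || ccc < -1 - 1e-9 || ccc > 1 + 1e-9)
    stop_usage("ccc must lie in [-1, 1]")
  tol <- if (is.null(printed_precision)) 0 else 0.5 * 10^(-printed_precision)
  pass <- ccc > 0.8 - tol
  note <- if (tol > 0) sprintf("rounded input, tolerance %g", tol) else NULL
  new_verdict("ccc", if (pass) "valid" else "invalid",
              list(ccc_rule = check_rec(pass, ccc, ">", 0.8, note = note)))
}

#' Train/test error-comparison criterion (method 4)
#'
#' Valid when the test-split `r2` exceeds 0.6 and the independent t-test
#' between training and test absolute errors is non-significant
#' (p > 0.05): the model should predict unseen compounds about as well as
#' its own training compounds.
#'
#' @param r2 squared correlation of the test split.
#' @param p_value p-value from [compare_errors()].
#' @return A `qsar_verdict`.
#' @export
error_ttest_rule <- function(r2, p_value) {
  if (!is.finite(r2) || !is.finite(p_value))
    stop_usage("error_ttest_rule expects finite inputs")
  c1 <- r2 > 0.6
  c2 <- p_value > 0.05
  new_verdict("error_ttest", if (c1 && c2) "valid" else "invalid",
              list(r2_rule = check_rec(c1, r2, ">", 0.6),
                   p_rule  = check_rec(c2, p_value, ">", 0.05)))
}

#' MAE / training-range classification (method 5)
#'
#' Classifies test-set predictivity against the span of the training
#' activities:
#' * GOOD when `aae <= 0.1 * range` and `aae + 3 * sd <= 0.2 * range`;
#' * BAD when `aae > 0.15 * range` or `aae + 3 * sd > 0.25 * range`;
#' * MODERATE otherwise.
#'
#' Because 0.1 < 0.15 and 0.2 < 0.25, the GOOD and BAD conditions are
#' mutually exclusive.
#'
#' @param aae average absolute error of the test split.
#' @param sd standard deviation of the test-split absolute errors.
#' @param training_range max minus min of the training experimental
#'   activities; must be positive.
#' @return A `qsar_verdict` with outcome `"good"`, `"moderate"` or
#'   `"bad"`.
#' @export
mae_range_class <- function(aae, sd, training_range) {
  if (!all(is.finite(c(aae, sd, training_range))) ||
      aae < 0 || sd < 0)
    stop_usage("aae and sd must be finite and non-negative")
  if (training_range <= 0)
    stop_degenerate("training range must be positive")
  spread <- aae + 3 * sd
  g1 <- aae <= 0.1 * training_range
  g2 <- spread <= 0.2 * training_range
  b1 <- aae > 0.15 * training_range
  b2 <- spread > 0.25 * training_range
  outcome <- if (g1 && g2) "good" else if (b1 || b2) "bad" else "moderate"
  new_verdict("mae_range", outcome, list(
    good_aae    = check_rec(g1, aae, "<=", 0.1 * training_range),
    good_spread = check_rec(g2, spread, "<=", 0.2 * training_range),
    bad_aae     = check_rec(!b1, aae, "<=", 0.15 * training_range),
    bad_spread  = check_rec(!b2, spread, "<=", 0.25 * training_range)))
}
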