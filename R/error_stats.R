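# Absolute-error summaries, the train/test error t-test and diagnostics.

#' Per-compound absolute errors
#'
#' `|y_exp - y_pred|`, order preserved.
#'
#' @inheritParams pearson_r2
#' @return Non-negative numeric vector of length `n`.
#' @export
absolute_errors <- function(pairs) {
  pairs <- as_pairs(pairs)
  abs(pairs$y_exp - pairs$y_pred)
}

#' Signed residuals
#'
#' `y_exp - y_pred` per compound, for residual diagnostics.
#'
#' @inheritParams pearson_r2
#' @return Numeric vector of length `n`.
#' @export
signed_residuals <- function(pairs) {
  pairs <- as_pairs(pairs)
  pairs$y_exp - pairs$y_pred
}

#' Proportions of absolute errors in the three conventional subgroups
#'
#' Splits absolute errors into AE < 0.1, 0.1 <= AE <= 0.2 and AE > 0.2 (the
#' middle bin is closed on both ends, so boundary values fall into it) and
#' returns the three proportions, which sum to 1.  Multiply by 100 for the
#' percentages used in relative-frequency bar charts.
#'
#' @param aes numeric vector of non-negative absolute errors.
#' @return Named numeric vector `c(lt_0.1, 0.1_to_0.2, gt_0.2)`.
#' @export
frequency_bins <- function(aes) {
  if (length(aes) == 0L) stop_insufficient("no absolute errors supplied")
  if (!all(is.finite(aes)) || any(aes < 0))
    stop_schema("absolute errors must be finite and non-negative")
  c(lt_0.1     = mean(aes < 0.1),
    `0.1_to_0.2` = mean(aes >= 0.1 & aes <= 0.2),
    gt_0.2     = mean(aes > 0.2))
}

#' Summary of a split's absolute errors
#'
#' Average absolute error (AAE), its standard deviation and the three
#' frequency-bin proportions from [frequency_bins()].
#'
#' @param aes numeric vector of non-negative absolute errors.
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n).
#' @return An object of class `error_summary`: a list with `aae`, `sd`,
#'   `n` and `bins`.
#' @export
error_summary <- function(aes, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(aes) == 0L) stop_insufficient("no absolute errors supplied")
  if (!all(is.finite(aes)) || any(aes < 0))
    stop_schema("absolute errors must be finite and non-negative")
  n <- length(aes)
  s <- if (n == 1L) 0 else sd(aes)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  structure(list(aae = mean(aes), sd = s, n = n, bins = frequency_bins(aes)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("AAE %s +/- %s (n = %d); AE bins <0.1 / 0.1-0.2 / >0.2: %s\n",
              fmt_num(x$aae, 3), fmt_num(x$sd, 3), x$n,
              paste0(round(100 * x$bins), "%", collapse = " / ")))
  invisible(x)
}

#' Independent t-test between training and test absolute errors
#'
#' Two-sided two-sample t-test on the absolute-error sequences of the two
#' splits.  A significant difference (p <= 0.05) signals that the model
#' predicts its own training compounds materially better than new ones.
#' `"student"` uses the pooled-variance test, `"welch"` the
#' unequal-variance form.  When both groups have zero variance, p is 1 for
#' equal means and 0 otherwise, by convention.
#'
#' @param train_aes,test_aes numeric vectors of absolute errors, each of
#'   length at least 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return An object of class `error_comparison`: a list with
#'   `t_statistic`, `p_value`, `df` and `variant`.
#' @export
compare_errors <- function(train_aes, test_aes,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(train_aes) < 2L || length(test_aes) < 2L)
    stop_insufficient("each error sequence needs at least 2 values")
  if (!all(is.finite(train_aes)) || !all(is.finite(test_aes)))
    stop_schema("absolute errors must be finite")
  if (var(train_aes) == 0 && var(test_aes) == 0) {
    eq <- isTRUE(all.equal(mean(train_aes), mean(test_aes)))
    out <- list(t_statistic = if (eq) 0 else Inf * sign(mean(train_aes) - mean(test_aes)),
                p_value = if (eq) 1 else 0,
                df = length(train_aes) + length(test_aes) - 2,
                variant = variant)
  } else {
    tt <- t.test(train_aes, test_aes, var.equal = variant == "student",
                 alternative = "two.sided")
    out <- list(t_statistic = unname(tt$statistic),
                p_value = unname(tt$p.value),
                df = unname(tt$parameter),
                variant = variant)
  }
  class(out) <- "error_comparison"
  out
}

#' @export
print.error_comparison <- function(x, ...) {
  cat(sprintf("%s t-test on absolute errors: t = %s, df = %s, p = %s\n",
              x$variant, fmt_num(x$t_statistic, 3), fmt_num(x$df, 1),
              fmt_num(x$p_value, 3)))
  invisible(x)
}
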