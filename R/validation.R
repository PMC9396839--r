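# Orchestration: evaluate one model's dataset (raw compound data) or one
# summary record against all five criterion families.

#' Evaluate a QSAR model against the five external-validation criteria
#'
#' The central entry point.  Given a [qsar_dataset()] (raw per-compound
#' data), computes the full metric set on the test split, the
#' absolute-error summaries of both splits, the training/test error t-test
#' and the training range, then applies all five criterion families:
#' Golbraikh-Tropsha rules, Roy's rm2, Lin's CCC, the error t-test rule and
#' the MAE/training-range classification.
#'
#' Given a one-row data frame of summary statistics (the shape returned by
#' [qsar_benchmark44()]), the same verdicts are produced from the printed
#' numbers alone; quantities that cannot be recomputed from summaries
#' (CCC, slopes, p-values) are taken from the record when present and
#' marked unavailable otherwise, and the CCC threshold comparison becomes
#' rounding-aware (see [ccc_rule()]).
#'
#' @param x a [qsar_dataset()] or a one-row summary data frame.
#' @param ... passed on to methods.
#' @return An object of class `qsar_validation` with `print`, `summary`,
#'   `plot` and `residuals` methods.
#' @examples
#' d <- synth_dataset(n_train = 30, n_test = 10, noise_sd = 0.2, seed = 1)
#' v <- qsar_validate(d)
#' v
#' summary(v)
#' @export
qsar_validate <- function(x, ...) UseMethod("qsar_validate")

#' @rdname qsar_validate
#' @param ttest `"student"` (pooled variance, default) or `"welch"`.
#' @param convention reverse through-origin convention, see
#'   [r0sq_reverse()].
#' @param sd_type standard-deviation denominator, see [error_summary()].
#' @export
qsar_validate.qsar_dataset <- function(x, ttest = c("student", "welch"),
                                       convention = "reverse_centered",
                                       sd_type = "sample", ...) {
  ttest <- match.arg(ttest)
  metrics <- withCallingHandlers(
    qsar_metrics(x$test, convention = convention),
    error = function(e) {
      e$message <- sprintf("model '%s': %s", x$model_id, conditionMessage(e))
      stop(e)
    })
  train_aes <- absolute_errors(x$train)
  test_aes <- absolute_errors(x$test)
  train_err <- error_summary(train_aes, sd_type)
  test_err <- error_summary(test_aes, sd_type)
  cmp <- compare_errors(train_aes, test_aes, ttest)
  training_range <- diff(range(x$train$y_exp))
  verdicts <- list(
    m1_golbraikh_tropsha = gt_rules(metrics$r2, metrics$k, metrics$k_prime,
                                    metrics$r0sq, metrics$r0sq_reverse),
    m2_rm2 = rm2_rule(metrics$rm2),
    m3_ccc = ccc_rule(metrics$ccc),
    m4_error_ttest = error_ttest_rule(metrics$r2, cmp$p_value),
    m5_mae_range = mae_range_class(test_err$aae, test_err$sd,
                                   training_range))
  structure(list(model_id = x$model_id, mode = "raw", metrics = metrics,
                 train_errors = train_err, test_errors = test_err,
                 comparison = cmp, training_range = training_range,
                 verdicts = verdicts, dataset = x),
            class = "qsar_validation")
}

unavailable_verdict <- function(method, what) {
  new_verdict(method, "unavailable",
              stats::setNames(list(list(pass = NULL, value = NA_real_,
                                        op = "", threshold = NA_real_,
                                        note = paste(what,
                                          "not computable from summary data"))),
                              method))
}

#' @rdname qsar_validate
#' @export
qsar_validate.data.frame <- function(x, ...) {
  if (nrow(x) != 1L)
    stop_usage("summary-mode qsar_validate expects exactly one record; use qsar_validate_batch() for several")
  rec <- as.list(x)
  need <- c("r2", "r0sq", "r0sq_rev", "aae_test", "sd_test",
            "training_range")
  missing_f <- need[!vapply(need, function(f)
    !is.null(rec[[f]]) && is.finite(rec[[f]]), logical(1))]
  if (length(missing_f))
    stop_schema(sprintf("summary record lacks field(s): %s",
                        paste(missing_f, collapse = ", ")))
  get_opt <- function(f) {
    v <- rec[[f]]
    if (is.null(v) || !is.finite(v)) NA_real_ else v
  }
  k <- get_opt("k"); kp <- get_opt("k_prime")
  ccc_v <- get_opt("ccc"); p_v <- get_opt("p_value")
  rm2_v <- rm2(rec$r2, rec$r0sq)
  metrics <- structure(list(
    r2 = rec$r2, r_sign = 1L, k = k, k_prime = kp, r0sq = rec$r0sq,
    r0sq_reverse = rec$r0sq_rev, r0sq_uncentered = get_opt("r0sq_unc"),
    rm2 = rm2_v, ccc = ccc_v, convention = "as_reported"),
    class = "qsar_metrics")
  m1 <- if (is.na(k) || is.na(kp)) {
    unavailable_verdict("golbraikh_tropsha", "through-origin slopes")
  } else gt_rules(rec$r2, k, kp, rec$r0sq, rec$r0sq_rev)
  m3 <- if (is.na(ccc_v)) unavailable_verdict("ccc", "CCC")
        else ccc_rule(ccc_v, printed_precision = 2)
  m4 <- if (is.na(p_v)) unavailable_verdict("error_ttest", "p-value")
        else error_ttest_rule(rec$r2, p_v)
  mk_err <- function(aae, s, n) {
    if (is.na(aae)) return(NULL)
    structure(list(aae = aae, sd = s, n = n,
                   bins = c(lt_0.1 = NA_real_, `0.1_to_0.2` = NA_real_,
                            gt_0.2 = NA_real_)),
              class = "error_summary")
  }
  verdicts <- list(
    m1_golbraikh_tropsha = m1,
    m2_rm2 = rm2_rule(rm2_v),
    m3_ccc = m3,
    m4_error_ttest = m4,
    m5_mae_range = mae_range_class(rec$aae_test, rec$sd_test,
                                   rec$training_range))
  structure(list(
    model_id = as.character(rec$model %||% "summary"),
    mode = "summary", metrics = metrics,
    train_errors = mk_err(get_opt("aae_train"), get_opt("sd_train"),
                          rec$n_train %||% NA_integer_),
    test_errors = mk_err(rec$aae_test, rec$sd_test,
                         rec$n_test %||% NA_integer_),
    comparison = if (is.na(p_v)) NULL else
      structure(list(t_statistic = NA_real_, p_value = p_v, df = NA_real_,
                     variant = "as_reported"), class = "error_comparison"),
    training_range = rec$training_range,
    verdicts = verdicts, dataset = NULL),
    class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, ...) {
  cat(sprintf("External validation of QSAR model '%s' (%s data)\n",
              x$model_id, x$mode))
  v <- x$verdicts
  out <- vapply(v, function(z) z$outcome, character(1))
  lab <- c(m1_golbraikh_tropsha = "1 Golbraikh-Tropsha rules",
           m2_rm2 = "2 rm2 > 0.5",
           m3_ccc = "3 CCC > 0.8",
           m4_error_ttest = "4 train/test error t-test",
           m5_mae_range = "5 MAE vs training range")
  for (nm in names(out))
    cat(sprintf("  method %-28s %s\n", lab[[nm]], toupper(out[[nm]])))
  cat(sprintf("  r2 = %s, rm2 = %s, CCC = %s, test AAE = %s +/- %s, range = %s\n",
              fmt_num(x$metrics$r2, 3), fmt_num(x$metrics$rm2, 2),
              fmt_num(x$metrics$ccc, 2),
              fmt_num(x$test_errors$aae, 3), fmt_num(x$test_errors$sd, 3),
              fmt_num(x$training_range, 2)))
  invisible(x)
}

#' @export
summary.qsar_validation <- function(object, ...) {
  print(object)
  cat("\nSubchecks:\n")
  for (v in object$verdicts) print(v)
  if (!is.null(object$comparison)) print(object$comparison)
  if (object$metrics$r_sign < 0)
    cat("warning: experimental and calculated activities are negatively correlated\n")
  invisible(object)
}

#' @export
residuals.qsar_validation <- function(object, split = c("test", "train"),
                                      ...) {
  split <- match.arg(split)
  if (is.null(object$dataset))
    stop_usage("residuals are only available for raw-data validations")
  signed_residuals(object$dataset[[split]])
}

#' Diagnostic plots for a validation report
#'
#' Two base-graphics panels in the style used for error diagnostics of
#' QSAR models: relative frequencies of the absolute errors in the three
#' conventional subgroups (< 0.1, 0.1-0.2, > 0.2) for both splits, and the
#' signed residuals of the test split against experimental activity.
#'
#' @param x a raw-data `qsar_validation` object.
#' @param which `"bins"`, `"residuals"` or `"both"` (default).
#' @param ... ignored.
#' @export
plot.qsar_validation <- function(x, which = c("both", "bins", "residuals"),
                                 ...) {
  which <- match.arg(which)
  if (is.null(x$dataset))
    stop_usage("plots need raw compound data")
  if (which == "both") {
    old <- par(mfrow = c(1, 2))
    on.exit(par(old))
  }
  if (which %in% c("both", "bins")) {
    m <- 100 * rbind(train = x$train_errors$bins, test = x$test_errors$bins)
    barplot(m, beside = TRUE, names.arg = c("<0.1", "0.1-0.2", ">0.2"),
            ylab = "relative frequency (%)", xlab = "absolute error",
            legend.text = rownames(m),
            main = sprintf("model %s: AE distribution", x$model_id))
  }
  if (which %in% c("both", "residuals")) {
    te <- x$dataset$test
    plot(te$y_exp, signed_residuals(te), xlab = "experimental activity",
         ylab = "residual (exp - calc)",
         main = sprintf("model %s: test residuals", x$model_id))
    points(x$dataset$train$y_exp, signed_residuals(x$dataset$train),
           pch = 3, col = "grey50")
    abline(h = 0, lty = 2)
    legend("topright", pch = c(1, 3), col = c("black", "grey50"),
           legend = c("test", "train"), bty = "n")
  }
  invisible(x)
}
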