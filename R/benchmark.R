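# The embedded 44-model benchmark and its no-download reproduction.

#' Summary statistics for 44 published QSAR models
#'
#' A compiled benchmark of external-validation summary statistics for 44
#' QSAR models of biologically active compounds collected from the
#' literature.  Each row carries the split sizes, the test-split squared
#' correlation `r2`, the through-origin determination coefficients under
#' the forward (`r0sq`), reverse (`r0sq_rev`; published convention, not
#' uniform across sources) and uncentered (`r0sq_unc`) forms, the
#' training/test average absolute errors with standard deviations, the
#' training-set activity range, and the values reported alongside in the
#' published comparison: through-origin slopes `k`/`k_prime`, `ccc`, the
#' training-vs-test t-test `p_value` (`p_below` flags values reported only
#' as below 0.01), the reported derived columns (`*_rep`) and the reported
#' GOOD/MODERATE/BAD letter (`class_rep`).
#'
#' Raw per-compound activities for these models are not redistributed
#' here; summary-level reproduction via [reproduce_benchmark()] needs only
#' this table.
#'
#' @return A 44-row data frame.
#' @examples
#' b <- qsar_benchmark44()
#' sum(b$r2 < 0.6)
#' @export
qsar_benchmark44 <- function() {
  path <- system.file("extdata", "qsar_models_44.csv", package = "qsarval",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "ND"))
  stopifnot(nrow(df) == 44L)
  df
}

#' Validate several models at once
#'
#' Applies [qsar_validate()] to a list of [qsar_dataset()] objects or to
#' every row of a summary data frame (e.g. [qsar_benchmark44()]).
#'
#' @param x list of datasets, or a summary data frame.
#' @param ... passed to [qsar_validate()].
#' @return A list of `qsar_validation` objects, class
#'   `qsar_validation_batch`.
#' @export
qsar_validate_batch <- function(x, ...) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) stop_insufficient("empty summary table")
    reports <- lapply(seq_len(nrow(x)),
                      function(i) qsar_validate(x[i, , drop = FALSE], ...))
  } else if (is.list(x) && length(x)) {
    reports <- lapply(x, qsar_validate, ...)
  } else stop_insufficient("no models supplied")
  structure(reports, class = "qsar_validation_batch")
}

#' Per-criterion counts over a batch of validations
#'
#' Counts of valid/invalid outcomes per criterion, of the method-5
#' classes with integer percentages, and the cross-tabulation observed
#' between the CCC criterion and the others.
#'
#' @param object a `qsar_validation_batch`.
#' @param ... ignored.
#' @return A list of class `qsar_batch_summary`.
#' @export
summary.qsar_validation_batch <- function(object, ...) {
  if (length(object) == 0L) stop_insufficient("empty batch")
  out_of <- function(method)
    vapply(object, function(r) r$verdicts[[method]]$outcome, character(1))
  m_names <- c("m1_golbraikh_tropsha", "m2_rm2", "m3_ccc", "m4_error_ttest")
  valid <- vapply(m_names, function(m) out_of(m) == "valid",
                  logical(length(object)))
  if (is.null(dim(valid)))
    valid <- matrix(valid, nrow = 1L, dimnames = list(NULL, m_names))
  cls <- out_of("m5_mae_range")
  n <- length(object)
  res <- list(
    n = n,
    valid_counts = colSums(valid),
    invalid_counts = colSums(!valid),
    class_counts = table(factor(cls, levels = c("good", "moderate", "bad"))),
    class_percent = round(100 * table(factor(cls,
      levels = c("good", "moderate", "bad"))) / n),
    agreement = list(
      ccc_and_m1 = sum(valid[, "m3_ccc"] & valid[, "m1_golbraikh_tropsha"]),
      ccc_and_m4 = sum(valid[, "m3_ccc"] & valid[, "m4_error_ttest"]),
      m1_and_m2 = sum(valid[, "m1_golbraikh_tropsha"] & valid[, "m2_rm2"])))
  class(res) <- "qsar_batch_summary"
  res
}

#' @export
print.qsar_batch_summary <- function(x, ...) {
  cat(sprintf("Batch of %d models\n", x$n))
  for (m in names(x$valid_counts))
    cat(sprintf("  %-22s %d valid / %d invalid\n", m,
                x$valid_counts[[m]], x$invalid_counts[[m]]))
  cat(sprintf("  method 5: %s\n",
              paste(sprintf("%s %d (%d%%)", names(x$class_counts),
                            x$class_counts, x$class_percent),
                    collapse = ", ")))
  cat(sprintf("  CCC-valid that are also rule-valid (method 1): %d\n",
              x$agreement$ccc_and_m1))
  cat(sprintf("  CCC-valid with non-significant error difference: %d\n",
              x$agreement$ccc_and_m4))
  invisible(x)
}

#' Reproduce the published 44-model comparison from summary data alone
#'
#' Recomputes, for every benchmark row, the derived quantities of the
#' published comparison table — the rule-III relative gaps, `rm2`,
#' `AAE + 3 SD` and the 0.1/0.15/0.2/0.25 training-range multiples — plus
#' all criterion verdicts, and tallies the headline counts: models with
#' r2 < 0.6, models with rm2 > 0.5, models invalid under the
#' Golbraikh-Tropsha rule set, CCC-valid models, method-4-valid models,
#' their overlap, and the GOOD/MODERATE/BAD percentages (computed, and
#' from the reported letters).
#'
#' @param bench a benchmark-shaped data frame; defaults to
#'   [qsar_benchmark44()].
#' @return A list of class `qsar_benchmark_repro` with elements `table`
#'   (per-model derived columns and verdicts), `reports` (the batch) and
#'   `counts`.
#' @export
reproduce_benchmark <- function(bench = qsar_benchmark44()) {
  reports <- qsar_validate_batch(bench)
  derived <- data.frame(
    model = bench$model,
    ratio_fwd = (bench$r2 - bench$r0sq) / bench$r2,
    ratio_rev = (bench$r2 - bench$r0sq_rev) / bench$r2,
    rm2 = mapply(rm2, bench$r2, bench$r0sq),
    aae_3sd = bench$aae_test + 3 * bench$sd_test,
    mult10 = 0.10 * bench$training_range,
    mult20 = 0.20 * bench$training_range,
    mult15 = 0.15 * bench$training_range,
    mult25 = 0.25 * bench$training_range)
  verdict_of <- function(m)
    vapply(reports, function(r) r$verdicts[[m]]$outcome, character(1))
  derived$m1 <- verdict_of("m1_golbraikh_tropsha")
  derived$m2 <- verdict_of("m2_rm2")
  derived$m3 <- verdict_of("m3_ccc")
  derived$m4 <- verdict_of("m4_error_ttest")
  derived$class <- verdict_of("m5_mae_range")
  letter <- c(good = "G", moderate = "M", bad = "B")
  derived$class_letter <- letter[derived$class]

  cls_rep <- factor(bench$class_rep, levels = c("G", "M", "B"))
  counts <- list(
    n = nrow(bench),
    r2_below_0.6 = sum(bench$r2 < 0.6),
    rm2_valid = sum(derived$m2 == "valid"),
    m1_invalid = sum(derived$m1 == "invalid"),
    ratio_rule_fail = sum(pmin(derived$ratio_fwd, derived$ratio_rev) >= 0.1),
    ccc_valid = sum(derived$m3 == "valid"),
    m4_valid = sum(derived$m4 == "valid"),
    ccc_and_m4 = sum(derived$m3 == "valid" & derived$m4 == "valid"),
    class_percent_computed = round(100 * table(factor(derived$class,
      levels = c("good", "moderate", "bad"))) / nrow(bench)),
    class_percent_reported = round(100 * table(cls_rep) / nrow(bench)))
  structure(list(table = derived, reports = reports, counts = counts),
            class = "qsar_benchmark_repro")
}

#' @export
print.qsar_benchmark_repro <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("Reproduction over %d benchmark models\n", ct$n))
  cat(sprintf("  r2 < 0.6:                       %d\n", ct$r2_below_0.6))
  cat(sprintf("  rm2 > 0.5:                      %d\n", ct$rm2_valid))
  cat(sprintf("  Golbraikh-Tropsha invalid:      %d\n", ct$m1_invalid))
  cat(sprintf("  CCC-valid:                      %d\n", ct$ccc_valid))
  cat(sprintf("  error-t-test valid (method 4):  %d\n", ct$m4_valid))
  cat(sprintf("  CCC-valid and method-4 valid:   %d\n", ct$ccc_and_m4))
  cat(sprintf("  classes (computed):  G %d%% / M %d%% / B %d%%\n",
              ct$class_percent_computed[["good"]],
              ct$class_percent_computed[["moderate"]],
              ct$class_percent_computed[["bad"]]))
  cat(sprintf("  classes (reported):  G %d%% / M %d%% / B %d%%\n",
              ct$class_percent_reported[["G"]],
              ct$class_percent_reported[["M"]],
              ct$class_percent_reported[["B"]]))
  invisible(x)
}
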