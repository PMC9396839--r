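# Report serialization: JSON for single models, TSV tables for batches.

verdict_as_list <- function(v) {
  list(outcome = v$outcome,
       checks = lapply(v$checks, function(ck)
         list(pass = ck$pass, value = ck$value, op = ck$op,
              threshold = ck$threshold, note = ck$note)))
}

report_as_list <- function(x) {
  stopifnot(inherits(x, "qsar_validation"))
  m <- x$metrics
  list(
    model_id = x$model_id,
    mode = x$mode,
    metrics = list(r2 = m$r2, r_sign = m$r_sign, k = m$k,
                   k_prime = m$k_prime, r0sq = m$r0sq,
                   r0sq_reverse = m$r0sq_reverse,
                   r0sq_uncentered = m$r0sq_uncentered, rm2 = m$rm2,
                   ccc = m$ccc, convention = m$convention),
    train_errors = if (is.null(x$train_errors)) NULL else
      list(aae = x$train_errors$aae, sd = x$train_errors$sd,
           n = x$train_errors$n, bins = as.list(x$train_errors$bins)),
    test_errors = list(aae = x$test_errors$aae, sd = x$test_errors$sd,
                       n = x$test_errors$n,
                       bins = as.list(x$test_errors$bins)),
    comparison = if (is.null(x$comparison)) NULL else
      list(t_statistic = x$comparison$t_statistic,
           p_value = x$comparison$p_value, df = x$comparison$df,
           variant = x$comparison$variant),
    training_range = x$training_range,
    verdicts = lapply(x$verdicts, verdict_as_list))
}

batch_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    m <- r$metrics
    data.frame(
      model = r$model_id,
      r2 = fmt_num(m$r2, 3),
      k = fmt_num(m$k, 2), k_prime = fmt_num(m$k_prime, 2),
      ratio_fwd = fmt_num((m$r2 - m$r0sq) / m$r2, 3),
      ratio_rev = fmt_num((m$r2 - m$r0sq_reverse) / m$r2, 3),
      rm2 = fmt_num(m$rm2, 2),
      ccc = fmt_num(m$ccc, 2),
      p_value = fmt_num(if (is.null(r$comparison)) NA_real_ else
        r$comparison$p_value, 2),
      aae_3sd = fmt_num(r$test_errors$aae + 3 * r$test_errors$sd, 2),
      mult10 = fmt_num(0.10 * r$training_range, 2),
      mult20 = fmt_num(0.20 * r$training_range, 2),
      mult15 = fmt_num(0.15 * r$training_range, 2),
      mult25 = fmt_num(0.25 * r$training_range, 2),
      m1 = r$verdicts$m1_golbraikh_tropsha$outcome,
      m2 = r$verdicts$m2_rm2$outcome,
      m3 = r$verdicts$m3_ccc$outcome,
      m4 = r$verdicts$m4_error_ttest$outcome,
      class = c(good = "G", moderate = "M",
                bad = "B")[r$verdicts$m5_mae_range$outcome],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize validation reports
#'
#' Single reports serialize to JSON at full floating precision (the
#' not-determinable rm2 becomes JSON `null`); batches serialize to a TSV
#' table with one row per model, numbers rendered at the conventional 2-3
#' decimals (half away from zero) and `ND` written literally.
#'
#' @param x a `qsar_validation`, `qsar_validation_batch` or
#'   `qsar_benchmark_repro` object.
#' @param path output file.
#' @param format `"json"` or `"tsv"`; the default suits the object.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = NULL) UseMethod("write_report")

#' @export
write_report.qsar_validation <- function(x, path, format = "json") {
  format <- match.arg(format, c("json", "tsv"))
  if (format == "json") {
    jsonlite::write_json(report_as_list(x), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  } else {
    utils::write.table(batch_table(list(x)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
write_report.qsar_validation_batch <- function(x, path, format = "tsv") {
  format <- match.arg(format, c("json", "tsv"))
  if (format == "tsv") {
    utils::write.table(batch_table(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(lapply(x, report_as_list), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' @export
write_report.qsar_benchmark_repro <- function(x, path, format = "tsv") {
  write_report(x$reports, path, format)
}

#' Re-read a JSON report
#'
#' Inverse of the JSON form of [write_report()]; values come back at full
#' precision.
#'
#' @param path path to a JSON report.
#' @return The report as a plain named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
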