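# Conditions ------------------------------------------------------------

qv_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "qsarval_error")))
}

stop_insufficient <- function(msg) qv_stop(msg, "qsarval_error_insufficient")
stop_degenerate   <- function(msg) qv_stop(msg, "qsarval_error_degenerate")
stop_schema       <- function(msg) qv_stop(msg, "qsarval_error_schema")
stop_usage        <- function(msg) qv_stop(msg, "qsarval_error_usage")

is_constant <- function(x) diff(range(x)) == 0

# round half away from zero, the convention of the printed tables
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "ND", formatC(round_half_away(x, digits),
                                 format = "f", digits = digits))
}

# Activity pairs ---------------------------------------------------------

#' Paired experimental and calculated activities
#'
#' Container for one data split of a QSAR model: the experimental (log-scale,
#' unitless) biological activities and the activities calculated by the
#' model for the same compounds, in the same order.
#'
#' All downstream metrics consume this object.  Values must be finite;
#' length checks specific to each metric (for example, at least 3 compounds
#' for any centered statistic) are enforced by the metric functions.
#'
#' @param y_exp numeric vector of experimental activities.
#' @param y_pred numeric vector of calculated (predicted) activities,
#'   same length as `y_exp`.
#' @return An object of class `activity_pairs`: a list with elements
#'   `y_exp`, `y_pred` and `n`.
#' @examples
#' p <- activity_pairs(c(5.1, 6.2, 7.0, 6.4), c(5.3, 6.0, 6.8, 6.6))
#' pearson_r2(p)
#' @export
activity_pairs <- function(y_exp, y_pred) {
  y_exp <- as.numeric(y_exp)
  y_pred <- as.numeric(y_pred)
  if (length(y_exp) != length(y_pred))
    stop_schema(sprintf("y_exp (%d) and y_pred (%d) differ in length",
                        length(y_exp), length(y_pred)))
  if (length(y_exp) == 0L)
    stop_insufficient("activity_pairs needs at least one compound")
  if (!all(is.finite(y_exp)) || !all(is.finite(y_pred)))
    stop_schema("activities must be finite (no NA/NaN/Inf)")
  structure(list(y_exp = y_exp, y_pred = y_pred, n = length(y_exp)),
            class = "activity_pairs")
}

as_pairs <- function(x) {
  if (inherits(x, "activity_pairs")) return(x)
  if (is.data.frame(x)) return(activity_pairs(x$y_exp, x$y_pred))
  stop_usage("expected an activity_pairs object")
}

#' @export
print.activity_pairs <- function(x, ...) {
  cat(sprintf("activity pairs: %d compounds\n", x$n))
  cat(sprintf("  experimental: [%.3g, %.3g]  calculated: [%.3g, %.3g]\n",
              min(x$y_exp), max(x$y_exp), min(x$y_pred), max(x$y_pred)))
  invisible(x)
}

check_pairs <- function(pairs, n_min = 2L, nonconstant_exp = FALSE,
                        nonconstant_pred = FALSE) {
  if (pairs$n < n_min)
    stop_insufficient(sprintf("need at least %d compounds, got %d",
                              n_min, pairs$n))
  if (nonconstant_exp && is_constant(pairs$y_exp))
    stop_degenerate("experimental activities are constant")
  if (nonconstant_pred && is_constant(pairs$y_pred))
    stop_degenerate("calculated activities are constant")
  invisible(pairs)
}
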