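# Seeded synthetic datasets with controlled error structure, so every
# metric and verdict can be exercised without external data.

#' Generate a synthetic QSAR external-validation dataset
#'
#' Emulates the (experimental, calculated) pair structure the validation
#' criteria consume — no descriptors and no model fitting.  Experimental
#' activities are drawn uniformly over `activity_range` (so the expected
#' training range approaches `diff(activity_range)`); calculated
#' activities are truth plus a constant `bias` plus noise of standard
#' deviation `noise_sd` (Gaussian by default, or a scaled Student-t with 3
#' degrees of freedom for heavy, outlier-like tails); a
#' `floor(outlier_fraction * n)` subset of compounds is additionally
#' shifted by `outlier_shift`, in both splits, the test split only, or the
#' training split only.
#'
#' Defaults mirror a typical benchmarked model: 40 training and 10 test
#' compounds over a 4-log-unit activity range with noise_sd 0.25 (giving an
#' expected absolute error of about 0.2), no bias and no contamination.
#' The same `seed` and parameters always regenerate the identical dataset;
#' the caller's random-number state is left untouched.
#'
#' @param n_train,n_test compounds per split (each at least 3).
#' @param activity_range length-2 numeric, low and high experimental
#'   activity.
#' @param noise_sd standard deviation of the prediction noise (activity
#'   units, non-negative).
#' @param bias constant added to every calculated activity.
#' @param outlier_fraction fraction in \[0, 1) of compounds shifted.
#' @param outlier_shift size of the shift (activity units).
#' @param outlier_split `"both"` (default), `"test"` or `"train"`.
#' @param noise `"gaussian"` (default) or `"t"` (scaled Student-t, df 3).
#' @param seed integer seed; fully determines the dataset.
#' @param model_id identifier for the generated dataset.
#' @return A [qsar_dataset()].
#' @examples
#' d <- synth_dataset(seed = 42)
#' qsar_validate(d)
#' @export
synth_dataset <- function(n_train = 40, n_test = 10,
                          activity_range = c(2, 6), noise_sd = 0.25,
                          bias = 0, outlier_fraction = 0,
                          outlier_shift = 0,
                          outlier_split = c("both", "test", "train"),
                          noise = c("gaussian", "t"), seed = 1,
                          model_id = "synthetic") {
  outlier_split <- match.arg(outlier_split)
  noise <- match.arg(noise)
  if (n_train < 3 || n_test < 3)
    stop_usage("n_train and n_test must each be at least 3")
  if (length(activity_range) != 2L ||
      activity_range[2] <= activity_range[1])
    stop_usage("activity_range must be c(low, high) with high > low")
  if (noise_sd < 0) stop_usage("noise_sd must be non-negative")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop_usage("outlier_fraction must lie in [0, 1)")
  seed <- as.integer(seed)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  draw_split <- function(n, contaminate) {
    truth <- runif(n, activity_range[1], activity_range[2])
    eps <- switch(noise,
      gaussian = rnorm(n, 0, noise_sd),
      t = noise_sd * rt(n, df = 3) / sqrt(3))
    pred <- truth + bias + eps
    k <- floor(outlier_fraction * n)
    if (contaminate && k > 0) {
      idx <- sample.int(n, k)
      pred[idx] <- pred[idx] + outlier_shift
    }
    activity_pairs(truth, pred)
  }
  train <- draw_split(n_train, outlier_split %in% c("both", "train"))
  test <- draw_split(n_test, outlier_split %in% c("both", "test"))
  qsar_dataset(model_id, train, test,
               source = sprintf("synthetic (seed %d)", seed))
}

#' One-parameter grid of synthetic datasets
#'
#' Generates one dataset per value of a single varied parameter, holding
#' all other arguments of [synth_dataset()] fixed.  Seeds are derived
#' deterministically as `seed + index - 1`, so the grid is reproducible
#' and its points are independent draws.
#'
#' @param param name of the [synth_dataset()] argument to vary.
#' @param values vector of values for `param` (non-empty).
#' @param ... fixed arguments passed to [synth_dataset()], including the
#'   base `seed`.
#' @return A list of [qsar_dataset()] objects, one per grid point.
#' @examples
#' grid <- synth_grid("bias", c(0, 0.5, 1), noise_sd = 0.1, seed = 7)
#' sapply(grid, function(d) ccc(d$test))
#' @export
synth_grid <- function(param, values, ...) {
  fixed <- list(...)
  if (length(values) == 0L) stop_usage("empty parameter grid")
  if (!param %in% names(formals(synth_dataset)))
    stop_usage(sprintf("unknown synth_dataset parameter '%s'", param))
  base_seed <- as.integer(fixed$seed %||% 1L)
  lapply(seq_along(values), function(i) {
    args <- fixed
    args[[param]] <- values[[i]]
    args$seed <- base_seed + i - 1L
    args$model_id <- sprintf("%s_%s_%g", fixed$model_id %||% "grid",
                             param, as.numeric(values[[i]]))
    do.call(synth_dataset, args)
  })
}
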