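# Dataset container, CSV input and report serialization.

#' A QSAR model's external-validation dataset
#'
#' Bundles the training and test splits of one model.  Each split needs at
#' least 3 compounds; when compound identifiers are supplied the two splits
#' must be disjoint (a shared identifier means test-set leakage).
#'
#' @param model_id character identifier for the model.
#' @param train,test [activity_pairs()] objects (or data frames with
#'   `y_exp`/`y_pred` columns).
#' @param source free-text provenance.
#' @param train_ids,test_ids optional compound identifiers, parallel to the
#'   splits.
#' @return An object of class `qsar_dataset`.
#' @export
qsar_dataset <- function(model_id, train, test, source = "",
                         train_ids = NULL, test_ids = NULL) {
  train <- as_pairs(train)
  test <- as_pairs(test)
  if (train$n < 3L || test$n < 3L)
    stop_insufficient("train and test splits each need at least 3 compounds")
  if (!is.null(train_ids) && !is.null(test_ids)) {
    leaked <- intersect(train_ids, test_ids)
    if (length(leaked))
      stop_schema(sprintf("compound id(s) present in both splits: %s",
                          paste(utils::head(leaked, 5), collapse = ", ")))
  }
  structure(list(model_id = as.character(model_id), train = train,
                 test = test, source = source,
                 train_ids = train_ids, test_ids = test_ids),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("QSAR dataset '%s': %d training / %d test compounds\n",
              x$model_id, x$train$n, x$test$n))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Read a per-model activity CSV
#'
#' Expects a comma-separated, period-decimal, UTF-8 file with a header and
#' columns `compound_id`, `split`, `y_exp`, `y_calc`; `split` must be
#' `"train"` or `"test"`.  Row order is preserved within each split.
#'
#' @param path path to the CSV file.
#' @param model_id identifier for the model; defaults to the file name
#'   without extension.
#' @return A [qsar_dataset()].
#' @export
read_qsar_dataset <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop_schema(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound_id", "split", "y_exp", "y_calc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_schema(sprintf("missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  bad_split <- setdiff(unique(df$split), c("train", "test"))
  if (length(bad_split))
    stop_schema(sprintf("unknown split label(s): %s",
                        paste(bad_split, collapse = ", ")))
  for (col in c("y_exp", "y_calc")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | !is.finite(v))
    if (length(bad))
      stop_schema(sprintf("non-numeric %s at row %d", col, bad[1]))
    df[[col]] <- v
  }
  tr <- df[df$split == "train", ]
  te <- df[df$split == "test", ]
  if (nrow(tr) < 3L || nrow(te) < 3L)
    stop_insufficient("each split needs at least 3 rows")
  if (is.null(model_id))
    model_id <- sub("\\.[^.]*$", "", basename(path))
  qsar_dataset(model_id,
               activity_pairs(tr$y_exp, tr$y_calc),
               activity_pairs(te$y_exp, te$y_calc),
               source = path,
               train_ids = tr$compound_id, test_ids = te$compound_id)
}

#' Write a dataset back to the standard CSV schema
#'
#' @param dataset a [qsar_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qsar_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  ids_tr <- dataset$train_ids %||% paste0("trn_", seq_len(dataset$train$n))
  ids_te <- dataset$test_ids %||% paste0("tst_", seq_len(dataset$test$n))
  df <- rbind(
    data.frame(compound_id = ids_tr, split = "train",
               y_exp = dataset$train$y_exp, y_calc = dataset$train$y_pred),
    data.frame(compound_id = ids_te, split = "test",
               y_exp = dataset$test$y_exp, y_calc = dataset$test$y_pred))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen a dataset for common data problems
#'
#' Returns warnings (as data, not conditions) for duplicated compound
#' identifiers within a split, constant activity columns, and extreme
#' absolute errors (AE above mean + 3 standard deviations of its split).
#' An empty data frame means no issue was found.
#'
#' @param dataset a [qsar_dataset()].
#' @return A data frame with columns `split`, `type` and `detail`.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  issues <- list()
  add <- function(split, type, detail)
    issues[[length(issues) + 1L]] <<- data.frame(split = split, type = type,
                                                 detail = detail)
  for (sp in c("train", "test")) {
    pairs <- dataset[[sp]]
    ids <- dataset[[paste0(sp, "_ids")]]
    if (!is.null(ids)) {
      dup <- unique(ids[duplicated(ids)])
      for (d in dup) add(sp, "duplicate_id", as.character(d))
    }
    if (is_constant(pairs$y_exp)) add(sp, "constant_column", "y_exp")
    if (is_constant(pairs$y_pred)) add(sp, "constant_column", "y_calc")
    aes <- absolute_errors(pairs)
    if (length(aes) > 2 && sd(aes) > 0) {
      out <- which(aes > mean(aes) + 3 * sd(aes))
      for (i in out)
        add(sp, "ae_outlier",
            sprintf("row %d: AE %.3f > mean + 3 SD (%.3f)", i, aes[i],
                    mean(aes) + 3 * sd(aes)))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(split = character(), type = character(),
                  detail = character())
}
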