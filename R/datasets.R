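#' Load a labelled tabular dataset from CSV
#'
#' Reads a comma-separated file with a header row, one label column and
#' numeric feature columns, the layout used by the classic UCI-style tables
#' (iris, wine quality, sonar, ball bearings).
#'
#' @param path Path to a CSV file.
#' @param label_column Name of the label column.
#' @return A tibble whose columns are the numeric features plus the label
#'   column (kept under its original name).
#' @export
load_csv <- function(path, label_column) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(data) == 0L) abort("empty dataset")
  if (!label_column %in% names(data)) {
    abort(paste0("label column '", label_column, "' not present"))
  }
  feats <- setdiff(names(data), label_column)
  if (length(feats) == 0L) abort("no feature columns")
  bad <- feats[!vapply(data[feats], is.numeric, logical(1))]
  if (length(bad) > 0L) {
    abort(paste0("non-numeric feature column(s): ", paste(bad, collapse = ", ")))
  }
  if (anyNA(data)) abort("missing values are not supported")
  data
}

# internal: split a labelled tibble into feature matrix + labels
dataset_parts <- function(data, label) {
  if (!label %in% names(data)) {
    abort(paste0("label column '", label, "' not present"))
  }
  X <- as.matrix(data[setdiff(names(data), label)])
  storage.mode(X) <- "double"
  list(X = X, y = data[[label]], feature_names = colnames(X))
}

#' Build a semi-supervised train/test split
#'
#' Draws `n_train` samples of the declared normal class(es) uniformly without
#' replacement for training; the remaining normal samples form the normal
#' test set and every other sample the anomalous test set. This is the split
#' scheme used for semi-supervised anomaly detection benchmarks on labelled
#' multi-class tables.
#'
#' @param data A labelled tibble (e.g. from [load_csv()]).
#' @param label Name of the label column.
#' @param normal_labels Character (or coercible) vector of labels treated as
#'   the normal class.
#' @param n_train Number of normal samples used for training.
#' @param seed Optional integer seed; the split is deterministic given it.
#' @return A `cfa_split`: list with tibbles `train_normal`, `test_normal`,
#'   `test_anomalous` plus the `label`, `normal_labels` and `seed` used.
#' @export
make_split <- function(data, label, normal_labels, n_train, seed = NULL) {
  if (length(normal_labels) == 0L) abort("normal_labels must be non-empty")
  y <- data[[label]]
  if (is.null(y)) abort(paste0("label column '", label, "' not present"))
  is_normal <- y %in% normal_labels
  if (!any(is_normal)) abort("no sample carries a normal label")
  if (n_train > sum(is_normal)) {
    abort(sprintf("n_train (%d) exceeds the %d available normal samples",
                  n_train, sum(is_normal)))
  }
  if (!is.null(seed)) set.seed(seed)
  normal_idx <- which(is_normal)
  train_idx <- sort(sample(normal_idx, n_train))
  split <- list(
    train_normal = data[train_idx, , drop = FALSE],
    test_normal = data[setdiff(normal_idx, train_idx), , drop = FALSE],
    test_anomalous = data[which(!is_normal), , drop = FALSE],
    label = label,
    normal_labels = normal_labels,
    seed = seed
  )
  structure(split, class = "cfa_split")
}

#' @export
print.cfa_split <- function(x, ...) {
  cat("<cfa_split>\n")
  cat("  normal labels:", paste(x$normal_labels, collapse = ", "), "\n")
  cat(sprintf("  train_normal: %d  test_normal: %d  test_anomalous: %d\n",
              nrow(x$train_normal), nrow(x$test_normal), nrow(x$test_anomalous)))
  invisible(x)
}

#' Replicate feature columns to reach a minimum presenter count
#'
#' Agent populations with too few presenters can lock into stable matchings,
#' which defeats the frustrated dynamics. When the dataset has
#' `N_f <= min_presenters` features, the feature columns are tiled `k` times,
#' with `k` the smallest even integer such that `k * N_f > min_presenters`;
#' datasets already above the threshold are returned unchanged. Replicated
#' columns are exact copies (suffixed `_r2`, `_r3`, ...).
#'
#' @param data A labelled tibble.
#' @param label Name of the label column (kept as-is). `NULL` if the data is
#'   unlabelled.
#' @param min_presenters Presenter count that must be exceeded (default 32).
#' @return A tibble with the tiled feature columns and the label column.
#' @export
replicate_features <- function(data, label = NULL, min_presenters = 32) {
  stopifnot(min_presenters >= 1)
  feats <- setdiff(names(data), label)
  n_f <- length(feats)
  if (n_f > min_presenters) return(data)
  k <- 2L * as.integer(ceiling((min_presenters + 1) / (2 * n_f)))
  blocks <- lapply(seq_len(k), function(r) {
    b <- data[feats]
    if (r > 1L) names(b) <- paste0(feats, "_r", r)
    b
  })
  out <- dplyr::bind_cols(blocks)
  if (!is.null(label)) out[[label]] <- data[[label]]
  tibble::as_tibble(out)
}

#' Monte-Carlo cross-validation folds
#'
#' Produces `k` independent random splits (each fold resamples the normal
#' training subset; folds are not a partition), the scheme used to report
#' mean and spread of detection rates.
#'
#' @inheritParams make_split
#' @param k Number of folds.
#' @return List of `k` [make_split()] results with fold-derived seeds.
#' @export
monte_carlo_folds <- function(data, label, normal_labels, n_train, k, seed = NULL) {
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, k)
  lapply(fold_seeds, function(s) {
    make_split(data, label, normal_labels, n_train, seed = s)
  })
}
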