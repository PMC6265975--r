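# k-NN classification under stratified k-fold validation.
#
# Per fold: standardize on the training rows, fit the chosen reduction
# (none / PCA / GA) on the training rows, classify the held-out rows, record
# the fraction correct. Nothing from a test fold ever reaches
# standardization, the PCA rotation, or the GA fitness.

#' k-NN configuration
#' @param n_neighbors neighbours voting per test point (default 5: odd, so a
#'   balanced binary vote cannot tie).
#' @param distance metric name; only `"euclidean"` is implemented.
#' @return list of class `knn_config`.
#' @export
knn_config <- function(n_neighbors = 5L, distance = "euclidean") {
  stopifnot(n_neighbors >= 1L, distance == "euclidean")
  structure(list(n_neighbors = as.integer(n_neighbors), distance = distance),
            class = "knn_config")
}

#' Majority-vote k-nearest-neighbour prediction
#'
#' Votes among the `k` nearest training rows by Euclidean distance. A tied
#' vote is broken toward the label with the larger summed inverse distance
#' among its voting neighbours, then by label order — the rule is fully
#' deterministic.
#'
#' @param train_x,train_y training matrix (standardized) and labels.
#' @param test_x matrix with the same columns.
#' @param cfg a [knn_config()]; `n_neighbors` must not exceed `nrow(train_x)`.
#' @return character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, test_x, cfg = knn_config()) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  k <- cfg$n_neighbors
  if (nrow(train_x) == 0L) abort("empty training set", "eegstress_validation_error")
  if (k > nrow(train_x)) {
    abort(sprintf("k = %d exceeds the %d training rows", k, nrow(train_x)),
          "eegstress_validation_error")
  }
  if (ncol(train_x) != ncol(test_x)) {
    abort("train/test column mismatch", "eegstress_shape_error")
  }
  train_y <- as.character(train_y)
  d <- cross_dist(test_x, train_x)
  apply(d, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      w <- vapply(top, function(lab) {
        idx <- nn[train_y[nn] == lab]
        sum(1 / pmax(row[idx], .Machine$double.eps))
      }, numeric(1))
      top <- top[w == max(w)]
      top <- sort(top)[1]
    }
    top
  })
}

#' Stratified fold assignment
#'
#' Shuffles within each class and deals rows round-robin over folds, so fold
#' class counts differ by at most one per class.
#'
#' @param labels class label per row.
#' @param k_folds number of folds.
#' @param seed integer seed for the shuffle.
#' @return integer fold id (1..k_folds) per row.
#' @export
stratified_folds <- function(labels, k_folds = 3L, seed = 1L) {
  labels <- as.character(labels)
  if (any(table(labels) < k_folds)) {
    abort(sprintf(
      "every class needs at least %d segments for %d-fold validation; counts: %s",
      k_folds, k_folds,
      paste(sprintf("%s=%d", names(table(labels)), table(labels)), collapse = ", ")),
      "eegstress_validation_error")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fold <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

#' Evaluate one participant's segments with k-fold validation
#'
#' @param x numeric feature matrix (rows = segments), unstandardized; each
#'   fold standardizes with its own training statistics.
#' @param labels calm/stress label per row; both classes must appear at
#'   least `k_folds` times.
#' @param method `"all"` (no reduction), `"pca"`, or `"ga"`.
#' @param k_folds folds (default 3).
#' @param seed integer seed driving the fold shuffle and, for `"ga"`, the
#'   per-fold GA seeds.
#' @param knn_cfg a [knn_config()].
#' @param ga_cfg a [ga_config()] template; its seed is re-derived per fold.
#' @param pca_variance_threshold retained cumulative explained variance for
#'   `"pca"`.
#' @return list with `method`, `fold_accuracy` (length `k_folds`),
#'   `accuracy` (their mean), and per-fold `detail` (masks / component
#'   counts).
#' @export
kfold_evaluate <- function(x, labels, method = c("all", "pca", "ga"),
                           k_folds = 3L, seed = 1L,
                           knn_cfg = knn_config(), ga_cfg = ga_config(),
                           pca_variance_threshold = 0.95) {
  method <- match.arg(method)
  x <- as.matrix(x)
  labels <- as.character(labels)
  fold <- stratified_folds(labels, k_folds, seed)
  acc <- numeric(k_folds)
  detail <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    fit <- zscore_fit(x[tr, , drop = FALSE])
    xtr <- zscore_apply(fit, x[tr, , drop = FALSE])
    xte <- zscore_apply(fit, x[!tr, , drop = FALSE])
    if (method == "ga") {
      cfg <- ga_cfg
      cfg$random_seed <- as.integer((seed * 1009L + f * 9973L) %% .Machine$integer.max)
      sel <- ga_select(xtr, labels[tr], cfg)
      xtr <- xtr[, sel$mask, drop = FALSE]
      xte <- xte[, sel$mask, drop = FALSE]
      detail[[f]] <- list(mask = sel$mask, fitness = sel$fitness)
    } else if (method == "pca") {
      red <- pca_reduce(xtr, xte, variance_threshold = pca_variance_threshold)
      xtr <- red$train
      xte <- red$projected
      detail[[f]] <- list(n_components = red$n_components)
    }
    pred <- knn_predict(xtr, labels[tr], xte, knn_cfg)
    acc[f] <- mean(pred == labels[!tr])
  }
  list(method = method, fold_accuracy = acc, accuracy = mean(acc),
       detail = detail)
}

#' Run the per-participant evaluation over a cohort
#'
#' Produces one accuracy per participant and method plus the unweighted mean
#' accuracy per method over participants.
#'
#' @param fm a [feature_matrix()] with labels; rows are grouped by
#'   `segment_keys$participant_id`.
#' @param methods subset of `c("all", "pca", "ga")`.
#' @param k_folds,seed,knn_cfg,ga_cfg,pca_variance_threshold passed to
#'   [kfold_evaluate()].
#' @return list of class `eval_report`: `per_participant` data.frame
#'   (participant_id, method, accuracy), `mean_accuracy` named vector.
#' @export
run_experiment <- function(fm, methods = c("all", "pca", "ga"),
                           k_folds = 3L, seed = 1L,
                           knn_cfg = knn_config(), ga_cfg = ga_config(),
                           pca_variance_threshold = 0.95) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  pids <- unique(fm$segment_keys$participant_id)
  stopifnot(length(pids) >= 1L)
  rows <- list()
  for (pid in pids) {
    sel <- fm$segment_keys$participant_id == pid
    for (m in methods) {
      rep_ <- kfold_evaluate(fm$values[sel, , drop = FALSE], fm$labels[sel],
                             method = m, k_folds = k_folds, seed = seed,
                             knn_cfg = knn_cfg, ga_cfg = ga_cfg,
                             pca_variance_threshold = pca_variance_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, method = m, accuracy = rep_$accuracy,
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  mean_acc <- vapply(methods, function(m)
    mean(per$accuracy[per$method == m]), numeric(1))
  structure(list(per_participant = per, mean_accuracy = mean_acc,
                 methods = methods, k_folds = k_folds, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d participants, %d-fold\n",
              length(unique(x$per_participant$participant_id)), x$k_folds))
  for (m in x$methods) {
    cat(sprintf("  mean accuracy (%s): %.4f\n", m, x$mean_accuracy[[m]]))
  }
  invisible(x)
}
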