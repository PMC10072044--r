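#' Build stratified cross-validation folds
#'
#' Fold assignment is drawn once from the current RNG state and then reused
#' for every subset evaluation in a run, so the wrapper's fitness is a pure
#' function of the feature mask (enabling caching and monotone elitist
#' tracking). Within each class, samples are shuffled and dealt round-robin.
#' If the smaller class has fewer samples than `folds`, the fold count is
#' reduced to that size (with a message).
#'
#' @param labels two-level factor of sample classes.
#' @param folds requested fold count (default 5).
#' @return Integer vector of fold ids (1..folds), one per sample.
#' @export
make_cv_folds <- function(labels, folds = 5L) {
  cls_sizes <- tabulate(as.integer(labels))
  k <- min(folds, min(cls_sizes[cls_sizes > 0]))
  if (k < 2L) stop("cannot form >= 2 folds with a single-sample class")
  if (k < folds) message("make_cv_folds: fold count reduced to ", k)
  fold <- integer(length(labels))
  for (ci in seq_along(levels(labels))) {
    idx <- which(as.integer(labels) == ci)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated accuracy of a linear SVM on a feature subset
#'
#' Mean accuracy over stratified k-fold cross-validation of [svm_linear()]
#' trained on the given features. Folds are either supplied (the in-run
#' convention: fixed splits for every mask) or drawn from the current RNG.
#'
#' @param X numeric matrix (samples x features of the evaluated subset).
#' @param labels two-level factor.
#' @param cost SVM cost.
#' @param folds fold count used when `fold_id` is `NULL`.
#' @param fold_id optional precomputed fold assignment from
#'   [make_cv_folds()].
#' @return Accuracy in \[0, 1\].
#' @export
cv_accuracy <- function(X, labels, cost = 1, folds = 5L, fold_id = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("cv_accuracy needs at least one feature")
  if (is.null(fold_id)) fold_id <- make_cv_folds(labels, folds)
  accs <- vapply(sort(unique(fold_id)), function(f) {
    test <- fold_id == f
    fit <- svm_linear(X[!test, , drop = FALSE], labels[!test], cost = cost)
    pred <- predict(fit, X[test, , drop = FALSE])
    mean(pred == labels[test])
  }, numeric(1L))
  mean(accs)
}

# Closure evaluating masks over the pool with a fixed fold split and a cache
# keyed by the mask bits. Returns list(acc=..). Pure given the split.
make_fitness_evaluator <- function(X_pool, labels, cost = 1, folds = 5L) {
  fold_id <- make_cv_folds(labels, folds)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  function(mask) {
    key <- rawToChar(as.raw(mask + 48L))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    acc <- cv_accuracy(X_pool[, mask == 1L, drop = FALSE], labels,
                       cost = cost, fold_id = fold_id)
    cache[[key]] <- acc
    acc
  }
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, recall, precision and F1 with the positive class taken as the
#' disease/tumor label (factor level 2). Ratios with a zero denominator are
#' reported as 0.
#'
#' @param y_true,y_pred two-level factors (or vectors coercible with the same
#'   levels), equal length.
#' @return Named numeric vector `accuracy`, `recall`, `precision`, `f1`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!is.factor(y_true)) y_true <- factor(y_true)
  y_pred <- factor(as.character(y_pred), levels = levels(y_true))
  pos <- levels(y_true)[2L]
  tp <- sum(y_true == pos & y_pred == pos)
  fp <- sum(y_true != pos & y_pred == pos)
  fn <- sum(y_true == pos & y_pred != pos)
  acc <- mean(y_true == y_pred)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = acc, recall = recall, precision = precision, f1 = f1)
}

#' Cross-validated metrics for a feature subset
#'
#' Per-fold accuracy/recall/precision/F1 of the linear SVM on the selected
#' features, averaged over folds.
#'
#' @inheritParams cv_accuracy
#' @return Named numeric vector of the four averaged metrics.
#' @export
cv_metrics <- function(X, labels, cost = 1, folds = 5L, fold_id = NULL) {
  X <- as.matrix(X)
  if (is.null(fold_id)) fold_id <- make_cv_folds(labels, folds)
  per_fold <- vapply(sort(unique(fold_id)), function(f) {
    test <- fold_id == f
    fit <- svm_linear(X[!test, , drop = FALSE], labels[!test], cost = cost)
    pred <- predict(fit, X[test, , drop = FALSE])
    classification_metrics(labels[test], pred)
  }, numeric(4L))
  rowMeans(per_fold)
}

#' Welch t statistic of a feature between classes
#'
#' `t = |mean(pos) - mean(neg)| / sqrt(s2_pos/n_pos + s2_neg/n_neg)` with
#' sample variances (n - 1 denominator); the two-sided p-value uses the
#' Welch–Satterthwaite degrees of freedom. Both groups identical and
#' constant gives `t = 0`, `p = 1`.
#'
#' @param f_pos,f_neg numeric value vectors of the feature in the positive
#'   and negative class (each of length >= 2).
#' @return Named numeric vector `t` (>= 0), `p_value`, `df`.
#' @export
t_statistic <- function(f_pos, f_neg) {
  n1 <- length(f_pos); n2 <- length(f_neg)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 values")
  v1 <- stats::var(f_pos); v2 <- stats::var(f_neg)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    t <- if (mean(f_pos) == mean(f_neg)) 0 else Inf
    return(c(t = t, p_value = if (t == 0) 1 else 0, df = NA_real_))
  }
  t <- abs(mean(f_pos) - mean(f_neg)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-t, df)
  c(t = t, p_value = p, df = df)
}

#' Fold change of a feature between classes
#'
#' Ratio of class means, `FC = mean(pos) / mean(neg)`; values near 1 mean
#' little difference. Undefined (`NA`) when the negative-class mean is 0.
#'
#' @inheritParams t_statistic
#' @return Scalar fold change, or `NA` with a message.
#' @export
fold_change <- function(f_pos, f_neg) {
  m_neg <- mean(f_neg)
  if (m_neg == 0) {
    message("fold_change: negative-class mean is 0; FC undefined")
    return(NA_real_)
  }
  mean(f_pos) / m_neg
}

#' Per-feature biomarker statistics
#'
#' Welch t, two-sided p and fold change for each requested feature,
#' ranked by increasing p-value.
#'
#' @param ds an `ExpressionDataset`.
#' @param features feature indices or ids (default: all).
#' @return A data.frame with `feature_id`, `t`, `p_value`, `FC`, `rank`.
#' @export
biomarker_stats <- function(ds, features = seq_len(n_features(ds))) {
  if (is.character(features)) features <- match(features, ds$feature_ids)
  check_two_classes(ds)
  pos <- positive_idx(ds); neg <- negative_idx(ds)
  rows <- lapply(features, function(j) {
    ts <- t_statistic(ds$values[pos, j], ds$values[neg, j])
    data.frame(feature_id = ds$feature_ids[j],
               t = unname(ts["t"]), p_value = unname(ts["p_value"]),
               FC = fold_change(ds$values[pos, j], ds$values[neg, j]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(out$p_value, ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}
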