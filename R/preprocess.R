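#' Average duplicate features
#'
#' Features sharing an identical identifier are collapsed to a single feature
#' whose per-sample value is the arithmetic mean of the duplicates, skipping
#' missing entries (a cell missing in every duplicate stays missing). The
#' order of first occurrence is preserved.
#'
#' @param ds an `ExpressionDataset`.
#' @return An `ExpressionDataset` with unique feature ids.
#' @export
average_duplicate_features <- function(ds) {
  ids <- ds$feature_ids
  if (!anyDuplicated(ids)) return(ds)
  keep <- !duplicated(ids)
  out_ids <- ids[keep]
  vals <- matrix(NA_real_, n_samples(ds), length(out_ids),
                 dimnames = list(ds$sample_ids, out_ids))
  grp <- match(ids, out_ids)
  for (g in seq_along(out_ids)) {
    cols <- which(grp == g)
    if (length(cols) == 1L) {
      vals[, g] <- ds$values[, cols]
    } else {
      block <- ds$values[, cols, drop = FALSE]
      m <- rowMeans(block, na.rm = TRUE)
      m[is.nan(m)] <- NA_real_  # all-missing row stays missing
      vals[, g] <- m
    }
  }
  expression_dataset(vals, as.character(ds$labels), feature_ids = out_ids,
                     sample_ids = ds$sample_ids,
                     positive_class = levels(ds$labels)[2L])
}

#' Flag outliers with Tukey fences
#'
#' Per feature, values outside `[Q1 - k*IQR, Q3 + k*IQR]` are re-flagged as
#' missing (to be filled by [knn_impute()]). Quartiles use linear
#' interpolation (`stats::quantile` type 7) over the non-missing values.
#' Features with fewer than 4 non-missing values are skipped.
#'
#' @param ds an `ExpressionDataset`.
#' @param k fence multiplier (> 0; 1.5 gives the classic inner fences).
#' @return An `ExpressionDataset` with outlying cells set to missing.
#' @export
tukey_flag_outliers <- function(ds, k = 1.5) {
  stopifnot(k > 0)
  vals <- ds$values
  skipped <- 0L
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    ok <- !is.na(v)
    if (sum(ok) < 4L) { skipped <- skipped + 1L; next }
    q <- stats::quantile(v[ok], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    lo <- q[1L] - k * iqr
    hi <- q[2L] + k * iqr
    out <- ok & (v < lo | v > hi)
    if (any(out)) vals[out, j] <- NA_real_
  }
  if (skipped > 0L) {
    message("tukey_flag_outliers: skipped ", skipped,
            " feature(s) with < 4 non-missing values")
  }
  expression_dataset(vals, as.character(ds$labels),
                     feature_ids = ds$feature_ids, sample_ids = ds$sample_ids,
                     positive_class = levels(ds$labels)[2L])
}

#' Fill missing cells by K nearest neighbors
#'
#' Each missing cell is filled with the mean of that feature's values in the
#' `k` nearest samples, with sample-to-sample Euclidean distance computed
#' over mutually non-missing features (missing dimensions are ignored rather
#' than iteratively imputed, so the fill is single-pass and deterministic).
#' Only neighbors observed on the target feature count; if fewer than `k`
#' such neighbors exist, all available ones are used.
#'
#' @param ds an `ExpressionDataset`.
#' @param k neighbor count (>= 1).
#' @return An `ExpressionDataset` with no missing cells.
#' @export
knn_impute <- function(ds, k = 5L) {
  stopifnot(k >= 1L)
  vals <- ds$values
  if (!anyNA(vals)) return(ds)
  n <- nrow(vals)
  all_missing <- rowSums(!is.na(vals)) == 0L
  if (any(all_missing)) {
    stop("sample(s) with all values missing: ",
         paste(ds$sample_ids[all_missing], collapse = ", "))
  }
  holes <- which(is.na(vals), arr.ind = TRUE)
  need <- unique(holes[, 1L])
  obs <- !is.na(vals)
  filled <- vals
  for (i in need) {
    # mean squared difference over shared dims, scaled back to a Euclidean-
    # style distance; samples sharing no dims are unusable (Inf)
    shared <- obs & matrix(obs[i, ], n, ncol(vals), byrow = TRUE)
    diff2 <- sweep(vals, 2L, vals[i, ])^2
    diff2[!shared] <- 0
    nshared <- rowSums(shared)
    d <- sqrt(rowSums(diff2) / nshared * ncol(vals))
    d[nshared == 0L] <- Inf
    d[i] <- Inf
    ord <- order(d, seq_len(n))  # deterministic tie-break: lower index
    for (j in holes[holes[, 1L] == i, 2L]) {
      donors <- ord[obs[ord, j] & is.finite(d[ord])]
      if (length(donors) == 0L) {
        stop("feature '", ds$feature_ids[j], "' has no complete value")
      }
      use <- donors[seq_len(min(k, length(donors)))]
      filled[i, j] <- mean(vals[use, j])
    }
  }
  expression_dataset(filled, as.character(ds$labels),
                     feature_ids = ds$feature_ids, sample_ids = ds$sample_ids,
                     positive_class = levels(ds$labels)[2L])
}

#' Z-score features
#'
#' Standardizes each feature to mean 0 and population standard deviation 1
#' (divisor n, not n - 1: the transform is a scaling, not an inference).
#' Zero-variance features become all-zeros.
#'
#' @param ds an `ExpressionDataset` with no missing cells.
#' @return A standardized `ExpressionDataset`.
#' @export
zscore_features <- function(ds) {
  vals <- ds$values
  if (anyNA(vals)) stop("zscore_features requires a complete matrix; run knn_impute first")
  n <- nrow(vals)
  mu <- colMeans(vals)
  sdp <- sqrt(colMeans(sweep(vals, 2L, mu)^2))
  const <- sdp == 0
  sdp[const] <- 1
  out <- sweep(sweep(vals, 2L, mu), 2L, sdp, "/")
  if (any(const)) {
    out[, const] <- 0
    message("zscore_features: ", sum(const), " constant feature(s) set to 0")
  }
  expression_dataset(out, as.character(ds$labels),
                     feature_ids = ds$feature_ids, sample_ids = ds$sample_ids,
                     positive_class = levels(ds$labels)[2L])
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: duplicate averaging, Tukey outlier flagging, KNN imputation,
#' z-scoring. A second pass changes nothing (up to the idempotence of the
#' z-score).
#'
#' @param ds an `ExpressionDataset`.
#' @param cfg a [bdba_config()] (supplies `tukey_k` and `knn_k`).
#' @return A clean, standardized `ExpressionDataset`.
#' @export
preprocess <- function(ds, cfg = bdba_config()) {
  ds <- average_duplicate_features(ds)
  ds <- tukey_flag_outliers(ds, k = cfg$tukey_k)
  ds <- knn_impute(ds, k = cfg$knn_k)
  zscore_features(ds)
}
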