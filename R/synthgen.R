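#' Generate a microarray-like synthetic dataset with planted structure
#'
#' Emulates the regime of two-class gene-expression microarrays — far more
#' features than samples — with known ground truth, so every pipeline stage
#' can be tested without external downloads. The feature blocks are, in
#' column order:
#'
#' * informative: class-shifted Gaussians, `N(+effect_size/2, noise_sd)` in
#'   the positive class and `N(-effect_size/2, noise_sd)` in the negative;
#' * redundant: near-copies of randomly chosen informative features plus
#'   `N(0, 0.1 * noise_sd)` jitter;
#' * complementary pairs: marginally uninformative but jointly separating —
#'   each sample draws a sign `c` and the pair is `(c, c) * effect_size/2`
#'   in the positive class and `(c, -c) * effect_size/2` in the negative
#'   (plus noise), so either margin is a symmetric two-component mixture in
#'   both classes while the product of the pair separates them;
#' * noise: class-independent `N(0, noise_sd)`.
#'
#' Missing cells are then blanked at `missing_rate`, and Tukey-detectable
#' outliers injected at `outlier_rate` (cell set to its feature mean plus
#' eight noise SDs, sign random).
#'
#' @param n_samples number of samples (>= 10).
#' @param n_features total features.
#' @param n_informative planted class-informative features.
#' @param n_redundant near-copies of informative features.
#' @param n_complementary_pairs jointly-informative pairs (2 features each).
#' @param class_balance fraction of positive samples.
#' @param effect_size class-mean separation of informative features, in
#'   noise-SD units of scale (2 is a typical well-powered microarray effect).
#' @param noise_sd residual SD.
#' @param missing_rate,outlier_rate cell-level injection rates.
#' @param positive_label,negative_label label strings (lexicographic order
#'   still decides the positive class downstream; defaults "tumor" >
#'   "normal" keep tumor positive).
#' @return A list with `dataset` (an `ExpressionDataset`) and `truth`
#'   (index vectors `informative`, `redundant`, `complementary`, `noise`,
#'   plus `redundant_source`).
#' @export
make_synthetic <- function(n_samples = 100L, n_features = 1000L,
                           n_informative = 20L, n_redundant = 10L,
                           n_complementary_pairs = 5L,
                           class_balance = 0.5, effect_size = 2,
                           noise_sd = 1, missing_rate = 0,
                           outlier_rate = 0,
                           positive_label = "tumor",
                           negative_label = "normal") {
  stopifnot(n_samples >= 10L,
            n_informative + n_redundant + 2L * n_complementary_pairs <= n_features,
            class_balance > 0, class_balance < 1,
            noise_sd > 0, missing_rate >= 0, missing_rate < 1,
            outlier_rate >= 0, outlier_rate < 1)
  if (positive_label <= negative_label) {
    stop("positive_label must sort after negative_label (lexicographic label mapping)")
  }
  n_pos <- max(1L, round(class_balance * n_samples))
  n_neg <- n_samples - n_pos
  labels <- c(rep(positive_label, n_pos), rep(negative_label, n_neg))
  is_pos <- labels == positive_label
  sign_cls <- ifelse(is_pos, 1, -1)

  X <- matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
              n_samples, n_features)
  inf_idx <- seq_len(n_informative)
  for (j in inf_idx) {
    X[, j] <- X[, j] + sign_cls * effect_size / 2
  }
  red_idx <- seq_len(n_redundant) + n_informative
  red_src <- integer(0)
  if (n_redundant > 0L) {
    red_src <- sample(inf_idx, n_redundant, replace = TRUE)
    for (k in seq_len(n_redundant)) {
      X[, red_idx[k]] <- X[, red_src[k]] +
        stats::rnorm(n_samples, sd = 0.1 * noise_sd)
    }
  }
  comp_idx <- seq_len(2L * n_complementary_pairs) + n_informative + n_redundant
  if (n_complementary_pairs > 0L) {
    for (p in seq_len(n_complementary_pairs)) {
      a <- comp_idx[2L * p - 1L]
      b <- comp_idx[2L * p]
      comp_sign <- sample(c(-1, 1), n_samples, replace = TRUE)
      X[, a] <- stats::rnorm(n_samples, sd = noise_sd) +
        comp_sign * effect_size / 2
      X[, b] <- stats::rnorm(n_samples, sd = noise_sd) +
        comp_sign * sign_cls * effect_size / 2
    }
  }
  noise_idx <- setdiff(seq_len(n_features), c(inf_idx, red_idx, comp_idx))

  if (outlier_rate > 0) {
    cells <- which(stats::runif(length(X)) < outlier_rate)
    if (length(cells) > 0L) {
      col_of <- (cells - 1L) %/% n_samples + 1L
      mu <- colMeans(X)[col_of]
      X[cells] <- mu + sample(c(-1, 1), length(cells), replace = TRUE) *
        8 * noise_sd
    }
  }
  if (missing_rate > 0) {
    cells <- which(stats::runif(length(X)) < missing_rate)
    X[cells] <- NA_real_
  }
  ds <- expression_dataset(X, labels,
                           feature_ids = sprintf("g%04d", seq_len(n_features)),
                           sample_ids = sprintf("s%03d", seq_len(n_samples)),
                           positive_class = positive_label)
  list(dataset = ds,
       truth = list(informative = inf_idx, redundant = red_idx,
                    redundant_source = red_src,
                    complementary = comp_idx, noise = noise_idx))
}

#' Write the small deterministic worked-example fixtures
#'
#' Emits the toy datasets used in examples and documentation as CSV files:
#' a 6 + 6 two-feature SMOTE toy, the two-sample complementarity toy, a
#' confusion-matrix toy (10 samples, predictions encoded as a feature), and
#' a three-class-free Fisher toy. Each loads through
#' [read_expression_matrix()].
#'
#' @param out_dir directory to write into (created if absent).
#' @return Named character vector of the file paths, invisibly.
#' @export
make_worked_toys <- function(out_dir = tempfile("toys")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c()
  smote <- expression_dataset(
    matrix(c(0, 0.5, 2, -2, 1, 1, 0.5, 0.5, 1.5, -1, -0.5, 2,
             0, 3.5, -2, 4, 3.2, 2.8, 3.9, 2.6, 3.3, 3.1, 2.9, 3.6),
           nrow = 12, ncol = 2),
    labels = c(rep("tumor", 6), rep("normal", 6)),
    feature_ids = c("fA", "fB"))
  paths["smote"] <- file.path(out_dir, "smote_toy.csv")
  write_expression_matrix(smote, paths["smote"])
  comp <- expression_dataset(
    matrix(c(0, 1, 0, 2), nrow = 2, ncol = 2),
    labels = c("normal", "tumor"), feature_ids = c("fp", "fq"))
  paths["complementarity"] <- file.path(out_dir, "complementarity_toy.csv")
  write_expression_matrix(comp, paths["complementarity"])
  conf <- expression_dataset(
    matrix(c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0), ncol = 1),
    labels = c(rep("tumor", 4), rep("normal", 6)),
    feature_ids = "pred")
  paths["confusion"] <- file.path(out_dir, "confusion_toy.csv")
  write_expression_matrix(conf, paths["confusion"])
  fisher <- expression_dataset(
    matrix(c(0, 0, 1, 1, 5, 5, 5, 5, 0.1, -0.1, 0.2, -0.2), ncol = 3),
    labels = c("normal", "normal", "tumor", "tumor"),
    feature_ids = c("separated", "constant", "noise"))
  paths["fisher"] <- file.path(out_dir, "fisher_toy.csv")
  write_expression_matrix(fisher, paths["fisher"])
  invisible(paths)
}
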