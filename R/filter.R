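#' Pearson correlation coefficient
#'
#' `r = sum((x - mx) (y - my)) / sqrt(sum((x - mx)^2) sum((y - my)^2))`.
#' When either vector is constant the ratio is 0/0; it is defined as 0 here
#' so downstream relevance/redundancy rules stay total.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length(x) != length(y)")
  if (length(x) < 2L) stop("need at least 2 observations")
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(0)
  min(1, max(-1, sum(dx * dy) / den))
}

# correlation of x against every column of M (constant columns give 0)
pearson_vec <- function(x, M) {
  dx <- x - mean(x)
  dM <- sweep(M, 2L, colMeans(M))
  den <- sqrt(sum(dx^2) * colSums(dM^2))
  num <- as.numeric(crossprod(dM, dx))
  r <- ifelse(den == 0, 0, num / den)
  pmin(1, pmax(-1, r))
}

# one synthetic SMOTE point: s_i + r * |s_i - s_j| with elementwise absolute
# difference (kept exactly in this form; it differs from signed-difference
# SMOTE and biases synthetic points upward from s_i)
smote_point <- function(s_i, s_j, r) {
  s_i + r * abs(s_i - s_j)
}

#' Balance two sample sets by SMOTE oversampling
#'
#' Augments the minority set with synthetic samples
#' `s_k = s_i + rand(0,1) * |s_i - s_j|`, where `s_i` is a random minority
#' sample and `s_j` one of its `k` nearest same-class neighbors (Euclidean),
#' until both sets have equal size. Note the elementwise absolute difference.
#'
#' @param pos,neg numeric matrices (rows = samples) or vectors (treated as
#'   one-dimensional samples) of the two classes.
#' @param k neighbor count; clipped to minority size - 1 if larger.
#' @return A list with balanced matrices `pos` and `neg`.
#' @export
smote_balance <- function(pos, neg, k = 5L) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1L)
  if (is.null(dim(neg))) neg <- matrix(neg, ncol = 1L)
  if (nrow(pos) == nrow(neg)) return(list(pos = pos, neg = neg))
  min_is_pos <- nrow(pos) < nrow(neg)
  minority <- if (min_is_pos) pos else neg
  target <- max(nrow(pos), nrow(neg))
  m <- nrow(minority)
  if (m < 2L) stop("minority class needs >= 2 samples for SMOTE")
  if (k > m - 1L) {
    message("smote_balance: k clipped from ", k, " to ", m - 1L)
    k <- m - 1L
  }
  d <- as.matrix(stats::dist(minority))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(row) order(row, seq_len(m))[seq_len(k)],
              simplify = FALSE)
  synth <- matrix(NA_real_, target - m, ncol(minority))
  for (s in seq_len(target - m)) {
    i <- sample.int(m, 1L)
    j <- nn[[i]][sample.int(k, 1L)]
    synth[s, ] <- smote_point(minority[i, ], minority[j, ], stats::runif(1L))
  }
  balanced <- rbind(minority, synth)
  if (min_is_pos) list(pos = balanced, neg = neg) else list(pos = pos, neg = balanced)
}

#' Class relevance of a single feature
#'
#' Measures how well a feature separates the two classes: after SMOTE
#' balancing the per-class value vectors to equal length, both are sorted
#' ascending (the only permutation-invariant pairing) and their similarity
#' `r_pn` computed; `r_cf = 0.8 * (1 - r_pn)`. Similar class profiles give
#' relevance near 0; dissimilar ones approach the 0.8 cap (the cap guards
#' against accidental deletion of meaningful features downstream).
#'
#' `r_pn` is the *uncentered* cosine similarity of the sorted vectors,
#' clamped to \[0, 1\]. A centered correlation is exactly invariant to a
#' shift of either class and therefore cannot see a class-mean difference —
#' the very signal a relevance score must detect; the uncentered form is
#' location-sensitive and lies in \[0, 1\] for the aligned (sorted)
#' profiles of features that do not separate the classes. Two identical
#' class profiles give `r_pn = 1` hence relevance 0.
#'
#' @param x numeric feature values, one per sample.
#' @param labels two-level factor (level 2 = positive class).
#' @param k SMOTE neighbor count.
#' @return Relevance score in \[0, 0.8\].
#' @export
class_relevance <- function(x, labels, k = 5L) {
  pos <- x[as.integer(labels) == 2L]
  neg <- x[as.integer(labels) == 1L]
  if (length(pos) == 0L || length(neg) == 0L) stop("both classes must be present")
  bal <- smote_balance(pos, neg, k = k)
  fp <- sort(as.numeric(bal$pos))
  fn <- sort(as.numeric(bal$neg))
  den <- sqrt(sum(fp^2) * sum(fn^2))
  r_pn <- if (den == 0) {
    1  # both profiles identically zero: indistinguishable classes
  } else {
    min(1, max(0, sum(fp * fn) / den))
  }
  0.8 * (1 - r_pn)
}

#' Complementarity between two features
#'
#' Estimates the joint discriminative value of a feature pair via the
#' Manhattan distance between a sample and its heterogeneous (opposite
#' class) nearest neighbor in the two feature dimensions:
#' `C = mean(|v_ip - v_jp| + |v_iq - v_jq|)` over `n` randomly drawn distinct
#' samples. By default the heterogeneous neighbor is the opposite-class
#' sample closest in sample-order index (ties to the lower index); a
#' Euclidean-distance rule over the two dimensions is available.
#'
#' @param ds an `ExpressionDataset`.
#' @param fp,fq feature indices.
#' @param n number of sample draws (clipped to the number of samples).
#' @param rule neighbor rule, `"index"` or `"euclidean"`.
#' @return Nonnegative complementarity score.
#' @export
feature_complementarity <- function(ds, fp, fq, n = 20L,
                                    rule = c("index", "euclidean")) {
  rule <- match.arg(rule)
  check_two_classes(ds)
  ns <- n_samples(ds)
  if (n > ns) {
    message("feature_complementarity: n clipped from ", n, " to ", ns)
    n <- ns
  }
  draws <- sample.int(ns, n)
  cls <- as.integer(ds$labels)
  vp <- ds$values[, fp]
  vq <- ds$values[, fq]
  dis <- vapply(draws, function(i) {
    het <- which(cls != cls[i])
    if (length(het) == 0L) stop("both classes must be present")
    j <- if (rule == "index") {
      het[order(abs(het - i), het)[1L]]
    } else {
      het[order((vp[het] - vp[i])^2 + (vq[het] - vq[i])^2, het)[1L]]
    }
    abs(vp[i] - vp[j]) + abs(vq[i] - vq[j])
  }, numeric(1L))
  mean(dis)
}

#' Improved fast correlation-based filter
#'
#' Stage-one relevance/redundancy/complementarity filter for continuous
#' expression data. Features are scored by [class_relevance()]; those above
#' the threshold form the candidate list, processed in decreasing relevance:
#' the current best (salient) feature joins the optimal set `O`, and every
#' remaining candidate whose absolute Pearson correlation with it is at
#' least its own relevance is eliminated (approximate Markov blanket rule).
#' Among the features eliminated in a round, the one with the greatest
#' [feature_complementarity()] to the salient feature is rescued into the
#' complementary set. Rescued features stay passive: they never act as
#' salient features themselves.
#'
#' @param ds a preprocessed `ExpressionDataset`.
#' @param cfg a [bdba_config()]; uses `delta`/`relevance_keep`, `smote_k`,
#'   `n_comp` and `comp_neighbor`.
#' @return A list with `optimal` and `complementary` feature index vectors
#'   (in selection order) and the per-feature `relevance` scores.
#' @export
improved_fcbf <- function(ds, cfg = bdba_config()) {
  check_two_classes(ds)
  p <- n_features(ds)
  r_cf <- vapply(seq_len(p),
                 function(j) class_relevance(ds$values[, j], ds$labels,
                                             k = cfg$smote_k),
                 numeric(1L))
  if (!is.null(cfg$delta)) {
    cand <- which(r_cf > cfg$delta)
  } else {
    keep_n <- max(1L, ceiling(cfg$relevance_keep * p))
    cand <- order(-r_cf, seq_len(p))[seq_len(keep_n)]
  }
  if (length(cand) == 0L) {
    warning("improved_fcbf: no feature passed the relevance threshold")
    return(list(optimal = integer(0), complementary = integer(0),
                relevance = r_cf))
  }
  S <- cand[order(-r_cf[cand], cand)]
  O <- integer(0)
  Cset <- integer(0)
  while (length(S) > 0L) {
    f_s <- S[1L]
    O <- c(O, f_s)
    S <- S[-1L]
    if (length(S) == 0L) break
    r_sj <- abs(pearson_vec(ds$values[, f_s], ds$values[, S, drop = FALSE]))
    removed <- S[r_sj >= r_cf[S]]
    S <- S[r_sj < r_cf[S]]
    if (length(removed) > 0L) {
      comp <- vapply(removed, function(j)
        feature_complementarity(ds, f_s, j, n = cfg$n_comp,
                                rule = cfg$comp_neighbor), numeric(1L))
      best <- removed[order(-comp, removed)[1L]]
      Cset <- c(Cset, best)
    }
  }
  list(optimal = O, complementary = unique(Cset), relevance = r_cf)
}

#' Fisher score of every feature
#'
#' Ratio of between-class to within-class variance,
#' `J = S_B / S_w` with `S_B = sum_i (n_i/n) (m_i - m)^2` and
#' `S_w = (1/n) sum_i sum_{y in class i} (y - m_i)^2`. A vanishing
#' within-class variance is regularized with `eps = 1e-12` so perfectly
#' separated features get a large finite score.
#'
#' @param ds an `ExpressionDataset` (two or more classes).
#' @param eps denominator floor.
#' @return Numeric vector of nonnegative scores, one per feature.
#' @export
fisher_score <- function(ds, eps = 1e-12) {
  cls <- as.integer(ds$labels)
  lev <- sort(unique(cls))
  if (length(lev) < 2L) stop("need at least 2 classes")
  n <- n_samples(ds)
  m_all <- colMeans(ds$values)
  S_B <- numeric(n_features(ds))
  S_w <- numeric(n_features(ds))
  for (ci in lev) {
    rows <- cls == ci
    n_i <- sum(rows)
    m_i <- colMeans(ds$values[rows, , drop = FALSE])
    S_B <- S_B + (n_i / n) * (m_i - m_all)^2
    S_w <- S_w + colSums(sweep(ds$values[rows, , drop = FALSE], 2L, m_i)^2) / n
  }
  S_B / (S_w + eps)
}

#' Build the candidate feature pool (ensemble filter)
#'
#' Intersects the improved-FCBF selection (optimal plus complementary sets)
#' with the top-`fisher_top_k` features by Fisher score. An empty
#' intersection falls back to the union (the downstream wrapper needs a
#' non-empty pool) with a warning.
#'
#' @param ds a preprocessed `ExpressionDataset`.
#' @param cfg a [bdba_config()].
#' @return An object of class `FilterResult`: list with `relevance`,
#'   `fcbf_selected`, `fisher_scores`, `fisher_topk` and `pool` (sorted
#'   feature indices), plus `pool_ids`.
#' @export
build_pool <- function(ds, cfg = bdba_config()) {
  fcbf <- improved_fcbf(ds, cfg)
  fcbf_selected <- union(fcbf$optimal, fcbf$complementary)
  J <- fisher_score(ds)
  k <- min(cfg$fisher_top_k, n_features(ds))
  fisher_topk <- order(-J, seq_along(J))[seq_len(k)]
  pool <- sort(intersect(fcbf_selected, fisher_topk))
  if (length(pool) == 0L) {
    warning("build_pool: empty intersection; falling back to the union")
    pool <- sort(union(fcbf_selected, fisher_topk))
  }
  structure(
    list(relevance = fcbf$relevance,
         fcbf_optimal = fcbf$optimal,
         fcbf_complementary = fcbf$complementary,
         fcbf_selected = fcbf_selected,
         fisher_scores = J,
         fisher_topk = fisher_topk,
         pool = pool,
         pool_ids = ds$feature_ids[pool]),
    class = "FilterResult"
  )
}

#' @export
print.FilterResult <- function(x, ...) {
  cat("FilterResult: pool of ", length(x$pool), " features\n", sep = "")
  cat("  FCBF: ", length(x$fcbf_optimal), " optimal + ",
      length(x$fcbf_complementary), " complementary\n", sep = "")
  cat("  Fisher top-k: ", length(x$fisher_topk), "\n", sep = "")
  invisible(x)
}
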