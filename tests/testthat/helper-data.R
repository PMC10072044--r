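# small in-code fixtures shared across test files

# dataset from a plain matrix with default tumor/normal labels
toy_dataset <- function(values, labels = NULL, feature_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(labels)) {
    half <- nrow(values) %/% 2
    labels <- c(rep("tumor", half), rep("normal", nrow(values) - half))
  }
  expression_dataset(values, labels, feature_ids = feature_ids)
}

# two well-separated Gaussian clusters: linearly separable by a wide margin
separable_dataset <- function(n_per_class = 20, d = 4, gap = 10, seed = 5) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), ncol = d) + gap / 2,
             matrix(rnorm(n_per_class * d), ncol = d) - gap / 2)
  toy_dataset(X, labels = rep(c("tumor", "normal"), each = n_per_class))
}

# independent hinge-loss SVM oracle: projected subgradient descent on
#   0.5||w||^2 + C sum max(0, 1 - y (w.x + b))
# slow but implementation-independent
svm_subgradient_oracle <- function(X, ypm, C, iters = 20000) {
  d <- ncol(X)
  w <- rep(0, d); b <- 0
  for (t in seq_len(iters)) {
    eta <- 1 / t
    marg <- ypm * (X %*% w + b)
    viol <- marg < 1
    gw <- w - C * colSums(X[viol, , drop = FALSE] * ypm[viol])
    gb <- -C * sum(ypm[viol])
    w <- w - eta * gw
    b <- b - eta * gb
  }
  list(w = w, b = b)
}

svm_objective <- function(X, ypm, C, w, b) {
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - ypm * (X %*% w + b)))
}
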