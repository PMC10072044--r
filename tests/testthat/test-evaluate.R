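test_that("the linear SVM agrees with an independent hinge-loss oracle", {
  set.seed(40)
  n <- 14
  X <- rbind(matrix(rnorm(n * 2), ncol = 2) + 2,
             matrix(rnorm(n * 2), ncol = 2) - 2)
  ypm <- rep(c(1, -1), each = n)
  fit <- svm_linear(X, factor(rep(c("t", "n"), each = n), levels = c("n", "t")),
                    cost = 1)
  w <- fit$coef[1:2]; b <- fit$coef[3]
  oracle <- svm_subgradient_oracle(X, ypm, C = 1)
  obj_fit <- svm_objective(X, ypm, 1, w, b)
  obj_oracle <- svm_objective(X, ypm, 1, oracle$w, oracle$b)
  # the dual solver must reach (at least) the oracle's objective
  expect_lte(obj_fit, obj_oracle * 1.01 + 1e-8)
  # and classify the training set identically
  expect_equal(sign(X %*% w + b), sign(X %*% oracle$w + oracle$b))
})

test_that("CV accuracy separates wide-margin data and not permuted labels", {
  ds <- separable_dataset()
  set.seed(1)
  expect_equal(cv_accuracy(ds$values, ds$labels), 1.0)

  # permuted labels: near chance
  set.seed(2)
  labs_perm <- sample(ds$labels)
  accs <- replicate(5, cv_accuracy(ds$values, labs_perm))
  expect_lt(abs(mean(accs) - 0.5), 0.15)

  # invariance to feature order inside the mask
  set.seed(3)
  perm <- sample(ncol(ds$values))
  set.seed(4); a1 <- cv_accuracy(ds$values, ds$labels)
  set.seed(4); a2 <- cv_accuracy(ds$values[, perm], ds$labels)
  expect_equal(a1, a2)

  # determinism given the seed
  set.seed(9); b1 <- cv_accuracy(ds$values, ds$labels)
  set.seed(9); b2 <- cv_accuracy(ds$values, ds$labels)
  expect_identical(b1, b2)
})

test_that("stratified folds keep both classes in every training split", {
  labs <- factor(c(rep("t", 12), rep("n", 8)))
  set.seed(5)
  fold <- make_cv_folds(labs, 5)
  expect_length(fold, 20)
  for (f in 1:5) {
    expect_equal(nlevels(droplevels(labs[fold != f])), 2L)
  }
  # fold count reduced when the minority is tiny
  labs2 <- factor(c(rep("t", 3), rep("n", 10)))
  expect_message(f2 <- make_cv_folds(labs2, 5), "reduced")
  expect_equal(max(f2), 3L)
})

test_that("classification metrics follow confusion-matrix arithmetic", {
  y <- factor(c("t", "t", "t", "t", "n", "n"), levels = c("n", "t"))
  expect_equal(unname(classification_metrics(y, y)), rep(1, 4))

  # TP=3, FP=1, FN=1, TN=5
  y_true <- factor(c(rep("t", 4), rep("n", 6)), levels = c("n", "t"))
  y_pred <- factor(c("t", "t", "t", "n", "t", rep("n", 5)),
                   levels = c("n", "t"))
  m <- classification_metrics(y_true, y_pred)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["recall"]), 0.75)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["f1"]), 0.75)

  # no predicted positives: precision 0 by convention
  all_neg <- factor(rep("n", 10), levels = c("n", "t"))
  expect_equal(unname(classification_metrics(y_true, all_neg)["precision"]), 0)
})

test_that("Welch t and fold change match textbook implementations", {
  expect_equal(unname(t_statistic(c(1, 2, 3), c(1, 2, 3))["t"]), 0)
  ts <- t_statistic(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(ts["t"]), 3 / sqrt(2 / 3), tolerance = 1e-12)

  set.seed(60)
  for (i in 1:100) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:12, 1), mean = rnorm(1), sd = runif(1, 0.5, 2))
    mine <- t_statistic(a, b)
    ref <- t.test(a, b)  # Welch by default
    expect_equal(unname(mine["t"]), abs(unname(ref$statistic)),
                 tolerance = 1e-10)
    expect_equal(unname(mine["p_value"]), ref$p.value, tolerance = 1e-10)
    expect_equal(fold_change(a, b), mean(a) / mean(b), tolerance = 1e-12)
  }

  # symmetry/reciprocal identities
  a <- rnorm(6); b <- rnorm(6) + 1
  expect_equal(t_statistic(a, b)["t"], t_statistic(b, a)["t"])
  expect_equal(fold_change(a, b) * fold_change(b, a), 1, tolerance = 1e-12)
  expect_equal(fold_change(c(3, 3), c(2, 2)), 1.5)
  expect_message(fc0 <- fold_change(c(1, 2), c(-1, 1)), "undefined")
  expect_true(is.na(fc0))
})

test_that("biomarker_stats ranks features by p-value", {
  set.seed(13)
  syn <- make_synthetic(n_samples = 30, n_features = 10, n_informative = 2,
                        n_redundant = 0, n_complementary_pairs = 0,
                        effect_size = 4)
  st <- biomarker_stats(syn$dataset)
  expect_equal(nrow(st), 10L)
  expect_equal(st$rank, 1:10)
  # the strongly informative features must head the ranking
  expect_true(all(c("g0001", "g0002") %in% st$feature_id[1:3]))
  expect_true(all(st$p_value >= 0 & st$p_value <= 1))
})
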