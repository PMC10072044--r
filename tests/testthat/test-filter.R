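test_that("pearson_cor matches the closed-form oracle", {
  set.seed(14)
  x <- rnorm(8)
  expect_equal(pearson_cor(x, x), 1)
  expect_equal(pearson_cor(x, -x), -1)
  for (i in 1:100) {
    a <- rnorm(8); b <- rnorm(8)
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_cor(a, b), oracle, tolerance = 1e-12)
  }
  expect_equal(pearson_cor(rep(1, 5), rnorm(5)), 0)  # constant -> defined 0
  expect_error(pearson_cor(1:3, 1:4), "length")
})

test_that("SMOTE synthesis follows s_k = s_i + rand * |s_i - s_j|", {
  # direct evaluation with the elementwise absolute difference
  expect_equal(efbdba:::smote_point(c(0, 0), c(2, -2), 0.5), c(1, 1))
  expect_equal(efbdba:::smote_point(c(1, 3), c(1, 3), 0.7), c(1, 3))  # rand*0
  expect_equal(efbdba:::smote_point(c(0, 0), c(2, -2), 0), c(0, 0))

  # already balanced: no-op
  pos <- matrix(rnorm(10), 5)
  neg <- matrix(rnorm(10), 5)
  bal <- smote_balance(pos, neg)
  expect_identical(bal$pos, pos)
  expect_identical(bal$neg, neg)

  # sizes equalize; synthetics never fall below the minority elementwise min
  set.seed(9)
  pos2 <- matrix(rnorm(6), 3, 2)
  expect_message(bal2 <- smote_balance(pos2, neg, k = 5), "clipped")
  expect_equal(nrow(bal2$pos), 5L)
  synth <- bal2$pos[4:5, , drop = FALSE]
  expect_true(all(sweep(synth, 2, apply(pos2, 2, min)) >= -1e-12))
})

test_that("class relevance spans [0, 0.8] with the documented boundary cases", {
  # identical class profiles: r_pn = 1 -> relevance 0
  x <- c(1, 2, 3, 1, 2, 3)
  labs <- factor(c("n", "n", "n", "t", "t", "t"))
  expect_equal(class_relevance(x, labs), 0)

  # orthogonal sorted profiles: r_pn = 0 -> relevance 0.8
  x2 <- c(-1, 0, 0, 0, 0, 1)
  expect_equal(class_relevance(x2, labs), 0.8)

  # balanced case is deterministic: independent inline oracle
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(10)
    labs10 <- factor(rep(c("n", "t"), 5))
    fp <- sort(v[labs10 == "t"]); fn <- sort(v[labs10 == "n"])
    oracle <- 0.8 * (1 - min(1, max(0, sum(fp * fn) /
                                      sqrt(sum(fp^2) * sum(fn^2)))))
    expect_equal(class_relevance(v, labs10), oracle, tolerance = 1e-12)
    expect_gte(class_relevance(v, labs10), 0)
    expect_lte(class_relevance(v, labs10), 0.8)
  }

  # imbalanced case exercises SMOTE; still in range and seed-reproducible
  v <- rnorm(9)
  labs9 <- factor(c(rep("n", 6), rep("t", 3)))
  set.seed(5); r1 <- class_relevance(v, labs9)
  set.seed(5); r2 <- class_relevance(v, labs9)
  expect_identical(r1, r2)
  expect_gte(r1, 0); expect_lte(r1, 0.8)
})

test_that("complementarity matches exhaustive evaluation and is symmetric", {
  # 2 samples, one per class: the heterogeneous neighbor is the other sample
  ds <- toy_dataset(cbind(c(0, 1), c(0, 2)), labels = c("normal", "tumor"),
                    feature_ids = c("fp", "fq"))
  set.seed(1)
  expect_equal(feature_complementarity(ds, 1, 2, n = 2), 3)

  # symmetry under feature swap (same draws)
  set.seed(6)
  big <- toy_dataset(matrix(rnorm(40), 10, 4),
                     labels = rep(c("t", "n"), 5))
  set.seed(2); c_ab <- feature_complementarity(big, 1, 3, n = 10)
  set.seed(2); c_ba <- feature_complementarity(big, 3, 1, n = 10)
  expect_equal(c_ab, c_ba)

  # identical samples in both dimensions: zero
  flat <- toy_dataset(cbind(rep(1, 6), rep(2, 6)),
                      labels = rep(c("t", "n"), 3))
  expect_equal(feature_complementarity(flat, 1, 2, n = 6), 0)

  # n clipped with a message
  expect_message(feature_complementarity(flat, 1, 2, n = 99), "clipped")

  # index-adjacency oracle on a hand-checkable layout
  ds2 <- toy_dataset(cbind(c(10, 0, 0, 0), c(0, 0, 0, 5)),
                     labels = c("t", "n", "n", "n"),
                     feature_ids = c("fp", "fq"))
  # sample 1 (t): neighbor = sample 2 -> dis = 10 + 0
  # samples 2..4 (n): neighbor = sample 1 -> dis = 10, 10, 10 + 5
  set.seed(7)
  expect_equal(feature_complementarity(ds2, 1, 2, n = 4),
               mean(c(10, 10, 10, 15)))
})

test_that("improved FCBF follows the relevance/redundancy/rescue loop", {
  set.seed(30)
  # f1 strongly informative, f2 its exact copy, f3 noise
  cls <- rep(c(1, -1), each = 10)
  f1 <- cls * 2 + rnorm(20, sd = 0.3)
  ds <- toy_dataset(cbind(f1, f1, rnorm(20)),
                    labels = ifelse(cls > 0, "tumor", "normal"),
                    feature_ids = c("a", "b", "noise"))
  dsz <- zscore_features(ds)
  cfg <- bdba_config(delta = 0.3, n_comp = 10L)
  set.seed(11)
  res <- improved_fcbf(dsz, cfg)
  # ties in relevance break to the lower index: a is salient, b eliminated
  # as redundant (|r| = 1 >= r_cf(b)) and, being the only casualty, rescued
  expect_equal(res$optimal, 1L)
  expect_equal(res$complementary, 2L)
  expect_true(all(res$relevance >= 0 & res$relevance <= 0.8))

  # threshold just below the top feature's relevance: it leads the loop
  res2 <- improved_fcbf(dsz, bdba_config(delta = res$relevance[1] - 1e-6,
                                         n_comp = 10L))
  expect_true(1L %in% res2$optimal)

  # subset property and no intra-O Markov-blanket violation
  set.seed(44)
  syn <- make_synthetic(n_samples = 30, n_features = 40, n_informative = 5,
                        n_redundant = 5, n_complementary_pairs = 2,
                        effect_size = 3)
  dsz2 <- preprocess(syn$dataset)
  res3 <- improved_fcbf(dsz2, bdba_config(relevance_keep = 0.5))
  n_cand <- ceiling(0.5 * 40)
  expect_lte(length(union(res3$optimal, res3$complementary)), n_cand)
  O <- res3$optimal
  if (length(O) >= 2) {
    for (a in seq_along(O)[-1]) {
      for (b in seq_len(a - 1)) {
        r <- abs(pearson_cor(dsz2$values[, O[a]], dsz2$values[, O[b]]))
        expect_lt(r, min(res3$relevance[O[a]], res3$relevance[O[b]]))
      }
    }
  }
})

test_that("fisher score matches the brute-force oracle and its invariances", {
  # constant feature: between-class variance 0
  ds <- toy_dataset(cbind(rep(2, 4), c(0, 0, 1, 1)),
                    labels = c("n", "n", "t", "t"))
  J <- fisher_score(ds)
  expect_equal(J[[1]], 0)
  # perfectly separated: S_B = 0.25, S_w = 0 -> 0.25/eps
  expect_equal(J[[2]], 0.25 / 1e-12)

  set.seed(18)
  vals <- matrix(rnorm(100), 20, 5)
  labs <- rep(c("t", "n"), 10)
  ds2 <- toy_dataset(vals, labels = labs)
  J2 <- fisher_score(ds2)
  oracle <- sapply(1:5, function(j) {
    x <- vals[, j]
    m <- mean(x); n <- length(x)
    sb <- 0; sw <- 0
    for (cl in unique(labs)) {
      xi <- x[labs == cl]
      sb <- sb + (length(xi) / n) * (mean(xi) - m)^2
      sw <- sw + sum((xi - mean(xi))^2) / n
    }
    sb / (sw + 1e-12)
  })
  expect_equal(unname(J2), oracle, tolerance = 1e-10)

  # invariance: shifting a feature leaves J unchanged; scaling cancels
  ds_shift <- ds2; ds_shift$values[, 1] <- ds_shift$values[, 1] + 100
  ds_scale <- ds2; ds_scale$values[, 2] <- ds_scale$values[, 2] * 7
  expect_equal(fisher_score(ds_shift)[1], J2[1], tolerance = 1e-6)
  expect_equal(fisher_score(ds_scale)[2], J2[2], tolerance = 1e-6)
})

test_that("build_pool intersects the two filters with a union fallback", {
  set.seed(50)
  syn <- make_synthetic(n_samples = 30, n_features = 50, n_informative = 5,
                        n_redundant = 3, n_complementary_pairs = 0,
                        effect_size = 3)
  dsz <- preprocess(syn$dataset)
  res <- build_pool(dsz, bdba_config(fisher_top_k = 20L))
  expect_true(all(res$pool %in% res$fcbf_selected))
  expect_true(all(res$pool %in% res$fisher_topk))
  expect_lte(length(res$pool), 20L)

  # pure noise with a high absolute threshold empties the FCBF set; the
  # pool falls back to the union (here: the Fisher top-k) with a warning
  set.seed(51)
  null_syn <- make_synthetic(n_samples = 20, n_features = 30,
                             n_informative = 0, n_redundant = 0,
                             n_complementary_pairs = 0)
  dsz0 <- preprocess(null_syn$dataset)
  expect_warning(
    expect_warning(res2 <- build_pool(dsz0, bdba_config(delta = 0.7,
                                                        fisher_top_k = 10L)),
                   "threshold"),
    "union")
  expect_setequal(res2$pool, res2$fisher_topk)
})
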