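test_that("duplicate features are averaged with missing cells excluded", {
  ds <- toy_dataset(cbind(c(1, 5), c(3, 7)), feature_ids = c("g1", "g1"),
                    labels = c("tumor", "normal"))
  out <- average_duplicate_features(ds)
  expect_equal(out$feature_ids, "g1")
  expect_equal(unname(out$values[, 1]), c(2, 6))

  # no duplicates: identity
  ds2 <- toy_dataset(matrix(1:6, 3, 2), labels = c("a", "a", "b"))
  expect_identical(average_duplicate_features(ds2)$values, ds2$values)

  # brute-force masked mean oracle on 3 duplicates with holes
  set.seed(12)
  vals <- matrix(rnorm(12), 4, 3)
  vals[2, 1] <- NA
  vals[3, ] <- c(NA, NA, NA)
  ds3 <- toy_dataset(vals, feature_ids = rep("gX", 3))
  out3 <- average_duplicate_features(ds3)
  oracle <- apply(vals, 1, function(row) {
    if (all(is.na(row))) NA_real_ else mean(row[!is.na(row)])
  })
  expect_equal(unname(out3$values[, 1]), oracle)
})

test_that("Tukey fences flag exactly the outlying values", {
  vals <- cbind(c(1:9, 100), rep(5, 10))
  ds <- toy_dataset(vals, labels = rep(c("t", "n"), 5))
  out <- tukey_flag_outliers(ds, k = 1.5)
  # hand-computed: Q1=3.25, Q3=7.75, IQR=4.5 -> fences [-3.5, 14.5]
  expect_equal(unname(which(is.na(out$values[, 1]))), 10L)
  expect_equal(sum(is.na(out$values[, 2])), 0L)  # constant: IQR 0, all inside

  # already-missing cells stay missing; flags only add
  vals2 <- cbind(c(NA, 1:8, 100))
  ds2 <- toy_dataset(vals2, labels = rep(c("t", "n"), 5))
  out2 <- tukey_flag_outliers(ds2)
  expect_true(is.na(out2$values[1, 1]))
  expect_gte(sum(is.na(out2$values)), sum(is.na(vals2)))

  # short features are skipped with a message
  short <- toy_dataset(cbind(c(1, 2, 1000, NA, NA, NA, NA, NA, NA, NA)),
                       labels = rep(c("t", "n"), 5))
  expect_message(out3 <- tukey_flag_outliers(short), "skipped")
  expect_equal(sum(is.na(out3$values)), 7L)
})

test_that("KNN imputation matches a brute-force oracle", {
  # k=1 with an unambiguous nearest neighbor copies its value
  vals <- rbind(c(0, 0, NA), c(0, 0, 7), c(50, 50, -3))
  ds <- toy_dataset(vals, labels = c("t", "n", "t"))
  out <- knn_impute(ds, k = 1)
  expect_equal(out$values[1, 3], 7)
  expect_false(anyNA(out$values))

  # random 10x6 with 3 holes vs exhaustive-distance oracle
  set.seed(77)
  m <- matrix(rnorm(60), 10, 6)
  holes <- cbind(c(2, 5, 9), c(1, 4, 6))
  m[holes] <- NA
  ds2 <- toy_dataset(m, labels = rep(c("t", "n"), 5))
  out2 <- knn_impute(ds2, k = 3)
  for (h in seq_len(nrow(holes))) {
    i <- holes[h, 1]; j <- holes[h, 2]
    d <- sapply(seq_len(10), function(r) {
      if (r == i) return(Inf)
      shared <- !is.na(m[i, ]) & !is.na(m[r, ])
      if (!any(shared)) return(Inf)
      sqrt(mean((m[i, shared] - m[r, shared])^2) * 6)
    })
    donors <- order(d, seq_len(10))
    donors <- donors[!is.na(m[donors, j]) & is.finite(d[donors])][1:3]
    expect_equal(out2$values[i, j], mean(m[donors, j]))
  }

  # a fully-missing sample is an error
  m3 <- matrix(1, 3, 2); m3[2, ] <- NA
  expect_error(knn_impute(toy_dataset(m3, labels = c("t", "n", "t"))),
               "all values missing")
})

test_that("z-score uses the population SD and zeroes constant features", {
  ds <- toy_dataset(cbind(c(1, 2, 3), c(4, 4, 4)), labels = c("t", "n", "t"))
  expect_message(out <- zscore_features(ds), "constant")
  expect_equal(unname(out$values[, 1]),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(out$values[, 2]), c(0, 0, 0))

  set.seed(4)
  ds2 <- toy_dataset(matrix(rnorm(40, 10, 3), 8, 5))
  out2 <- zscore_features(ds2)
  expect_lt(max(abs(colMeans(out2$values))), 1e-12)
  sd_pop <- sqrt(colMeans(sweep(out2$values, 2, colMeans(out2$values))^2))
  expect_lt(max(abs(sd_pop - 1)), 1e-12)
})

test_that("the preprocessing pipeline is idempotent", {
  # bounded (uniform) values keep every point inside the Tukey fences, so a
  # second pass can only re-run the z-score, which must be a no-op
  set.seed(21)
  vals <- matrix(runif(20 * 10), 20, 10)
  vals[3, 2] <- 50     # one gross outlier
  vals[c(5, 17), 4] <- NA
  ds <- toy_dataset(vals, feature_ids = c("dup", "dup", paste0("g", 1:8)))
  once <- preprocess(ds)
  expect_false(anyNA(once$values))
  expect_equal(ncol(once$values), 9L)  # duplicates collapsed
  twice <- preprocess(once)
  expect_equal(twice$values, once$values, tolerance = 1e-10)
})
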