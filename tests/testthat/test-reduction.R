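test_that("pearson matrix matches the raw-moment formula and flags
           undefined entries", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  tab <- feature_table(cbind(X = x, Y = y), rep(c("a", "b"), 2))
  cm <- pearson_correlation_matrix(tab)
  expect_equal(cm["X", "Y"], 0.6, tolerance = 1e-12)
  expect_equal(diag(cm), c(X = 1, Y = 1))
  tab2 <- feature_table(cbind(X = c(1, 2, 3), Y = c(6, 4, 2)),
                        c("a", "b", "a"))
  expect_equal(pearson_correlation_matrix(tab2)["X", "Y"], -1,
               tolerance = 1e-12)
  # random vectors vs the raw-moment oracle
  set.seed(31)
  for (i in 1:30) {
    v <- matrix(rexp(40), 20, 2, dimnames = list(NULL, c("A", "B")))
    t3 <- feature_table(v, rep(c("a", "b"), 10))
    expect_equal(pearson_correlation_matrix(t3)["A", "B"],
                 oracle_pearson(v[, 1], v[, 2]), tolerance = 1e-12)
  }
  # constant feature -> undefined entry, not an exception
  t4 <- feature_table(cbind(A = c(1, 1, 1), B = c(1, 2, 3)),
                      c("a", "b", "a"))
  expect_true(is.na(pearson_correlation_matrix(t4)["A", "B"]))
})

test_that("correlated pairs are thresholded strictly and sorted", {
  m <- diag(3)
  dimnames(m) <- list(c("f1", "f2", "f3"), c("f1", "f2", "f3"))
  m["f1", "f2"] <- m["f2", "f1"] <- 0.9
  m["f1", "f3"] <- m["f3", "f1"] <- -0.6
  m["f2", "f3"] <- m["f3", "f2"] <- 0.2
  p <- find_correlated_pairs(m, 0.5)
  expect_identical(nrow(p), 2L)
  expect_identical(p$feature_a, c("f1", "f1"))
  expect_identical(p$feature_b, c("f2", "f3"))
  expect_identical(find_correlated_pairs(diag(3) |>
    (\(d) {dimnames(d) <- list(letters[1:3], letters[1:3]); d})(), 0.5) |>
      nrow(), 0L)
  # strict threshold: |r| exactly at the threshold is not a pair
  m["f2", "f3"] <- m["f3", "f2"] <- 0.5
  expect_identical(nrow(find_correlated_pairs(m, 0.5)), 2L)
  # threshold 0 on k fully defined features -> k(k-1)/2 pairs
  set.seed(8)
  k <- 6
  v <- matrix(rexp(20 * k), 20, k, dimnames = list(NULL, paste0("g", 1:k)))
  cm <- pearson_correlation_matrix(feature_table(v, rep(c("a", "b"), 10)))
  expect_equal(nrow(find_correlated_pairs(cm, 0)), k * (k - 1) / 2)
})

test_that("MI estimator equals the brute-force plug-in on discrete data", {
  # worked joint count table
  x <- rep(c(0, 0, 1, 1, 2), times = c(4, 0, 1, 3, 2))
  y <- c(rep("A", 4), "A", rep("B", 3), rep("B", 2))
  expect_equal(mutual_information(x, y), oracle_mi(x, y), tolerance = 1e-12)
  # deterministic dependence on a balanced binary target -> ln 2
  xb <- rep(c(0, 1), each = 50)
  yb <- rep(c("A", "B"), each = 50)
  expect_equal(mutual_information(xb, yb), log(2), tolerance = 1e-12)
  # independence at large n -> approximately 0 (discrete, exact plug-in)
  set.seed(4)
  xi <- sample(0:3, 5000, TRUE); yi <- sample(c("A", "B"), 5000, TRUE)
  expect_lt(mutual_information(xi, yi), 0.005)
  # random small discrete tables against the oracle
  for (i in 1:100) {
    n <- sample(10:60, 1)
    xr <- sample(0:4, n, TRUE); yr <- sample(c("u", "v", "w"), n, TRUE)
    expect_equal(mutual_information(xr, yr), oracle_mi(xr, yr),
                 tolerance = 1e-12)
  }
  expect_error(mutual_information(c(NA_real_, NA_real_), c("a", "b")),
               "missing")
})

test_that("continuous MI uses equal-frequency binning and is non-negative", {
  set.seed(12)
  x <- rnorm(500); y <- rep(c("a", "b"), 250)
  expect_gte(mutual_information(x, y), 0)
  x2 <- c(rnorm(250), rnorm(250, 3))
  expect_gt(mutual_information(x2, rep(c("a", "b"), each = 250)),
            mutual_information(x, y))
  expect_error(mutual_information(x, y, n_bins = 1), "n_bins")
})

test_that("reduce_features drops exactly the redundant pair members", {
  # no pair above threshold -> identity
  set.seed(3)
  v <- matrix(rexp(200 * 4), 200, 4, dimnames = list(NULL, paste0("h", 1:4)))
  tab <- feature_table(v, rep(c("a", "b"), 100))
  red0 <- reduce_features(tab, threshold = 0.99)
  expect_identical(red0$kept_features, paste0("h", 1:4))
  expect_length(red0$dropped_features, 0)
  # generator ground truth: informative members kept, redundant dropped
  tabg <- generate_cohort(recovery_config(seed = 13))
  redg <- reduce_features(stratified_split(tabg, 0.1, 13)$train)
  expect_setequal(redg$dropped_features, c("B06", "B07", "B08"))
  expect_true(all(c("B01", "B02", "B03", "B04", "B05") %in%
                    redg$kept_features))
  # partition invariant and never both members of a pair
  expect_setequal(c(redg$kept_features, redg$dropped_features),
                  colnames(tabg$values))
  for (i in seq_len(nrow(redg$pairs))) {
    both <- c(redg$pairs$feature_a[i], redg$pairs$feature_b[i])
    expect_identical(sum(both %in% redg$dropped_features), 1L)
    expect_true(redg$pairs$dropped[i] %in% both)
  }
})

test_that("reduction is invariant to input feature order", {
  tabg <- generate_cohort(recovery_config(seed = 29))
  tr <- stratified_split(tabg, 0.1, 29)$train
  perm <- sample(ncol(tr$values))
  tr_perm <- subset_table(tr, cols = colnames(tr$values)[perm])
  r1 <- reduce_features(tr)
  r2 <- reduce_features(tr_perm)
  expect_setequal(r1$dropped_features, r2$dropped_features)
})
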