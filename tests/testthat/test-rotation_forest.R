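test_that("feature partitions have the prescribed sizes and cover 1..D", {
  set.seed(1)
  p <- partition_features(200L, 8L)
  expect_length(p, 8L)
  expect_true(all(lengths(p) == 25L))
  expect_setequal(unlist(p), 1:200)

  set.seed(2)
  q <- partition_features(10L, 3L)
  expect_equal(unname(lengths(q)), c(4L, 3L, 3L))
  expect_setequal(unlist(q), 1:10)

  # property: disjoint cover for random (D, K)
  set.seed(3)
  for (i in 1:25) {
    D <- sample(2:80, 1L)
    K <- sample(seq_len(D), 1L)
    part <- partition_features(D, K)
    idx <- unlist(part)
    expect_length(idx, D)
    expect_setequal(idx, seq_len(D))
    expect_lte(diff(range(lengths(part))), 1L)
  }
  expect_error(partition_features(5L, 6L), "invalid partition")
})

test_that("rotation matrices are orthonormal and preserve pairwise distances", {
  d <- separable_data(30L, d = 12L, seed = 4)
  m <- rotation_forest(d$x, d$y, K = 1L, L = 1L, seed = 4)
  mat <- m$rotations[[1L]]
  expect_lt(max(abs(crossprod(mat) - diag(12L))), 1e-8)
  # a rotation preserves pairwise distances
  xr <- sweep(d$x, 2L, m$centers[[1L]]) %*% mat
  expect_equal(as.matrix(dist(xr)), as.matrix(dist(d$x)), tolerance = 1e-8)
})

test_that("rotated feature space keeps exactly D dimensions even when blocks are rank-deficient", {
  set.seed(5)
  x <- cbind(matrix(rnorm(40 * 4), 40, 4), 0, 1)  # two zero-variance columns
  y <- rep(c(0L, 1L), 20)
  m <- rotation_forest(x, y, K = 2L, L = 3L, seed = 5)
  for (mat in m$rotations) {
    expect_equal(dim(mat), c(6L, 6L))
    expect_lt(max(abs(crossprod(mat) - diag(6L))), 1e-8)
  }
})

test_that("well-separated Gaussian classes are fit to training accuracy 1", {
  d <- separable_data(100L, d = 10L, shift = 4, seed = 6)
  m <- rotation_forest(d$x, d$y, K = 2L, L = 5L, seed = 6)
  pred <- predict(m, d$x, type = "class")
  expect_equal(mean(pred == as.character(d$y)), 1)
  # and generating fresh labels from the same classes, test labels match
  d2 <- separable_data(50L, d = 10L, shift = 4, seed = 7)
  expect_gte(mean(predict(m, d2$x, type = "class") == as.character(d2$y)), 0.99)
})

test_that("fits are bit-identical under a fixed seed", {
  d <- separable_data(40L, d = 8L, seed = 8)
  m1 <- rotation_forest(d$x, d$y, K = 4L, L = 3L, seed = 99)
  m2 <- rotation_forest(d$x, d$y, K = 4L, L = 3L, seed = 99)
  expect_identical(m1$rotations, m2$rotations)
  expect_identical(m1$partitions, m2$partitions)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
})

test_that("bootstrap draws three-quarters of the rows by default", {
  d <- separable_data(60L, d = 6L, seed = 9)
  m <- rotation_forest(d$x, d$y, K = 2L, L = 2L, seed = 9)
  expect_identical(m$n_boot, as.integer(floor(0.75 * nrow(d$x))))
  set.seed(1)
  expect_length(ppiforest:::bootstrap_rows(100L, 0.75), 75L)
  expect_length(ppiforest:::bootstrap_rows(101L, 0.75), 75L)
  expect_identical(ppiforest:::bootstrap_rows(50L, 1, replace = FALSE), 1:50)
})

test_that("a single unpartitioned tree equals a plain tree on explicitly pre-rotated data", {
  d <- separable_data(60L, d = 7L, shift = 2.5, seed = 10)
  ctrl <- rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0.01,
                               xval = 0L, maxdepth = 30L)
  m <- rotation_forest(d$x, d$y, K = 1L, L = 1L, bootstrap_fraction = 1,
                       replace = FALSE, seed = 11, tree_control = ctrl)

  # brute-force construction outside the ensemble code
  mu <- colMeans(d$x)
  centered <- sweep(d$x, 2L, mu)
  V <- eigen(crossprod(centered) / (nrow(d$x) - 1L), symmetric = TRUE)$vectors
  for (j in seq_len(ncol(V))) {              # same sign convention
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  xr <- centered %*% V
  colnames(xr) <- sprintf("r%04d", seq_len(ncol(xr)))
  df <- as.data.frame(xr); df$.class <- factor(d$y)
  oracle <- rpart::rpart(.class ~ ., df, method = "class", control = ctrl)

  d2 <- separable_data(40L, d = 7L, shift = 2.5, seed = 12)
  xq <- sweep(d2$x, 2L, mu) %*% V
  colnames(xq) <- colnames(xr)
  expect_equal(unname(predict(m, d2$x, type = "prob")),
               unname(predict(oracle, as.data.frame(xq), type = "prob")),
               tolerance = 1e-12)
})

test_that("ensemble probabilities are averages: rows sum to 1, L=1 equals its tree", {
  d <- separable_data(30L, d = 6L, shift = 1, seed = 13)
  m <- rotation_forest(d$x, d$y, K = 3L, L = 4L, seed = 13)
  p <- predict(m, d$x, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, nrow(d$x)), tolerance = 1e-9)

  m1 <- rotation_forest(d$x, d$y, K = 3L, L = 1L, seed = 14)
  xr <- sweep(d$x, 2L, m1$centers[[1L]]) %*% m1$rotations[[1L]]
  colnames(xr) <- m1$feature_names
  expect_equal(unname(predict(m1, d$x, type = "prob")),
               unname(predict(m1$trees[[1L]], as.data.frame(xr), type = "prob")))

  # memorizing configuration: a duplicated sample pair per class is recalled
  xx <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  yy <- c(0L, 0L, 1L, 1L)
  mm <- rotation_forest(xx, yy, K = 1L, L = 3L, bootstrap_fraction = 1,
                        seed = 15)
  expect_gte(predict(mm, xx, type = "prob")[1L, "0"], 0.5)
  expect_gte(predict(mm, xx, type = "prob")[3L, "1"], 0.5)
})

test_that("exact probability ties resolve to the first listed class", {
  # two hand-built stumps that disagree with certainty at x = -1
  mk_tree <- function(flip) {
    xx <- data.frame(r0001 = c(-2, -1.5, 1.5, 2))
    xx$.class <- factor(if (flip) c(1L, 1L, 0L, 0L) else c(0L, 0L, 1L, 1L))
    rpart::rpart(.class ~ ., xx, method = "class",
                 control = rpart::rpart.control(minsplit = 2L, minbucket = 1L,
                                                cp = 0, xval = 0L))
  }
  model <- structure(
    list(trees = list(mk_tree(FALSE), mk_tree(TRUE)),
         rotations = list(matrix(1, 1, 1), matrix(1, 1, 1)),
         partitions = list(list(1L), list(1L)),
         centers = list(0, 0), classes = c("0", "1"), seed = 1L,
         K = 1L, L = 2L, D = 1L, N = 4L, bootstrap_fraction = 1,
         n_boot = 4L, replace = TRUE, base_learner = "rpart (CART)",
         feature_names = "r0001"),
    class = "rotation_forest")
  p <- predict(model, matrix(-1), type = "prob")
  expect_equal(unname(p), matrix(c(0.5, 0.5), 1L), tolerance = 1e-12)
  expect_identical(predict(model, matrix(-1), type = "class"), "0")
})

test_that("degenerate configurations raise informative errors", {
  d <- separable_data(20L, d = 5L, seed = 16)
  expect_error(rotation_forest(d$x, rep(1L, 40L)), "one class")
  expect_error(rotation_forest(d$x, d$y, K = 6L), "invalid partition")
  m <- rotation_forest(d$x, d$y, K = 2L, L = 1L, seed = 16)
  expect_error(predict(m, matrix(0, 2L, 4L)), "D = 5.*D = 4")
})

test_that("saved and reloaded models reproduce predictions bit-for-bit", {
  d <- separable_data(40L, d = 6L, seed = 17)
  m <- rotation_forest(d$x, d$y, seed = 17, K = 3L, L = 2L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, d$x), predict(m, d$x))
  saveRDS(list(), path)
  expect_error(load_model(path), "rotation_forest")
})

test_that("label-shuffled data yields chance-level cross-validated accuracy", {
  set.seed(18)
  x <- matrix(rnorm(120 * 12), 120, 12)
  y <- rep(c(0L, 1L), 60)
  accs <- vapply(c(21L, 22L, 23L), function(s) {
    set.seed(s)
    ys <- sample(y)
    cross_validate(x, ys, k = 5L, K = 3L, L = 3L, seed = s)$mean[["accuracy"]]
  }, numeric(1))
  expect_true(all(accs >= 0.35 & accs <= 0.65))
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})
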