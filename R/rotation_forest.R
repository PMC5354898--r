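#' Random disjoint feature partition
#'
#' Splits the feature indices 1..D into K disjoint subsets of near-equal
#' size: a random permutation of the indices is cut into K contiguous
#' chunks; when K does not divide D the first `D %% K` chunks carry one
#' extra index. Uses the current RNG state (callers seed it).
#'
#' @param D Number of features (positive integer).
#' @param K Number of subsets, `1 <= K <= D`.
#' @return List of K integer vectors covering 1..D.
#' @export
partition_features <- function(D, K) {
  D <- as.integer(D); K <- as.integer(K)
  if (K < 1L || K > D) {
    stop("invalid partition: K = ", K, " must satisfy 1 <= K <= D = ", D,
         call. = FALSE)
  }
  perm <- sample.int(D)
  sizes <- rep(D %/% K, K)
  if (D %% K) sizes[seq_len(D %% K)] <- sizes[seq_len(D %% K)] + 1L
  split(perm, rep(seq_len(K), times = sizes))
}

# Bootstrap row draw used for each feature subset's principal-axis fit.
# With replace = FALSE and fraction = 1 the draw is the identity: a full
# permutation has the same covariance, and skipping the shuffle makes the
# construction exactly reproducible outside the ensemble code.
bootstrap_rows <- function(N, fraction, replace = TRUE) {
  n_boot <- floor(fraction * N)
  if (n_boot < 1L) stop("bootstrap fraction too small for N = ", N, call. = FALSE)
  if (!replace && n_boot == N) return(seq_len(N))
  sample.int(N, n_boot, replace = replace)
}

# Full orthonormal principal-axis basis of a feature block, via the eigen
# decomposition of the block covariance. eigen() of a symmetric matrix
# always returns a complete basis, so rank-deficient blocks (zero-variance
# bootstrap columns) are handled without special casing. Eigenvector signs
# are fixed so the largest-|loading| element is positive.
principal_axes <- function(x) {
  n <- nrow(x)
  centered <- sweep(x, 2L, colMeans(x))
  covm <- crossprod(centered) / max(1L, n - 1L)
  V <- eigen(covm, symmetric = TRUE)$vectors
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Fit a rotation forest classifier
#'
#' Trains an ensemble of `L` decision trees. For each tree the feature set
#' is randomly partitioned into `K` disjoint subsets
#' ([partition_features()]); for each subset, `floor(bootstrap_fraction * N)`
#' rows are drawn (with replacement by default), a principal-axis transform
#' is fitted on the drawn rows restricted to the subset's columns, and ALL
#' components are kept. The per-subset axes are assembled into a sparse
#' block-diagonal D x D rotation matrix (mapped back to the original
#' feature order), the full training set is centered with the per-block
#' bootstrap means and rotated, and a CART tree ([rpart::rpart()]) is
#' trained on the rotated features. Defaults reproduce the reference
#' operating point: `K = 8`, `L = 5`, three-quarters bootstrap.
#'
#' All randomness flows from `seed`: the seed initializes a master stream
#' from which one sub-seed per tree is drawn, so refitting with the same
#' seed is bit-identical.
#'
#' @param x Numeric training matrix, N rows x D columns (D >= K).
#' @param y Binary labels (vector coercible to a 2-level factor; both
#'   classes must be present).
#' @param K Number of feature subsets per tree.
#' @param L Number of trees.
#' @param bootstrap_fraction Fraction of rows drawn for each subset's
#'   principal-axis fit, in (0, 1].
#' @param replace Draw bootstrap rows with replacement? Default `TRUE`.
#' @param seed Integer seed controlling all randomness.
#' @param tree_control [rpart::rpart.control()] for the base trees. The
#'   default (`minsplit = 2`, `minbucket = 1`, `cp = 0.01`) mirrors a
#'   C4.5-style tree that splits down to two objects with mild pruning.
#' @return Object of class `rotation_forest`: fields `trees`, `rotations`
#'   (D x D matrices), `partitions`, `centers`, `classes` (ordered label
#'   set), `seed`, `n_boot`, and the training configuration.
#' @seealso [predict.rotation_forest()]
#' @export
rotation_forest <- function(x, y, K = 8L, L = 5L, bootstrap_fraction = 0.75,
                            replace = TRUE, seed = 1L,
                            tree_control = rpart::rpart.control(
                              minsplit = 2L, minbucket = 1L, cp = 0.01,
                              xval = 0L, maxdepth = 30L)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  N <- nrow(x); D <- ncol(x)
  if (N < 2L) stop("need at least 2 training samples", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2L) {
    stop("degenerate training set: only one class present (",
         levels(y)[1L], ")", call. = FALSE)
  }
  if (bootstrap_fraction <= 0 || bootstrap_fraction > 1) {
    stop("bootstrap_fraction must be in (0, 1]", call. = FALSE)
  }
  K <- as.integer(K); L <- as.integer(L)
  if (K > D) stop("invalid partition: K = ", K, " exceeds D = ", D, call. = FALSE)

  set.seed(as.integer(seed))
  tree_seeds <- sample.int(.Machine$integer.max - 1L, L)
  feat_names <- sprintf("r%04d", seq_len(D))

  trees <- vector("list", L)
  rotations <- vector("list", L)
  partitions <- vector("list", L)
  centers <- vector("list", L)
  for (i in seq_len(L)) {
    set.seed(tree_seeds[i])
    part <- partition_features(D, K)
    mat <- matrix(0, D, D)
    center <- numeric(D)
    for (s in part) {
      idx <- bootstrap_rows(N, bootstrap_fraction, replace)
      xs <- x[idx, s, drop = FALSE]
      center[s] <- colMeans(xs)
      mat[s, s] <- principal_axes(xs)
    }
    xr <- sweep(x, 2L, center) %*% mat
    colnames(xr) <- feat_names
    df <- as.data.frame(xr)
    df$.class <- y
    trees[[i]] <- rpart::rpart(.class ~ ., data = df, method = "class",
                               control = tree_control)
    rotations[[i]] <- mat
    partitions[[i]] <- part
    centers[[i]] <- center
  }
  structure(
    list(trees = trees, rotations = rotations, partitions = partitions,
         centers = centers, classes = levels(y), seed = as.integer(seed),
         K = K, L = L, D = D, N = N,
         bootstrap_fraction = bootstrap_fraction,
         n_boot = as.integer(floor(bootstrap_fraction * N)),
         replace = replace, base_learner = "rpart (CART)",
         feature_names = feat_names),
    class = "rotation_forest"
  )
}

#' Class probabilities from a rotation forest
#'
#' Averages the class-probability estimates of the L trees, each evaluated
#' on the input rotated by that tree's matrix:
#' \deqn{\mu_j(x) = \frac{1}{L} \sum_{i=1}^{L} d_{i,j}(x \, Mat_i)}
#' Every output row sums to 1.
#'
#' @param object A fitted [rotation_forest()].
#' @param x Numeric matrix, M rows x D columns (D must match the model).
#' @param type `"prob"` for the M x 2 probability matrix, `"class"` for
#'   predicted labels (argmax; exact ties go to the class listed first in
#'   `object$classes`).
#' @param ... Unused.
#' @return Probability matrix with one column per class, or a character
#'   vector of labels.
#' @export
predict.rotation_forest <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != object$D) {
    stop("feature dimensionality mismatch: model expects D = ", object$D,
         " but input has D = ", ncol(x), call. = FALSE)
  }
  probs <- matrix(0, nrow(x), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (i in seq_len(object$L)) {
    xr <- sweep(x, 2L, object$centers[[i]]) %*% object$rotations[[i]]
    colnames(xr) <- object$feature_names
    p <- predict(object$trees[[i]], as.data.frame(xr), type = "prob")
    probs <- probs + p[, object$classes, drop = FALSE]
  }
  probs <- probs / object$L
  if (type == "prob") {
    probs
  } else {
    object$classes[max.col(probs, ties.method = "first")]
  }
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat("Rotation forest:", x$L, "trees, K =", x$K, "feature subsets, D =",
      x$D, "features\n")
  cat("trained on N =", x$N, "samples (bootstrap", x$n_boot,
      "rows/subset), classes:", paste(x$classes, collapse = ", "), "\n")
  cat("base learner:", x$base_learner, "| seed:", x$seed, "\n")
  invisible(x)
}

#' Save / load a rotation forest model
#'
#' Serializes the full model (trees, rotation matrices, partitions, class
#' order, seed, training metadata) to a single archive. A loaded model
#' reproduces the saved model's predictions bit-for-bit.
#'
#' @param model A [rotation_forest()] model.
#' @param path File path for the archive.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rotation_forest"))
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rotation_forest")) {
    stop("'", path, "' does not contain a rotation_forest model", call. = FALSE)
  }
  model
}
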