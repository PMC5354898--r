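#' Confusion-matrix classification metrics
#'
#' Computes the four standard binary-classification criteria from confusion
#' counts:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' precision `TP/(TP+FP)`, and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' A metric whose denominator is zero is defined as 0 and its name is
#' recorded in the `degenerate` field.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts (at least one
#'   must be positive).
#' @return Object of class `metrics_report`: `counts`, `accuracy`,
#'   `precision`, `sensitivity`, `mcc` (in `[-1, 1]`), `degenerate`
#'   (character vector of zero-denominator metrics).
#' @examples
#' m <- compute_metrics(tp = 40, fp = 5, tn = 45, fn = 10)
#' m$accuracy  # 0.85
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  # arithmetic in doubles: the MCC denominator product overflows 32-bit
  # integers already for counts in the hundreds
  counts <- c(tp = as.numeric(tp), fp = as.numeric(fp),
              tn = as.numeric(tn), fn = as.numeric(fn))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  total <- sum(counts)
  if (total == 0) stop("empty evaluation: all confusion counts are zero", call. = FALSE)
  degenerate <- character(0)
  div <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  accuracy <- (tp + tn) / total
  sensitivity <- div(tp, tp + fn, "sensitivity")
  precision <- div(tp, tp + fp, "precision")
  mcc_den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den2 == 0) {
    degenerate <- c(degenerate, "mcc")
    0
  } else {
    (tp * tn - fp * fn) / sqrt(mcc_den2)
  }
  structure(list(counts = as.list(counts), accuracy = accuracy,
                 precision = precision, sensitivity = sensitivity,
                 mcc = mcc, degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accu. %.2f%%  Prec. %.2f%%  Sen. %.2f%%  MCC %.2f%%\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$sensitivity,
              100 * x$mcc))
  cat(sprintf("counts: TP=%g FP=%g TN=%g FN=%g\n", x$counts$tp, x$counts$fp,
              x$counts$tn, x$counts$fn))
  if (length(x$degenerate)) {
    cat("degenerate (zero denominator):", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct scores (highest first;
#' tied scores are grouped into one point), records (false positive rate,
#' true positive rate) at each threshold, anchors the curve at (0, 0) and
#' (1, 1), and integrates the area under the curve by the trapezoid rule.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels (0/1, logical, or a 2-level factor whose
#'   second level is positive). Both classes must be present.
#' @return List with `points` (data frame `fpr`, `tpr`, ordered along the
#'   sweep) and `auc`.
#' @export
roc_points <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L) {
    stop("ROC undefined: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # one point per distinct score: cumulative counts at each group boundary
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tpr <- cumsum(l)[last_of_group] / P
  fpr <- cumsum(1L - l)[last_of_group] / N
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  n <- length(fpr)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-n]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into k folds. Retries (a fresh shuffle) if some training fold
# would miss a class, then errors.
stratified_folds <- function(y, k, max_retry = 5L) {
  y <- factor(y)
  for (attempt in seq_len(max_retry)) {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    # every fold must itself contain both classes (it serves once as the
    # test set, where sensitivity and ROC need positives and negatives)
    ok <- all(vapply(seq_len(k), function(f) {
      nlevels(droplevels(y[fold == f])) == nlevels(y)
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("stratification failed: some training fold has a single class ",
       "(class too small for k = ", k, ")", call. = FALSE)
}

#' Stratified k-fold cross-validation of a rotation forest
#'
#' Splits the samples into k class-balanced folds, uses each fold once as
#' the test set, fits a [rotation_forest()] on the remaining folds, and
#' reports per-fold metrics plus their mean and sample standard deviation
#' (the `mean +/- std` convention of benchmark tables).
#'
#' @param x Numeric feature matrix (N x D).
#' @param y Binary labels.
#' @param k Number of folds (>= 2).
#' @param K,L,bootstrap_fraction,replace,tree_control Passed to
#'   [rotation_forest()].
#' @param seed Integer seed: drives the fold split and per-fold model seeds.
#' @param positive Label treated as the positive class; defaults to `"1"`
#'   when present, otherwise the second factor level.
#' @param threshold Probability threshold for calling a pair positive
#'   (default 0.5).
#' @param folds Optional precomputed integer fold assignment (length N,
#'   values 1..k); used by [grid_search()] to hold the split fixed.
#' @return Object of class `cv_report`: `per_fold` (data frame with one row
#'   per fold: confusion counts, accuracy, precision, sensitivity, mcc,
#'   auc), `mean`, `sd` (named vectors over the five metrics), `k`,
#'   `positive`, `seed`.
#' @export
cross_validate <- function(x, y, k = 5L, K = 8L, L = 5L,
                           bootstrap_fraction = 0.75, replace = TRUE,
                           seed = 1L, positive = NULL, threshold = 0.5,
                           folds = NULL,
                           tree_control = rpart::rpart.control(
                             minsplit = 2L, minbucket = 1L, cp = 0.01,
                             xval = 0L, maxdepth = 30L)) {
  x <- as.matrix(x)
  k <- as.integer(k)
  if (k < 2L) stop("cross-validation needs k >= 2 folds", call. = FALSE)
  yf <- factor(y)
  if (nlevels(yf) != 2L) stop("cross_validate expects binary labels", call. = FALSE)
  if (is.null(positive)) {
    positive <- if ("1" %in% levels(yf)) "1" else levels(yf)[2L]
  }
  # fold seeds are drawn before the fold split so that a call with a
  # precomputed (but identically drawn) `folds` reproduces a direct call
  set.seed(as.integer(seed))
  fold_seeds <- sample.int(.Machine$integer.max - 1L, k)
  if (is.null(folds)) folds <- stratified_folds(yf, k)

  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- folds != f
    model <- rotation_forest(x[train, , drop = FALSE], yf[train],
                             K = K, L = L,
                             bootstrap_fraction = bootstrap_fraction,
                             replace = replace, seed = fold_seeds[f],
                             tree_control = tree_control)
    prob <- predict(model, x[!train, , drop = FALSE], type = "prob")
    p_pos <- prob[, positive]
    truth <- yf[!train] == positive
    call_pos <- p_pos >= threshold
    m <- compute_metrics(tp = sum(call_pos & truth),
                         fp = sum(call_pos & !truth),
                         tn = sum(!call_pos & !truth),
                         fn = sum(!call_pos & truth))
    auc <- roc_points(p_pos, as.integer(truth))$auc
    rows[[f]] <- data.frame(fold = f, tp = m$counts$tp, fp = m$counts$fp,
                            tn = m$counts$tn, fn = m$counts$fn,
                            accuracy = m$accuracy, precision = m$precision,
                            sensitivity = m$sensitivity, mcc = m$mcc,
                            auc = auc)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "precision", "sensitivity", "mcc", "auc")
  structure(
    list(per_fold = per_fold,
         mean = colMeans(per_fold[metric_cols]),
         sd = vapply(per_fold[metric_cols], stats::sd, numeric(1)),
         k = k, positive = positive, seed = as.integer(seed)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (positive class: %s)\n", x$k, x$positive))
  cat("Fold  Accu.(%)  Prec.(%)  Sen.(%)  MCC(%)    AUC\n")
  for (f in seq_len(nrow(x$per_fold))) {
    r <- x$per_fold[f, ]
    cat(sprintf("%4d  %8.2f  %8.2f  %7.2f  %6.2f  %.4f\n", r$fold,
                100 * r$accuracy, 100 * r$precision, 100 * r$sensitivity,
                100 * r$mcc, r$auc))
  }
  cat(sprintf("Avg   %5.2f+/-%.2f  %5.2f+/-%.2f  %5.2f+/-%.2f  %5.2f+/-%.2f  %.4f\n",
              100 * x$mean["accuracy"], 100 * x$sd["accuracy"],
              100 * x$mean["precision"], 100 * x$sd["precision"],
              100 * x$mean["sensitivity"], 100 * x$sd["sensitivity"],
              100 * x$mean["mcc"], 100 * x$sd["mcc"], x$mean["auc"]))
  invisible(x)
}

#' Grid search over rotation-forest parameters K and L
#'
#' Evaluates every (K, L) cell of the Cartesian grid by stratified k-fold
#' cross-validation with the fold split held fixed across cells, and
#' returns the full accuracy table plus the best cell (ties broken toward
#' smaller L, then smaller K).
#'
#' @param x Numeric feature matrix.
#' @param y Binary labels.
#' @param K_grid,L_grid Integer vectors of candidate values.
#' @param k Folds per cell.
#' @param seed Seed for the shared fold split and per-cell model fits.
#' @param ... Further arguments forwarded to [cross_validate()].
#' @return Object of class `grid_search_result`: `table` (data frame `K`,
#'   `L`, `mean_accuracy`, `sd_accuracy`) and `best` (one-row data frame).
#' @export
grid_search <- function(x, y, K_grid, L_grid, k = 5L, seed = 1L, ...) {
  if (!length(K_grid) || !length(L_grid)) {
    stop("K_grid and L_grid must be non-empty", call. = FALSE)
  }
  # mirror cross_validate's stream (fold seeds first) so every cell equals
  # a direct cross_validate call with the same seed
  set.seed(as.integer(seed))
  invisible(sample.int(.Machine$integer.max - 1L, as.integer(k)))
  folds <- stratified_folds(factor(y), as.integer(k))
  cells <- expand.grid(K = as.integer(K_grid), L = as.integer(L_grid))
  acc <- numeric(nrow(cells)); sdv <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cv <- cross_validate(x, y, k = k, K = cells$K[i], L = cells$L[i],
                         seed = seed, folds = folds, ...)
    acc[i] <- cv$mean["accuracy"]
    sdv[i] <- cv$sd["accuracy"]
  }
  tab <- cbind(cells, mean_accuracy = acc, sd_accuracy = sdv)
  best <- tab[order(-tab$mean_accuracy, tab$L, tab$K), ][1L, ]
  structure(list(table = tab, best = best), class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("best: K = %d, L = %d (mean accuracy %.4f)\n",
              x$best$K, x$best$L, x$best$mean_accuracy))
  invisible(x)
}
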