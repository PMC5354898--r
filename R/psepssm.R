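#' Row-standardize a PSSM profile
#'
#' Standardizes every row of the raw score matrix to mean 0 and population
#' standard deviation 1 (divide-by-20 form):
#' \deqn{a_{i,j} = \frac{a^0_{i,j} - \bar a^0_i}{\sqrt{\tfrac{1}{20}\sum_u (a^0_{i,u} - \bar a^0_i)^2}}}
#' Rows whose 20 raw scores are all equal carry no information and map to 20
#' zeros by convention.
#'
#' @param profile A [pssm_profile].
#' @return An object of class `normalized_profile` with fields `protein_id`
#'   and `values` (L x 20 numeric matrix).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  s <- profile$scores
  storage.mode(s) <- "double"
  mu <- rowMeans(s)
  centered <- s - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  values <- centered / ifelse(sd_pop > 0, sd_pop, 1)
  values[sd_pop == 0, ] <- 0
  dimnames(values) <- list(NULL, AA_ORDER)
  structure(list(protein_id = profile$protein_id, values = values),
            class = "normalized_profile")
}

#' Lag correlation factors of a normalized profile
#'
#' For lag `eps = 0`, the per-column mean over the L residues. For
#' `eps >= 1`, the per-column mean squared difference between residues
#' `eps` positions apart:
#' \deqn{\bar a_j(\varepsilon) = \frac{1}{L-\varepsilon}
#'   \sum_{i=1}^{L-\varepsilon} (a_{i,j} - a_{i+\varepsilon,j})^2}
#' These factors retain sequence-order information that the plain column
#' mean discards.
#'
#' @param norm A `normalized_profile` from [normalize_profile()].
#' @param eps Non-negative integer lag, strictly smaller than the profile
#'   length L.
#' @return Numeric vector of length 20 (named by amino acid). All entries
#'   are non-negative for `eps >= 1`.
#' @export
lag_component <- function(norm, eps) {
  stopifnot(inherits(norm, "normalized_profile"))
  a <- norm$values
  L <- nrow(a)
  eps <- as.integer(eps)
  if (eps < 0L) stop("eps must be non-negative", call. = FALSE)
  if (eps >= L) {
    stop("lag too large: eps = ", eps, " but profile '", norm$protein_id,
         "' has only L = ", L, " residues (need eps < L)", call. = FALSE)
  }
  if (eps == 0L) {
    colMeans(a)
  } else {
    d <- a[seq_len(L - eps), , drop = FALSE] - a[seq_len(L - eps) + eps, , drop = FALSE]
    colMeans(d^2)
  }
}

#' Pseudo-PSSM descriptor of one protein
#'
#' Maps a variable-length PSSM profile to a fixed-length descriptor: the
#' concatenation of the [lag_component()] vectors for lags 0 through
#' `eps_max` of the row-standardized profile. With the default
#' `eps_max = 4` the descriptor has 20 x 5 = 100 entries, so proteins of
#' any length are represented in a uniform pattern.
#'
#' @param profile A [pssm_profile] with length L > `eps_max`.
#' @param eps_max Largest lag (non-negative integer). Default 4.
#' @return An object of class `psepssm_descriptor` with fields `protein_id`,
#'   `eps_max` and `values` (numeric vector of length `20 * (eps_max + 1)`,
#'   ordered lag-0 block first).
#' @examples
#' p <- pssm_profile("toy", matrix(sample(-8:8, 60 * 20, TRUE), 60, 20),
#'                   paste(rep("A", 60), collapse = ""))
#' length(protein_descriptor(p, eps_max = 4)$values)  # 100
#' @export
protein_descriptor <- function(profile, eps_max = 4L) {
  stopifnot(inherits(profile, "pssm_profile"))
  eps_max <- as.integer(eps_max)
  if (eps_max < 0L) stop("eps_max must be non-negative", call. = FALSE)
  L <- nrow(profile$scores)
  if (eps_max >= L) {
    stop("protein '", profile$protein_id, "' is too short: L = ", L,
         " residues but eps_max = ", eps_max,
         " requires at least ", eps_max + 1L, call. = FALSE)
  }
  norm <- normalize_profile(profile)
  blocks <- lapply(0:eps_max, function(e) lag_component(norm, e))
  values <- unlist(blocks, use.names = FALSE)
  names(values) <- paste0("eps", rep(0:eps_max, each = 20L), "_", AA_ORDER)
  structure(list(protein_id = profile$protein_id, eps_max = eps_max,
                 values = values),
            class = "psepssm_descriptor")
}

#' Ordered pair feature vector
#'
#' Concatenates the descriptors of two proteins (A first, B second) into the
#' feature vector of the ordered pair. With `eps_max = 4` the pair vector
#' has 200 entries. The predictor is therefore order-sensitive; see
#' [build_pair_features()] for the symmetrization option.
#'
#' @param da,db `psepssm_descriptor` objects with equal `eps_max`.
#' @param label Optional 0/1 interaction label (`NA` when unknown).
#' @return An object of class `pair_sample` with fields `id_a`, `id_b`,
#'   `features` and `label`.
#' @export
pair_descriptor <- function(da, db, label = NA_integer_) {
  stopifnot(inherits(da, "psepssm_descriptor"),
            inherits(db, "psepssm_descriptor"))
  if (da$eps_max != db$eps_max) {
    stop("incompatible descriptors: eps_max ", da$eps_max, " (",
         da$protein_id, ") vs ", db$eps_max, " (", db$protein_id, ")",
         call. = FALSE)
  }
  features <- c(da$values, db$values)
  names(features) <- sprintf("f%04d", seq_along(features))
  structure(list(id_a = da$protein_id, id_b = db$protein_id,
                 features = features, label = label),
            class = "pair_sample")
}

#' Build the feature table for a list of protein pairs
#'
#' Computes one pseudo-PSSM descriptor per distinct protein and assembles
#' the ordered-pair feature table: one row per pair with columns `id_a`,
#' `id_b`, `label` (NA when unlabeled) and `f0001 ...` feature columns
#' (`2 * 20 * (eps_max + 1)` of them).
#'
#' @param profiles Named list of [pssm_profile] objects (names are protein
#'   ids), or a list whose elements carry `protein_id` fields.
#' @param pairs Data frame with columns `id_a`, `id_b` and optionally
#'   `label`.
#' @param eps_max Largest lag passed to [protein_descriptor()].
#' @param symmetrize If `TRUE`, each labeled pair is emitted in both
#'   orderings (A,B and B,A), which trains an order-insensitive model.
#' @return A data frame feature table.
#' @export
build_pair_features <- function(profiles, pairs, eps_max = 4L,
                                symmetrize = FALSE) {
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- vapply(profiles, function(p) p$protein_id, character(1))
  }
  stopifnot(is.data.frame(pairs), all(c("id_a", "id_b") %in% names(pairs)))
  ids <- unique(c(as.character(pairs$id_a), as.character(pairs$id_b)))
  missing_ids <- setdiff(ids, names(profiles))
  if (length(missing_ids)) {
    stop("no profile for id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  desc <- lapply(profiles[ids], protein_descriptor, eps_max = eps_max)
  labels <- if ("label" %in% names(pairs)) as.integer(pairs$label) else
    rep(NA_integer_, nrow(pairs))
  if (symmetrize) {
    pairs2 <- pairs
    pairs2$id_a <- pairs$id_b
    pairs2$id_b <- pairs$id_a
    labels <- c(labels, labels)
    pairs <- rbind(pairs[c("id_a", "id_b")], pairs2[c("id_a", "id_b")])
  }
  nfeat <- 2L * 20L * (eps_max + 1L)
  feat <- matrix(NA_real_, nrow(pairs), nfeat,
                 dimnames = list(NULL, sprintf("f%04d", seq_len(nfeat))))
  for (r in seq_len(nrow(pairs))) {
    feat[r, ] <- c(desc[[as.character(pairs$id_a[r])]]$values,
                   desc[[as.character(pairs$id_b[r])]]$values)
  }
  out <- data.frame(id_a = as.character(pairs$id_a),
                    id_b = as.character(pairs$id_b),
                    label = labels, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(feat))
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param table Feature table from [build_pair_features()] or
#'   [read_feature_table()].
#' @return Numeric matrix of the `f....` columns.
#' @export
feature_matrix <- function(table) {
  cols <- grep("^f[0-9]+$", names(table), value = TRUE)
  if (!length(cols)) stop("no feature columns (f0001 ...) found", call. = FALSE)
  as.matrix(table[cols])
}

#' Write a pair feature table as TSV
#'
#' Columns: `id_a`, `id_b`, `label` (`-` when unlabeled), then the feature
#' columns. Numbers are written with full precision (17 significant digits)
#' so the file round-trips bit-for-bit.
#'
#' @param table Feature table data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  out <- table
  out$label <- ifelse(is.na(table$label), "-", as.character(table$label))
  fcols <- grep("^f[0-9]+$", names(out))
  for (j in fcols) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a pair feature table written by [write_feature_table()]
#'
#' @param path Path to the TSV file.
#' @return Feature table data frame (`label` is integer, NA when `-`).
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  tab$label <- suppressWarnings(as.integer(ifelse(tab$label == "-", NA, tab$label)))
  fcols <- grep("^f[0-9]+$", names(tab))
  for (j in fcols) tab[[j]] <- as.numeric(tab[[j]])
  tab$id_a <- as.character(tab$id_a)
  tab$id_b <- as.character(tab$id_b)
  tab
}
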