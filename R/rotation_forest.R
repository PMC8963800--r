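# Rotation forest ensemble, from scratch.
#
# Each of the L members draws its own random partition of the n features
# into K disjoint subsets, fits PCA per subset on a bootstrapped 75%
# subsample, assembles the per-subset coefficient blocks into a sparse
# block-diagonal n x n rotation matrix, rearranges it back to the original
# feature order, and trains an unpruned CART tree on the rotated data. At
# prediction time the class confidences of the L trees are averaged and
# the sample is assigned to the class with the largest confidence.

#' Rotation forest configuration
#'
#' Defaults L = 3 trees and K = 10 feature subsets follow the standard
#' grid-searched operating point for PSSM-texture PPI prediction; the
#' bootstrap subsample is 75% of the training objects, drawn with
#' replacement.
#'
#' @param L Number of base decision trees (>= 1).
#' @param K Number of feature subsets (>= 1, at most the feature count at
#'   fit time).
#' @param bootstrap_fraction Fraction of objects in each per-subset
#'   bootstrap sample, in (0, 1].
#' @param seed Integer master seed; member- and block-level seeds are
#'   derived from it with [derive_seed] so runs reproduce exactly.
#' @return An object of class `rof_config`.
#' @export
rof_config <- function(L = 3L, K = 10L, bootstrap_fraction = 0.75, seed = 1L) {
  L <- as.integer(L)
  K <- as.integer(K)
  stopifnot(L >= 1L, K >= 1L,
            bootstrap_fraction > 0, bootstrap_fraction <= 1)
  structure(list(L = L, K = K,
                 bootstrap_fraction = bootstrap_fraction,
                 seed = as.integer(seed)),
            class = "rof_config")
}

#' Randomly partition features into K disjoint subsets
#'
#' A seeded random permutation of `1:n` cut into K contiguous chunks; when
#' K does not divide n the first `n %% K` subsets get one extra feature,
#' so sizes differ by at most 1.
#'
#' @param n Number of features.
#' @param K Number of subsets, `1 <= K <= n`.
#' @param seed Integer seed.
#' @return Object of class `feature_partition`: list of K integer vectors,
#'   disjoint, covering `1:n`.
#' @export
partition_features <- function(n, K, seed = 1L) {
  n <- as.integer(n)
  K <- as.integer(K)
  if (K > n) data_error("K = ", K, " exceeds feature count n = ", n)
  if (K < 1L) data_error("K must be >= 1")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% K, K)
  extra <- n %% K
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  subsets <- lapply(seq_len(K), function(j) perm[starts[j]:ends[j]])
  structure(subsets, class = "feature_partition")
}

#' PCA coefficient block for one feature subset
#'
#' Draws a bootstrap subsample of `round(bootstrap_fraction * N)` objects
#' with replacement, runs PCA on it, and returns all principal-axis
#' coefficient vectors as an orthonormal `M_j x M_j` block. When the
#' subsample's covariance is rank-deficient the missing axes are completed
#' to a full orthonormal basis (QR), keeping the per-block map invertible.
#' If a draw has fewer than two distinct rows it is reseeded and retried a
#' bounded number of times.
#'
#' @param X_subset Numeric matrix, samples x M_j (the columns of one
#'   feature subset).
#' @param Y Class labels; unused by plain PCA but kept in the signature for
#'   rotation bases that need them.
#' @param bootstrap_fraction Fraction of objects to draw (default 0.75).
#' @param seed Integer seed.
#' @param max_retries Bounded retries for degenerate draws.
#' @return Object of class `rotation_block`: list with `block` (M_j x M_j
#'   orthonormal matrix, axes in columns), `center` (bootstrap-sample
#'   column means, subtracted before projection) and `n_boot` (subsample
#'   size actually drawn).
#' @export
fit_block_rotation <- function(X_subset, Y = NULL, bootstrap_fraction = 0.75,
                               seed = 1L, max_retries = 10L) {
  X_subset <- as.matrix(X_subset)
  N <- nrow(X_subset)
  Mj <- ncol(X_subset)
  if (N < 2L) data_error("need at least 2 samples to fit a rotation block")
  size <- max(2L, round(bootstrap_fraction * N))
  idx <- NULL
  for (attempt in seq_len(max_retries)) {
    cand <- with_seed(derive_seed(seed, attempt),
                      sample.int(N, size, replace = TRUE))
    if (nrow(unique(X_subset[cand, , drop = FALSE])) >= 2L) {
      idx <- cand
      break
    }
  }
  if (is.null(idx)) {
    data_error("bootstrap subsample degenerate (fewer than 2 distinct ",
               "samples) after ", max_retries, " retries")
  }
  Xb <- X_subset[idx, , drop = FALSE]
  center <- colMeans(Xb)
  pc <- stats::prcomp(Xb, center = TRUE, scale. = FALSE)
  V <- pc$rotation # Mj x r, orthonormal columns
  if (ncol(V) < Mj) {
    Q <- qr.Q(qr(cbind(V, diag(Mj))))
    V <- cbind(V, Q[, (ncol(V) + 1L):Mj, drop = FALSE])
  }
  structure(list(block = unname(V), center = unname(center),
                 n_boot = length(idx)),
            class = "rotation_block")
}

#' Assemble the sparse rotation matrix from per-subset blocks
#'
#' Builds the block-diagonal n x n matrix in subset order and its
#' rearrangement back to the original feature order, so that rotating a
#' sample is a single matrix product `(x - center) %*% rearranged`.
#'
#' @param blocks List of K `rotation_block`s (or bare M_j x M_j matrices),
#'   block j matching the j-th subset of `partition`.
#' @param partition A [partition_features] result.
#' @return Object of class `rotation_matrix`: list with `matrix` (block
#'   diagonal, features in subset order), `rearranged` (original feature
#'   order), `center` (length-n vector) and `partition`.
#' @export
build_rotation_matrix <- function(blocks, partition) {
  K <- length(partition)
  if (length(blocks) != K) {
    data_error("got ", length(blocks), " blocks for ", K, " subsets")
  }
  mats <- lapply(blocks, function(b) {
    if (inherits(b, "rotation_block")) b$block else as.matrix(b)
  })
  centers <- lapply(seq_len(K), function(j) {
    b <- blocks[[j]]
    if (inherits(b, "rotation_block")) b$center
    else rep(0, ncol(mats[[j]]))
  })
  sizes <- lengths(partition)
  for (j in seq_len(K)) {
    if (!all(dim(mats[[j]]) == c(sizes[j], sizes[j]))) {
      data_error("block ", j, " is ", nrow(mats[[j]]), " x ", ncol(mats[[j]]),
                 " but subset ", j, " has ", sizes[j], " features")
    }
  }
  n <- sum(sizes)
  R <- matrix(0, n, n)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (j in seq_len(K)) {
    R[starts[j]:ends[j], starts[j]:ends[j]] <- mats[[j]]
  }
  perm <- unlist(partition, use.names = FALSE)
  Ra <- matrix(0, n, n)
  Ra[perm, perm] <- R
  ctr <- numeric(n)
  ctr[perm] <- unlist(centers, use.names = FALSE)
  structure(list(matrix = R, rearranged = Ra, center = ctr,
                 partition = partition),
            class = "rotation_matrix")
}

#' Apply a rotation to a data matrix
#'
#' @param rotation A [build_rotation_matrix] result.
#' @param X Numeric matrix, samples x n (original feature order).
#' @return The rotated matrix `(X - center) %*% rearranged`.
#' @export
rotate_data <- function(rotation, X) {
  X <- as.matrix(X)
  n <- length(rotation$center)
  if (ncol(X) != n) {
    data_error("data has ", ncol(X), " features but rotation expects ", n)
  }
  sweep(X, 2L, rotation$center) %*% rotation$rearranged
}

#' Fit a rotation forest
#'
#' @param X Numeric matrix, N samples x n features.
#' @param Y Vector of class labels (both classes must be present; any
#'   atomic label type).
#' @param config A [rof_config].
#' @return Object of class `rotation_forest`: list with `members` (L pairs
#'   of `rotation` and `tree`), `classes` (sorted unique labels; order
#'   fixes tie-breaking), `config` and `n_features`.
#' @export
rof_fit <- function(X, Y, config = rof_config()) {
  X <- as.matrix(X)
  N <- nrow(X)
  n <- ncol(X)
  if (N < 2L) data_error("need at least 2 training samples")
  if (length(Y) != N) data_error("X and Y disagree on sample count")
  classes <- sort(unique(Y))
  if (length(classes) < 2L) {
    data_error("training labels contain a single class; cannot fit")
  }
  if (config$K > n) {
    data_error("K = ", config$K, " exceeds feature count n = ", n)
  }
  yi <- match(Y, classes)
  nclass <- length(classes)
  members <- vector("list", config$L)
  for (i in seq_len(config$L)) {
    si <- derive_seed(config$seed, 101L, i)
    part <- partition_features(n, config$K, seed = si)
    blocks <- lapply(seq_along(part), function(j) {
      fit_block_rotation(X[, part[[j]], drop = FALSE], Y,
                         bootstrap_fraction = config$bootstrap_fraction,
                         seed = derive_seed(config$seed, 202L, i, j))
    })
    rot <- build_rotation_matrix(blocks, part)
    tree <- fit_cart(rotate_data(rot, X), yi, nclass)
    members[[i]] <- list(rotation = rot, tree = tree)
  }
  structure(list(members = members, classes = classes, config = config,
                 n_features = n),
            class = "rotation_forest")
}

#' Class confidences of a rotation forest
#'
#' The confidence of class k is the average over the L trees of the leaf
#' class-frequency each tree assigns to the rotated sample; rows sum to 1.
#'
#' @param model A [rof_fit] model.
#' @param X Numeric matrix, samples x n (training feature order).
#' @return Matrix samples x classes of confidences; column names are the
#'   class labels.
#' @export
rof_predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    data_error("data has ", ncol(X), " features but model expects ",
               model$n_features)
  }
  acc <- matrix(0, nrow(X), length(model$classes))
  for (m in model$members) {
    acc <- acc + predict_cart_proba(m$tree, rotate_data(m$rotation, X))
  }
  out <- acc / length(model$members)
  colnames(out) <- as.character(model$classes)
  out
}

#' Predicted class labels of a rotation forest
#'
#' Argmax of the class confidences; exact ties go to the class that comes
#' earlier in the model's class ordering.
#'
#' @inheritParams rof_predict_proba
#' @return Vector of predicted labels, same type as the training labels.
#' @export
rof_predict <- function(model, X) {
  p <- rof_predict_proba(model, X)
  model$classes[max.col(p, ties.method = "first")]
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat(sprintf("Rotation forest: L = %d trees, K = %d subsets, %d features, classes: %s\n",
              x$config$L, x$config$K, x$n_features,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

# ---- model archive (versioned JSON schema) --------------------------------

#' Save a rotation forest to a single archive file
#'
#' Plain-JSON schema `rotation_forest/1` holding the config, per-member
#' partitions, rotation matrices, centers, and flat tree tables. Numeric
#' values are written at full precision, so a loaded model reproduces the
#' original's predictions exactly.
#'
#' @param model A [rof_fit] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
rof_save <- function(model, path) {
  stopifnot(inherits(model, "rotation_forest"))
  obj <- list(
    schema = "rotation_forest/1",
    config = unclass(model$config),
    classes = model$classes,
    class_type = class(model$classes)[1],
    n_features = model$n_features,
    members = lapply(model$members, function(m) list(
      partition = lapply(m$rotation$partition, as.integer),
      rearranged = m$rotation$rearranged,
      center = m$rotation$center,
      tree = list(feature = m$tree$feature, threshold = m$tree$threshold,
                  left = m$tree$left, right = m$tree$right,
                  counts = m$tree$counts, nclass = m$tree$nclass)
    ))
  )
  # fully boxed: auto_unbox would silently turn length-1 vectors (single
  # leaf trees, singleton feature subsets) into scalars
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       na = "null")
  invisible(path)
}

#' Load a rotation forest archive written by [rof_save]
#'
#' @param path Archive path.
#' @return A `rotation_forest` model.
#' @export
rof_load <- function(path) {
  if (!file.exists(path)) data_error("model archive not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  sc <- function(x) if (is.list(x)) x[[1]] else x # unbox
  if (!identical(sc(obj$schema), "rotation_forest/1")) {
    data_error("unsupported model schema: ", sc(obj$schema))
  }
  cfg <- rof_config(sc(obj$config$L), sc(obj$config$K),
                    sc(obj$config$bootstrap_fraction), sc(obj$config$seed))
  classes <- unlist(obj$classes)
  if (identical(sc(obj$class_type), "integer")) classes <- as.integer(classes)
  if (identical(sc(obj$class_type), "numeric")) classes <- as.numeric(classes)
  # JSON nulls (serialized NAs) come back as NULL list elements
  num_vec <- function(x) {
    vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           numeric(1))
  }
  int_vec <- function(x) as.integer(num_vec(x))
  num_mat <- function(rows) do.call(rbind, lapply(rows, num_vec))
  mem <- lapply(obj$members, function(m) {
    part <- structure(lapply(m$partition, int_vec),
                      class = "feature_partition")
    rot <- structure(list(matrix = NULL,
                          rearranged = num_mat(m$rearranged),
                          center = num_vec(m$center),
                          partition = part),
                     class = "rotation_matrix")
    tr <- structure(list(feature = int_vec(m$tree$feature),
                         threshold = num_vec(m$tree$threshold),
                         left = int_vec(m$tree$left),
                         right = int_vec(m$tree$right),
                         counts = num_mat(m$tree$counts),
                         nclass = as.integer(sc(m$tree$nclass))),
                    class = "cart_tree")
    list(rotation = rot, tree = tr)
  })
  structure(list(members = mem, classes = classes, config = cfg,
                 n_features = as.integer(obj$n_features)),
            class = "rotation_forest")
}
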