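# Unpruned CART-style classification tree (Gini impurity), the base
# learner of the rotation forest. Written from scratch: no tree package is
# assumed. Trees are stored flat (parallel vectors indexed by node id) so
# they serialize to plain JSON.
#
# Splits are axis-aligned `x[, j] <= threshold`; thresholds sit midway
# between consecutive distinct values. Growth continues until nodes are
# pure or no feature admits a split (all candidate features constant), i.e.
# no pruning, no depth cap. Ties in impurity favour the lower feature index
# then the lower threshold, which makes fits deterministic.

# Best split for one node. Returns NULL when no split reduces impurity.
best_gini_split <- function(X, y, nclass) {
  n <- length(y)
  total <- tabulate(y, nclass)
  best <- NULL
  best_score <- Inf
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    o <- order(v)
    sv <- v[o]
    sy <- y[o]
    cuts <- which(sv[-n] < sv[-1]) # split after position i
    if (length(cuts) == 0L) next
    cum <- matrix(0, n, nclass)
    for (k in seq_len(nclass)) cum[, k] <- cumsum(sy == k)
    nl <- cuts
    nr <- n - nl
    cl <- cum[cuts, , drop = FALSE]
    cr <- matrix(total, nrow = length(cuts), ncol = nclass, byrow = TRUE) - cl
    # weighted Gini: n_l * (1 - sum p_l^2) + n_r * (1 - sum p_r^2)
    score <- nl - rowSums(cl^2) / nl + nr - rowSums(cr^2) / nr
    i <- which.min(score)
    if (score[i] < best_score - 1e-12) {
      best_score <- score[i]
      best <- list(feature = j,
                   threshold = (sv[cuts[i]] + sv[cuts[i] + 1L]) / 2)
    }
  }
  # only accept splits that actually reduce impurity
  parent <- n - sum(total^2) / n
  if (!is.null(best) && best_score >= parent - 1e-12) best <- NULL
  best
}

#' Fit an unpruned CART classification tree
#'
#' @param X Numeric matrix, samples x features.
#' @param y Integer class labels in `1..nclass`.
#' @param nclass Number of classes.
#' @return An object of class `cart_tree`: flat node table with vectors
#'   `feature` (NA at leaves), `threshold`, `left`, `right` (child ids, NA
#'   at leaves) and matrix `counts` (per-node class counts).
#' @export
fit_cart <- function(X, y, nclass = max(y)) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y >= 1L), all(y <= nclass))
  env <- new.env()
  env$feature <- integer(0)
  env$threshold <- numeric(0)
  env$left <- integer(0)
  env$right <- integer(0)
  env$counts <- NULL
  grow <- function(idx) {
    id <- length(env$feature) + 1L
    cnt <- tabulate(y[idx], nclass)
    env$feature <- c(env$feature, NA_integer_)
    env$threshold <- c(env$threshold, NA_real_)
    env$left <- c(env$left, NA_integer_)
    env$right <- c(env$right, NA_integer_)
    env$counts <- rbind(env$counts, cnt)
    if (sum(cnt > 0L) <= 1L || length(idx) < 2L) {
      return(id)
    }
    sp <- best_gini_split(X[idx, , drop = FALSE], y[idx], nclass)
    if (is.null(sp)) {
      return(id)
    }
    go_left <- X[idx, sp$feature] <= sp$threshold
    lid <- grow(idx[go_left])
    rid <- grow(idx[!go_left])
    env$feature[id] <- sp$feature
    env$threshold[id] <- sp$threshold
    env$left[id] <- lid
    env$right[id] <- rid
    id
  }
  grow(seq_len(nrow(X)))
  structure(list(feature = env$feature, threshold = env$threshold,
                 left = env$left, right = env$right,
                 counts = unname(env$counts), nclass = as.integer(nclass)),
            class = "cart_tree")
}

#' Leaf class-frequency distributions for new samples
#'
#' @param tree A [fit_cart] tree.
#' @param X Numeric matrix, samples x features.
#' @return Matrix samples x nclass of leaf class frequencies (rows sum
#'   to 1).
#' @export
predict_cart_proba <- function(tree, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  out <- matrix(0, n, tree$nclass)
  route <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    f <- tree$feature[node]
    if (is.na(f)) {
      cnt <- tree$counts[node, ]
      out[idx, ] <<- matrix(cnt / sum(cnt), length(idx), tree$nclass,
                            byrow = TRUE)
      return(invisible())
    }
    go_left <- X[idx, f] <= tree$threshold[node]
    route(tree$left[node], idx[go_left])
    route(tree$right[node], idx[!go_left])
  }
  route(1L, seq_len(n))
  out
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("CART tree: %d nodes (%d leaves), %d classes\n",
              length(x$feature), sum(is.na(x$feature)), x$nclass))
  invisible(x)
}
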