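# Independent reference implementations used as oracles. These are written
# straight from the descriptor/statistic definitions, deliberately not
# sharing code with the package internals they check.

# clockwise ring positions in 3x3 matrix coordinates, n = 0..7 from top-left
oracle_ring <- list(c(1L, 1L), c(1L, 2L), c(1L, 3L), c(2L, 3L),
                    c(3L, 3L), c(3L, 2L), c(3L, 1L), c(2L, 1L))

oracle_masks <- function() {
  lapply(0:7, function(n) {
    m <- matrix(-3, 3L, 3L)
    m[2L, 2L] <- 0
    for (d in c(-1L, 0L, 1L)) {
      rc <- oracle_ring[[((n + d) %% 8L) + 1L]]
      m[rc[1], rc[2]] <- 5
    }
    m
  })
}

oracle_loop_code <- function(patch) {
  resp <- vapply(oracle_masks(), function(m) sum(m * patch), numeric(1))
  ord <- order(-abs(resp), seq_along(resp)) # magnitude desc, index tie-break
  w <- integer(8L)
  w[ord] <- 7:0
  code <- 0
  for (p in 1:8) {
    rc <- oracle_ring[[p]]
    if (patch[rc[1], rc[2]] >= patch[2L, 2L]) code <- code + 2^w[p]
  }
  as.integer(code)
}

# naive double loop over interior cells
oracle_loop_hist <- function(S) {
  codes <- integer(0)
  for (i in 2:(nrow(S) - 1L)) {
    for (j in 2:(ncol(S) - 1L)) {
      codes <- c(codes, oracle_loop_code(S[(i - 1L):(i + 1L),
                                           (j - 1L):(j + 1L)]))
    }
  }
  tabulate(codes + 1L, nbins = 256L) / length(codes)
}

# exhaustive Mann-Whitney pairwise comparison, ties counted 1/2
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

rand_pssm <- function(M, seed = 1) {
  set.seed(seed)
  pssm(matrix(rnorm(20 * M), 20L, M), protein_id = sprintf("rnd%d", seed))
}

# tiny k-fold CV of a single unpruned CART tree on raw features
tree_cv_accuracy <- function(X, Y, k, seed) {
  folds <- kfold_split(nrow(X), k, seed)
  accs <- vapply(seq_len(k), function(f) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(nrow(X)), te)
    cls <- sort(unique(Y[tr]))
    tree <- fit_cart(X[tr, , drop = FALSE], match(Y[tr], cls), length(cls))
    p <- predict_cart_proba(tree, X[te, , drop = FALSE])
    mean(cls[max.col(p, ties.method = "first")] == Y[te])
  }, numeric(1))
  mean(accs)
}
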