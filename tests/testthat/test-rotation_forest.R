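test_that("partition_features: sizes, disjointness, determinism", {
  p <- partition_features(512, 10, seed = 2)
  expect_identical(lengths(p), c(52L, 52L, rep(51L, 8)))
  expect_identical(sort(unlist(p)), 1:512)

  q <- partition_features(12, 4, seed = 9)
  expect_identical(lengths(q), rep(3L, 4))
  expect_identical(sort(unlist(q)), 1:12)

  expect_identical(partition_features(40, 7, seed = 5),
                   partition_features(40, 7, seed = 5))
  expect_false(identical(partition_features(40, 7, seed = 5),
                         partition_features(40, 7, seed = 6)))
  expect_error(partition_features(5, 6), "exceeds")
})

test_that("fit_block_rotation: bootstrap size, orthonormality, PCA axes", {
  set.seed(14)
  X <- matrix(rnorm(200 * 8), 200, 8)
  b <- fit_block_rotation(X, bootstrap_fraction = 0.75, seed = 4)
  expect_identical(b$n_boot, 150L) # round(0.75 * 200)
  expect_lt(max(abs(crossprod(b$block) - diag(8))), 1e-8)

  # diagonal covariance diag(4, 1): first axis aligns with feature 1
  set.seed(15)
  X2 <- cbind(rnorm(2000, sd = 2), rnorm(2000, sd = 1))
  b2 <- fit_block_rotation(X2, seed = 6)
  expect_gt(abs(b2$block[1, 1]), 0.95)

  # rank-deficient subsample still yields a full orthonormal basis
  X3 <- matrix(rnorm(4 * 9), 4, 9)
  b3 <- fit_block_rotation(X3, seed = 8)
  expect_identical(dim(b3$block), c(9L, 9L))
  expect_lt(max(abs(crossprod(b3$block) - diag(9))), 1e-8)

  # constant data: every bootstrap degenerate -> bounded retries then error
  expect_error(fit_block_rotation(matrix(1, 50, 3), seed = 1), "degenerate")
})

test_that("build_rotation_matrix assembles and rearranges correctly", {
  part1 <- structure(list(1:4), class = "feature_partition")
  r1 <- build_rotation_matrix(list(diag(4)), part1)
  expect_equal(r1$rearranged, diag(4))

  set.seed(23)
  part <- partition_features(11, 3, seed = 3)
  blocks <- lapply(lengths(part), function(m) qr.Q(qr(matrix(rnorm(m * m), m))))
  rot <- build_rotation_matrix(blocks, part)
  # off-block entries of the unpermuted form are exactly zero
  sizes <- lengths(part)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  mask <- matrix(TRUE, 11, 11)
  for (j in 1:3) mask[starts[j]:ends[j], starts[j]:ends[j]] <- FALSE
  expect_true(all(rot$matrix[mask] == 0))
  # two independent code paths agree: matrix product vs per-subset projection
  x <- rnorm(11)
  via_matrix <- as.vector(x %*% rot$rearranged)
  manual <- numeric(11)
  for (j in 1:3) manual[part[[j]]] <- as.vector(x[part[[j]]] %*% blocks[[j]])
  expect_equal(via_matrix, manual, tolerance = 1e-12)

  expect_error(build_rotation_matrix(list(diag(3)), part),
               "1 blocks for 3 subsets")
  expect_error(build_rotation_matrix(list(diag(2), diag(2), diag(2)), part),
               "subset")
})

test_that("rof_fit: structure, determinism, memorization of separable data", {
  set.seed(31)
  X <- matrix(rnorm(200 * 20), 200, 20)
  Y <- ifelse(X[, 1] + X[, 2] > 0, 1L, 0L)
  cfg <- rof_config(L = 3, K = 10, seed = 5)
  model <- rof_fit(X, Y, cfg)
  expect_length(model$members, 3)
  expect_identical(model$classes, c(0L, 1L))
  for (m in model$members) {
    expect_identical(dim(m$rotation$rearranged), c(20L, 20L))
  }
  expect_equal(mean(rof_predict(model, X) == Y), 1) # invertible rotations

  Xnew <- matrix(rnorm(50 * 20), 50, 20)
  model2 <- rof_fit(X, Y, cfg)
  expect_identical(rof_predict(model, Xnew), rof_predict(model2, Xnew))

  expect_error(rof_fit(X, rep(1L, 200), cfg), "single class")
  expect_error(rof_fit(X, Y, rof_config(K = 21)), "exceeds")
})

test_that("confidence averaging equals the hand-averaged tree distributions", {
  set.seed(41)
  X <- matrix(rnorm(120 * 12), 120, 12)
  Y <- ifelse(X[, 3] > 0.2, 1L, 0L)
  model <- rof_fit(X, Y, rof_config(L = 4, K = 3, seed = 2))
  Xte <- matrix(rnorm(10 * 12), 10, 12)
  p <- rof_predict_proba(model, Xte)
  hand <- Reduce(`+`, lapply(model$members, function(m) {
    predict_cart_proba(m$tree, rotate_data(m$rotation, Xte))
  })) / length(model$members)
  expect_equal(unname(p), hand, tolerance = 1e-12)
  expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-12)

  # L = 1: the ensemble is the single tree on rotated input
  m1 <- rof_fit(X, Y, rof_config(L = 1, K = 3, seed = 7))
  p1 <- rof_predict_proba(m1, Xte)
  expect_equal(unname(p1),
               predict_cart_proba(m1$members[[1]]$tree,
                                  rotate_data(m1$members[[1]]$rotation, Xte)))
})

test_that("predict is the argmax of predict_proba with first-class ties", {
  set.seed(55)
  X <- matrix(rnorm(150 * 10), 150, 10)
  Y <- ifelse(X[, 1] > 0, 1L, 0L)
  model <- rof_fit(X, Y, rof_config(L = 3, K = 5, seed = 3))
  Xte <- matrix(rnorm(100 * 10), 100, 10)
  p <- rof_predict_proba(model, Xte)
  expect_identical(rof_predict(model, Xte),
                   model$classes[max.col(p, ties.method = "first")])
  expect_error(rof_predict(model, Xte[, 1:9]), "features")

  # tie handling: a hand-built two-member model that always returns 0.5/0.5
  part <- structure(list(1:2), class = "feature_partition")
  rot <- build_rotation_matrix(list(diag(2)), part)
  Xt <- matrix(1, 4, 2)
  tree <- fit_cart(Xt, c(1L, 1L, 2L, 2L), 2) # single 50/50 leaf
  tied <- structure(list(members = list(list(rotation = rot, tree = tree)),
                         classes = c("neg", "pos"),
                         config = rof_config(L = 1, K = 1),
                         n_features = 2L),
                    class = "rotation_forest")
  expect_identical(rof_predict(tied, matrix(0, 3, 2)), rep("neg", 3))
})

test_that("identity rotations reduce the ensemble to a single tree", {
  set.seed(61)
  X <- matrix(rnorm(100 * 6), 100, 6)
  Y <- ifelse(X[, 2] - X[, 4] > 0.3, 1L, 0L)
  part <- structure(list(1:6), class = "feature_partition")
  rot <- build_rotation_matrix(list(diag(6)), part)
  tree <- fit_cart(X, match(Y, c(0L, 1L)), 2)
  model <- structure(list(members = rep(list(list(rotation = rot, tree = tree)), 3),
                          classes = c(0L, 1L),
                          config = rof_config(L = 3, K = 1),
                          n_features = 6L),
                     class = "rotation_forest")
  Xte <- matrix(rnorm(40 * 6), 40, 6)
  single <- c(0L, 1L)[max.col(predict_cart_proba(tree, Xte),
                              ties.method = "first")]
  expect_identical(rof_predict(model, Xte), single)
})

test_that("model archive round-trips predictions exactly", {
  set.seed(71)
  X <- matrix(rnorm(80 * 9), 80, 9)
  Y <- ifelse(X[, 1] * X[, 2] > 0, 1L, 0L)
  model <- rof_fit(X, Y, rof_config(L = 2, K = 3, seed = 11))
  f <- withr::local_tempfile(fileext = ".json")
  rof_save(model, f)
  loaded <- rof_load(f)
  Xte <- matrix(rnorm(30 * 9), 30, 9)
  expect_identical(rof_predict(loaded, Xte), rof_predict(model, Xte))
  expect_equal(rof_predict_proba(loaded, Xte), rof_predict_proba(model, Xte),
               tolerance = 1e-12)
})
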