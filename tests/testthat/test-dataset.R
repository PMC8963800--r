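test_that("pair_features concatenates in order", {
  a <- (1:256) / sum(1:256)
  b <- rev(a)
  v <- pair_features(a, b)
  expect_length(v, 512)
  expect_identical(v[1:256], a)
  expect_identical(v[257:512], b)
  expect_false(identical(pair_features(a, b), pair_features(b, a)))
  expect_error(pair_features(a[1:200], b), "256")
})

test_that("sample_negative_pairs respects exclusions and compartments", {
  prot <- sprintf("p%02d", 1:12)
  pos <- data.frame(id_a = prot[1:4], id_b = prot[5:8])
  neg <- sample_negative_pairs(prot, pos, n_neg = 4, seed = 3)
  expect_identical(nrow(neg), 4L)
  expect_true(all(neg$label == 0L))
  expect_false(any(neg$id_a == neg$id_b))
  key <- function(d) paste(pmin(d$id_a, d$id_b), pmax(d$id_a, d$id_b))
  expect_length(intersect(key(neg), key(pos)), 0)
  expect_identical(sample_negative_pairs(prot, pos, 4, seed = 3), neg)

  comp <- setNames(rep(c("nucleus", "cytosol"), each = 6), prot)
  negc <- sample_negative_pairs(prot, pos, 5, compartments = comp, seed = 1)
  expect_true(all(comp[negc$id_a] != comp[negc$id_b]))

  one_comp <- setNames(rep("nucleus", 3), prot[1:3])
  expect_error(sample_negative_pairs(prot[1:3], NULL, 1,
                                     compartments = one_comp),
               "only 0 eligible")
  expect_error(sample_negative_pairs(prot, pos, 10^4), "eligible")
})

test_that("kfold_split partitions indices into near-equal folds", {
  f <- kfold_split(10, 5, seed = 2)
  expect_identical(lengths(f), rep(2L, 5))
  expect_identical(sort(unlist(f)), 1:10)
  f2 <- kfold_split(11, 5, seed = 2)
  expect_identical(sort(lengths(f2)), c(2L, 2L, 2L, 2L, 3L))
  expect_identical(sort(unlist(f2)), 1:11)
  expect_identical(kfold_split(30, 4, seed = 9), kfold_split(30, 4, seed = 9))
  expect_error(kfold_split(3, 5), "folds")
})

test_that("gen_synthetic_ppi output is well-formed and deterministic", {
  ds <- gen_synthetic_ppi(n_prot = 24, n_pos = 5, n_neg = 5,
                          seq_len_range = c(50, 60), seed = 13)
  expect_length(ds$sequences, 24)
  expect_identical(min_length_filter(ds$sequences), ds$sequences)
  expect_identical(nrow(ds$pairs), 10L)
  expect_identical(sum(ds$pairs$label), 5L)
  expect_false(any(ds$pairs$id_a == ds$pairs$id_b))
  # vertex-disjoint: every protein occurs in at most one pair
  expect_false(any(duplicated(c(ds$pairs$id_a, ds$pairs$id_b))))
  for (p in ds$pssms) {
    expect_identical(nrow(p$scores), 20L)
    expect_identical(ncol(p$scores), nchar(ds$sequences[[p$protein_id]]))
  }
  ds2 <- gen_synthetic_ppi(n_prot = 24, n_pos = 5, n_neg = 5,
                           seq_len_range = c(50, 60), seed = 13)
  expect_identical(lapply(ds$pssms, `[[`, "scores"),
                   lapply(ds2$pssms, `[[`, "scores"))
  expect_identical(ds$pairs, ds2$pairs)

  expect_error(gen_synthetic_ppi(4, 10, 10), "infeasible")
  expect_error(gen_synthetic_ppi(100, 5, 5, seq_len_range = c(30, 60)),
               "minimum-length")
})

test_that("interaction dataset assembly checks descriptors and shapes", {
  ds <- gen_synthetic_ppi(n_prot = 16, n_pos = 4, n_neg = 4,
                          seq_len_range = c(50, 55), seed = 3)
  idt <- synthetic_interaction_dataset(ds)
  expect_identical(dim(idt$X), c(8L, 512L))
  expect_identical(idt$Y, idt$pairs$label)
  # first half of a row is the first protein's histogram
  D <- descriptor_matrix(ds$pssms)
  expect_equal(idt$X[1, 1:256], unname(D[idt$pairs$id_a[1], ]))

  expect_error(build_interaction_dataset(
    data.frame(id_a = "a", id_b = "zzz", label = 1),
    D), "zzz")
  expect_error(build_interaction_dataset(
    data.frame(id_a = "a", id_b = "a", label = 1), D), "self-pairs")
})

test_that("pairs and compartments TSV round-trip with comments/header", {
  f <- withr::local_tempfile(fileext = ".tsv")
  pairs <- data.frame(id_a = c("p1", "p2"), id_b = c("p3", "p4"),
                      label = c(1L, 0L), stringsAsFactors = FALSE)
  write_pairs_tsv(pairs, f)
  expect_identical(read_pairs_tsv(f), pairs)
  writeLines(c("# a comment", "p9\tp8\t1"), f)
  expect_identical(read_pairs_tsv(f)$id_a, "p9")
  writeLines(c("p1\tp2\t7"), f)
  expect_error(read_pairs_tsv(f), "0 or 1")

  writeLines(c("id\tcompartment", "# note", "p1\tnucleus", "p2\tcytosol"), f)
  comp <- read_compartments_tsv(f)
  expect_identical(comp, setNames(c("nucleus", "cytosol"), c("p1", "p2")))
})

test_that("synthetic dataset directory export is complete and parseable", {
  ds <- gen_synthetic_ppi(n_prot = 12, n_pos = 3, n_neg = 3,
                          seq_len_range = c(50, 55), seed = 8)
  d <- withr::local_tempdir()
  write_synthetic_dataset(ds, d)
  expect_true(file.exists(file.path(d, "proteins.fasta")))
  expect_true(file.exists(file.path(d, "pairs.tsv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  seqs <- read_fasta(file.path(d, "proteins.fasta"))
  expect_identical(seqs, ds$sequences)
  p1 <- parse_psiblast_pssm(file.path(d, "pssm", "prot0001.pssm"))
  expect_equal(unname(p1$scores), unname(ds$pssms[["prot0001"]]$scores),
               tolerance = 1e-3) # scores serialized to 3 decimals
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_identical(man$seed, 8L)
})

test_that("gen_rotated_gaussian is balanced, oblique and deterministic", {
  d <- gen_rotated_gaussian(N = 400, n = 20, seed = 5)
  expect_identical(dim(d$X), c(400L, 20L))
  expect_identical(sum(d$Y), 200L)
  expect_identical(gen_rotated_gaussian(N = 400, n = 20, seed = 5)$X, d$X)
  # class means differ by ~separation along some direction
  gap <- colMeans(d$X[d$Y == 1, ]) - colMeans(d$X[d$Y == 0, ])
  expect_equal(sqrt(sum(gap^2)), 3, tolerance = 0.35)
})
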