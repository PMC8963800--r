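# Labeled protein-pair datasets: pair features, compartment-aware negative
# sampling, fold splits, TSV interchange, and a fully synthetic PPI
# benchmark generator so the whole pipeline is testable offline.

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Pair feature vector from two protein descriptors
#'
#' Concatenation `[a || b]` in the given order (so the map is
#' order-sensitive), yielding the 512-dimensional classifier input.
#'
#' @param desc_a,desc_b `loop_descriptor` objects or bare length-256
#'   numeric vectors.
#' @return Numeric vector of length 512.
#' @export
pair_features <- function(desc_a, desc_b) {
  a <- if (inherits(desc_a, "loop_descriptor")) desc_a$histogram else as.numeric(desc_a)
  b <- if (inherits(desc_b, "loop_descriptor")) desc_b$histogram else as.numeric(desc_b)
  if (length(a) != 256L || length(b) != 256L) {
    data_error("descriptors must have length 256, got ",
               length(a), " and ", length(b))
  }
  c(a, b)
}

#' Assemble a labeled interaction dataset
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `label` (1 =
#'   interacting, 0 = non-interacting).
#' @param descriptors Matrix from [descriptor_matrix] / [read_descriptors]
#'   (rownames = protein ids, 256 columns).
#' @param both_orders If TRUE, each pair is additionally included with its
#'   proteins swapped (training augmentation; off by default).
#' @return Object of class `interaction_dataset`: list with `pairs`,
#'   `descriptors`, `X` (N x 512) and `Y` (integer labels).
#' @export
build_interaction_dataset <- function(pairs, descriptors, both_orders = FALSE) {
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)))
  pairs <- data.frame(id_a = as.character(pairs$id_a),
                      id_b = as.character(pairs$id_b),
                      label = as.integer(pairs$label),
                      stringsAsFactors = FALSE)
  if (any(pairs$id_a == pairs$id_b)) {
    data_error("self-pairs are not allowed")
  }
  if (both_orders) {
    pairs <- rbind(pairs, data.frame(id_a = pairs$id_b, id_b = pairs$id_a,
                                     label = pairs$label))
  }
  need <- unique(c(pairs$id_a, pairs$id_b))
  missing <- setdiff(need, rownames(descriptors))
  if (length(missing)) {
    data_error("no descriptor for protein id(s): ",
               paste(missing, collapse = ", "))
  }
  X <- cbind(descriptors[pairs$id_a, , drop = FALSE],
             descriptors[pairs$id_b, , drop = FALSE])
  dimnames(X) <- NULL
  structure(list(pairs = pairs, descriptors = descriptors,
                 X = X, Y = pairs$label),
            class = "interaction_dataset")
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf("Interaction dataset: %d pairs (%d positive), %d proteins, %d features\n",
              nrow(x$pairs), sum(x$Y == 1L), nrow(x$descriptors), ncol(x$X)))
  invisible(x)
}

#' Sample non-interacting protein pairs
#'
#' Draws `n_neg` distinct unordered pairs that are not in the positive set
#' and are never self-pairs. When subcellular-compartment labels are given,
#' only pairs whose proteins live in different compartments are eligible
#' (the standard negative-set construction when confirmed non-interactions
#' are unavailable).
#'
#' @param proteins Character vector of protein ids.
#' @param positives Data frame with `id_a`, `id_b` (or 2-column matrix) of
#'   known interacting pairs, treated as unordered.
#' @param n_neg Number of negative pairs to draw.
#' @param compartments Optional named character vector mapping protein id
#'   to compartment label.
#' @param seed Integer seed; the draw is deterministic given it.
#' @return Data frame `id_a`, `id_b`, `label = 0`.
#' @export
sample_negative_pairs <- function(proteins, positives, n_neg,
                                  compartments = NULL, seed = 1L) {
  proteins <- unique(as.character(proteins))
  if (length(proteins) < 2L) data_error("need at least 2 proteins")
  pos_key <- character(0)
  if (!is.null(positives) && NROW(positives) > 0) {
    pa <- as.character(positives[[1]])
    pb <- as.character(positives[[2]])
    pos_key <- pair_key(pa, pb)
  }
  cmb <- utils::combn(proteins, 2L)
  a <- cmb[1L, ]
  b <- cmb[2L, ]
  keep <- !(pair_key(a, b) %in% pos_key)
  if (!is.null(compartments)) {
    ca <- compartments[a]
    cb <- compartments[b]
    keep <- keep & !is.na(ca) & !is.na(cb) & ca != cb
  }
  a <- a[keep]
  b <- b[keep]
  if (n_neg > length(a)) {
    data_error("requested ", n_neg, " negative pairs but only ", length(a),
               " eligible pairs exist")
  }
  pick <- with_seed(seed, sample.int(length(a), n_neg))
  data.frame(id_a = a[pick], id_b = b[pick], label = 0L,
             stringsAsFactors = FALSE)
}

#' Split N indices into k cross-validation folds
#'
#' A seeded random permutation of `1:N` cut into k nearly equal disjoint
#' groups (sizes differ by at most 1).
#'
#' @param N Number of instances.
#' @param k Number of folds, `2 <= k <= N`.
#' @param seed Integer seed.
#' @return Object of class `fold_split`: list of k integer index vectors.
#' @export
kfold_split <- function(N, k, seed = 1L) {
  N <- as.integer(N)
  k <- as.integer(k)
  if (k < 2L) data_error("k must be >= 2")
  if (N < k) data_error("cannot split N = ", N, " instances into ", k, " folds")
  perm <- with_seed(seed, sample.int(N))
  sizes <- rep(N %/% k, k)
  extra <- N %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(j) sort(perm[starts[j]:ends[j]]))
  structure(folds, class = "fold_split")
}

# Smooth random 20 x w patch with unit entry standard deviation: white
# noise passed once through a 3 x 3 box filter (replicated borders), so
# neighbouring cells are correlated but the patch keeps enough local
# gradient to imprint a texture. The caller scales it by the amplitude.
smooth_patch <- function(w = 9L) {
  p <- matrix(stats::rnorm(20L * w), 20L, w)
  box <- function(m) {
    nr <- nrow(m)
    nc <- ncol(m)
    pad <- m[c(1L, 1:nr, nr), c(1L, 1:nc, nc), drop = FALSE]
    out <- matrix(0, nr, nc)
    for (dr in 0:2) for (dc in 0:2) {
      out <- out + pad[dr + 1:nr, dc + 1:nc, drop = FALSE]
    }
    out / 9
  }
  p <- box(p)
  p / stats::sd(p)
}

add_patch <- function(scores, patch, offset) {
  w <- ncol(patch)
  cols <- offset:(offset + w - 1L)
  scores[, cols] <- scores[, cols] + patch
  scores
}

#' Generate a synthetic PPI benchmark dataset
#'
#' Generates random protein sequences, pseudo-PSSMs, and labeled pairs in
#' which local PSSM texture carries a class-dependent signal. One smooth
#' 20 x `motif_width` additive motif patch (the "interface motif") is
#' drawn per dataset; every positive pair shares it, inserted at a
#' protein-specific random column offset in both partners' profiles.
#' Every other protein receives its own independent random patch of the
#' same amplitude, so the classes differ only in *which* texture their
#' profiles carry, never in whether they carry one. Pairs are
#' vertex-disjoint (each protein occurs in exactly one pair, so `n_prot`
#' must be at least `2 * (n_pos + n_neg)`): protein reuse would either
#' make pair labels contradict the per-protein features (a protein cannot
#' both carry and not carry the motif) or let a classifier recognise
#' individual proteins across folds, which at `signal_strength = 0` would
#' fake a signal out of pure identity memorisation. With
#' `signal_strength = 0` all patches vanish and the two classes are
#' statistically identical. Fully deterministic given `seed`.
#'
#' @param n_prot Number of proteins (>= 4).
#' @param n_pos,n_neg Number of positive / negative pairs.
#' @param seq_len_range Length-2 integer vector `(min, max)` of sequence
#'   lengths; the minimum must be >= 50 so the generated set passes the
#'   standard minimum-length filter unchanged.
#' @param signal_strength Amplitude of the motif patches (in PSSM log-odds
#'   units; generator noise has `noise_sd` sd).
#' @param noise_sd Pseudo-PSSM noise standard deviation.
#' @param motif_width Width (columns) of the motif patches.
#' @param seed Integer seed.
#' @return Object of class `synthetic_ppi`: list with `sequences` (named
#'   character), `pssms` (named list of [pssm]), `pairs` (data frame
#'   `id_a`, `id_b`, `label`) and `params`.
#' @export
gen_synthetic_ppi <- function(n_prot, n_pos, n_neg,
                              seq_len_range = c(50L, 70L),
                              signal_strength = 80, noise_sd = 1,
                              motif_width = 21L, seed = 1L) {
  n_prot <- as.integer(n_prot)
  if (n_prot < 4L) data_error("need n_prot >= 4")
  if (seq_len_range[1] < 50L) {
    data_error("seq_len_range minimum must be >= 50 (minimum-length filter)")
  }
  if (seq_len_range[1] < motif_width + 2L) {
    data_error("sequences too short for the motif width")
  }
  n_pos <- as.integer(n_pos)
  n_neg <- as.integer(n_neg)
  if (n_pos < 1L || n_neg < 1L || 2L * (n_pos + n_neg) > n_prot) {
    data_error("infeasible pair counts: vertex-disjoint pairing needs ",
               "n_prot >= 2 * (n_pos + n_neg) = ", 2L * (n_pos + n_neg),
               ", got n_prot = ", n_prot)
  }
  ids <- sprintf("prot%04d", seq_len(n_prot))
  ids_a <- ids[seq_len(2L * n_pos)] # motif carriers
  ids_b <- ids[(2L * n_pos + 1L):n_prot] # independent patches

  sequences <- with_seed(derive_seed(seed, 1L), {
    lens <- sample(seq.int(seq_len_range[1], seq_len_range[2]), n_prot,
                   replace = TRUE)
    vapply(lens, function(l) paste(sample(AA_ORDER, l, replace = TRUE),
                                   collapse = ""), character(1))
  })
  names(sequences) <- ids

  pssms <- lapply(seq_len(n_prot), function(i) {
    pseudo_pssm(sequences[i], noise_sd = noise_sd,
                seed = derive_seed(seed, 2L, i), protein_id = ids[i])
  })
  names(pssms) <- ids

  # vertex-disjoint pairing: random perfect matching within each pool
  pa <- with_seed(derive_seed(seed, 3L), sample(ids_a))
  pos <- data.frame(id_a = pa[seq_len(n_pos)],
                    id_b = pa[n_pos + seq_len(n_pos)],
                    label = 1L, stringsAsFactors = FALSE)
  pb <- with_seed(derive_seed(seed, 4L), sample(ids_b))
  neg <- data.frame(id_a = pb[seq_len(n_neg)],
                    id_b = pb[n_neg + seq_len(n_neg)],
                    label = 0L, stringsAsFactors = FALSE)

  # class-dependent texture signal: one patch per protein
  motif <- with_seed(derive_seed(seed, 5L),
                     smooth_patch(motif_width)) * signal_strength
  rand_offset <- function(id) sample.int(ncol(pssms[[id]]$scores) - motif_width + 1L, 1L)
  pssms <- with_seed(derive_seed(seed, 6L), {
    for (id in ids_a) {
      pssms[[id]]$scores <- add_patch(pssms[[id]]$scores, motif,
                                      rand_offset(id))
    }
    for (id in ids_b) {
      patch <- smooth_patch(motif_width) * signal_strength
      pssms[[id]]$scores <- add_patch(pssms[[id]]$scores, patch,
                                      rand_offset(id))
    }
    pssms
  })

  structure(list(sequences = sequences, pssms = pssms,
                 pairs = rbind(pos, neg),
                 params = list(n_prot = n_prot, n_pos = n_pos, n_neg = n_neg,
                               seq_len_range = as.integer(seq_len_range),
                               signal_strength = signal_strength,
                               noise_sd = noise_sd,
                               motif_width = as.integer(motif_width),
                               seed = as.integer(seed))),
            class = "synthetic_ppi")
}

#' @export
print.synthetic_ppi <- function(x, ...) {
  cat(sprintf("Synthetic PPI dataset: %d proteins, %d positive / %d negative pairs (seed %d)\n",
              length(x$sequences), sum(x$pairs$label == 1L),
              sum(x$pairs$label == 0L), x$params$seed))
  invisible(x)
}

#' Build the classifier-ready dataset from a synthetic benchmark
#'
#' Convenience: LOOP descriptors for every generated PSSM plus pair
#' assembly.
#'
#' @param x A [gen_synthetic_ppi] result.
#' @return An `interaction_dataset`.
#' @export
synthetic_interaction_dataset <- function(x) {
  stopifnot(inherits(x, "synthetic_ppi"))
  build_interaction_dataset(x$pairs, descriptor_matrix(x$pssms))
}

#' Rotated-Gaussian binary classification benchmark
#'
#' Two Gaussian classes sharing an anisotropic covariance whose principal
#' axes are a random rotation of the feature axes; the class-mean shift
#' points along an oblique direction (a mix of the leading rotated axes),
#' so no single axis-aligned split separates the classes well. This is the
#' setting where per-subset PCA rotations should help a tree ensemble over
#' a single axis-aligned tree.
#'
#' @param N Number of samples (default 1000, balanced classes).
#' @param n Number of features (default 20).
#' @param separation Distance between the class means (default 3).
#' @param seed Integer seed.
#' @return List with `X` (N x n matrix) and `Y` (0/1 labels).
#' @export
gen_rotated_gaussian <- function(N = 1000L, n = 20L, separation = 3, seed = 1L) {
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
    sds <- seq(3, 0.5, length.out = n)
    y <- rep(c(0L, 1L), length.out = N)
    mu_dir <- as.vector(Q %*% c(rep(0.5, 4), rep(0, n - 4))) # unit length
    Z <- matrix(stats::rnorm(N * n), N) %*% diag(sds) %*% t(Q)
    X <- Z + outer(ifelse(y == 1L, separation / 2, -separation / 2), mu_dir)
    list(X = X, Y = y)
  })
}

# ---- TSV interchange ------------------------------------------------------

#' Read a 3-column interaction list
#'
#' Tab-separated `id_a  id_b  label`; `#` comment lines skipped; a header
#' line is auto-detected (third field non-numeric).
#'
#' @param path Input path.
#' @return Data frame `id_a`, `id_b`, `label`.
#' @export
read_pairs_tsv <- function(path) {
  if (!file.exists(path)) data_error("pairs file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) data_error("pairs file is empty: ", path)
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3])))) {
    lines <- lines[-1]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    data_error("malformed pairs line(s): ", paste(bad, collapse = ", "))
  }
  lab <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3L)))
  if (any(is.na(lab)) || !all(lab %in% c(0L, 1L))) {
    data_error("pair labels must be 0 or 1 in ", path)
  }
  data.frame(id_a = vapply(parts, `[`, character(1), 1L),
             id_b = vapply(parts, `[`, character(1), 2L),
             label = lab, stringsAsFactors = FALSE)
}

#' Write a 3-column interaction list
#'
#' @param pairs Data frame `id_a`, `id_b`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs[, c("id_a", "id_b", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read per-protein compartment labels
#'
#' Tab-separated `id  compartment`, optional header, `#` comments.
#'
#' @param path Input path.
#' @return Named character vector (names = protein ids).
#' @export
read_compartments_tsv <- function(path) {
  if (!file.exists(path)) data_error("compartments file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && identical(tolower(parts[[1]][1]), "id")) {
    parts <- parts[-1]
  }
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    data_error("malformed compartment line(s): ", paste(bad, collapse = ", "))
  }
  stats::setNames(vapply(parts, `[`, character(1), 2L),
                  vapply(parts, `[`, character(1), 1L))
}

#' Write a synthetic dataset as a directory
#'
#' Writes `proteins.fasta`, one PSI-BLAST-style ASCII PSSM per protein
#' under `pssm/`, `pairs.tsv`, and `manifest.json` recording the generator
#' parameters (including the seed).
#'
#' @param x A [gen_synthetic_ppi] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_ppi"))
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(x$sequences, file.path(dir, "proteins.fasta"))
  for (id in names(x$pssms)) {
    write_psiblast_pssm(x$pssms[[id]], file.path(dir, "pssm", paste0(id, ".pssm")),
                        residues = x$sequences[[id]])
  }
  write_pairs_tsv(x$pairs, file.path(dir, "pairs.tsv"))
  jsonlite::write_json(c(list(format = "synthetic_ppi/1"), x$params),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
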