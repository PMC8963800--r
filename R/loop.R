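# LOOP (local optimal-oriented pattern) texture descriptor over a PSSM.
#
# Each interior cell of the 20 x M profile gets an 8-bit code: the eight
# ring neighbours are thresholded against the center (LBP-style), and each
# neighbour's bit weight 2^w is assigned by the rank of the magnitude of
# its Kirsch directional edge response (LDP-style). The protein descriptor
# is the 256-bin histogram of codes, normalized to frequencies.
#
# Neighbour ring convention (fixed, documented): n = 0..7 enumerates
# (row, col) offsets clockwise from the top-left:
#   (-1,-1), (-1,0), (-1,+1), (0,+1), (+1,+1), (+1,0), (+1,-1), (0,-1).
# Mask n places its three +5 weights on neighbour n and its two
# ring-adjacent neighbours, -3 on the remaining five, 0 at the center, so
# every mask sums to zero and mask n is the 45-degree rotation of mask n-1.

loop_ring_offsets <- function() {
  matrix(c(-1L, -1L,
           -1L,  0L,
           -1L,  1L,
            0L,  1L,
            1L,  1L,
            1L,  0L,
            1L, -1L,
            0L, -1L),
         ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("drow", "dcol")))
}

# 8 x 8 weight table: W[p, n] = weight of ring position p-1 in mask n-1
kirsch_weight_table <- function() {
  W <- matrix(-3, 8L, 8L)
  for (n in 0:7) {
    for (d in c(-1L, 0L, 1L)) {
      W[((n + d) %% 8L) + 1L, n + 1L] <- 5
    }
  }
  W
}

#' The eight Kirsch directional edge masks
#'
#' @return List of eight 3 x 3 integer matrices; mask n (1-based element
#'   n+1) responds to direction n of the neighbour ring. Each mask has
#'   three `5` entries, five `-3` entries, `0` at the center, and sums to
#'   zero.
#' @export
kirsch_masks <- function() {
  off <- loop_ring_offsets()
  W <- kirsch_weight_table()
  lapply(1:8, function(n) {
    m <- matrix(0, 3L, 3L)
    m[cbind(off[, 1] + 2L, off[, 2] + 2L)] <- W[, n]
    m
  })
}

#' Kirsch responses of a 3 x 3 patch
#'
#' @param patch A 3 x 3 numeric matrix.
#' @return Numeric vector of the eight mask responses (center weight is 0,
#'   so the center intensity never contributes).
#' @export
kirsch_responses <- function(patch) {
  patch <- as.matrix(patch)
  if (!all(dim(patch) == c(3L, 3L))) {
    data_error("patch must be 3 x 3, got ", nrow(patch), " x ", ncol(patch))
  }
  off <- loop_ring_offsets()
  ring <- patch[cbind(off[, 1] + 2L, off[, 2] + 2L)]
  as.vector(ring %*% kirsch_weight_table())
}

#' Bit-weight exponents from response magnitudes
#'
#' The direction whose response has the largest magnitude receives exponent
#' 7, the next 6, down to 0; ties are broken by the smaller direction index
#' taking the larger exponent.
#'
#' @param responses Numeric vector of eight Kirsch responses.
#' @return Integer vector: a permutation of `0:7`.
#' @export
rank_exponents <- function(responses) {
  if (length(responses) != 8L) {
    data_error("need exactly 8 responses, got ", length(responses))
  }
  as.integer(8L - rank(-abs(responses), ties.method = "first"))
}

#' LOOP code of a 3 x 3 patch
#'
#' `sum_n s(i_n - i_c) * 2^w_n` where `s(x) = 1` iff `x >= 0`, `i_c` is the
#' center intensity, `i_n` the ring intensities, and `w_n` the
#' [rank_exponents] of the patch's [kirsch_responses].
#'
#' @param patch A 3 x 3 numeric matrix.
#' @return Integer in `[0, 255]`.
#' @export
loop_code <- function(patch) {
  patch <- as.matrix(patch)
  if (!all(dim(patch) == c(3L, 3L))) {
    data_error("patch must be 3 x 3, got ", nrow(patch), " x ", ncol(patch))
  }
  w <- rank_exponents(kirsch_responses(patch))
  off <- loop_ring_offsets()
  ring <- patch[cbind(off[, 1] + 2L, off[, 2] + 2L)]
  s <- ring >= patch[2L, 2L]
  as.integer(sum(2^w[s]))
}

# Vectorized LOOP codes over all interior cells of a numeric matrix.
loop_codes_matrix <- function(S) {
  nr <- nrow(S)
  nc <- ncol(S)
  if (nr < 3L || nc < 3L) {
    data_error("sequence too short for texture window (need a 3 x 3 ",
               "neighbourhood; matrix is ", nr, " x ", nc, ")")
  }
  ri <- 2:(nr - 1L)
  ci <- 2:(nc - 1L)
  center <- as.vector(S[ri, ci, drop = FALSE])
  off <- loop_ring_offsets()
  ncell <- length(center)
  NBR <- matrix(0, ncell, 8L)
  for (p in 1:8) {
    NBR[, p] <- as.vector(S[ri + off[p, 1], ci + off[p, 2], drop = FALSE])
  }
  RESP <- abs(NBR %*% kirsch_weight_table())
  # per-cell exponents: rank magnitudes descending, first-index tie-break
  OM <- matrix(0L, ncell, 8L)
  for (i in seq_len(ncell)) {
    OM[i, ] <- 8L - rank(-RESP[i, ], ties.method = "first")
  }
  SB <- NBR >= center
  codes <- as.integer(rowSums(SB * 2^OM))
  matrix(codes, nrow = length(ri), ncol = length(ci))
}

#' LOOP code field of a PSSM
#'
#' @param x A [pssm] (or bare 20 x M matrix) with `M >= 3`.
#' @return Integer matrix of LOOP codes over the interior cells
#'   (18 x (M - 2)); every code lies in `[0, 255]`. Border cells have no
#'   full 3 x 3 neighbourhood and are skipped, never padded.
#' @export
loop_codes <- function(x) {
  S <- if (inherits(x, "pssm")) x$scores else as.matrix(x)
  loop_codes_matrix(S)
}

#' LOOP descriptor (256-bin histogram) of a PSSM
#'
#' Computes the LOOP code at every interior cell and bins the codes into a
#' 256-component frequency histogram summing to 1.
#'
#' @param x A [pssm] (or bare 20 x M matrix) with `M >= 3`.
#' @param protein_id Identifier; defaults to the PSSM's.
#' @return An object of class `loop_descriptor`: list with `protein_id` and
#'   `histogram` (length-256 numeric, non-negative, sums to 1; component k
#'   is the frequency of code k-1).
#' @export
loop_histogram <- function(x, protein_id = NULL) {
  if (is.null(protein_id)) {
    protein_id <- if (inherits(x, "pssm")) x$protein_id else "protein"
  }
  codes <- loop_codes(x)
  counts <- tabulate(as.vector(codes) + 1L, nbins = 256L)
  structure(list(protein_id = as.character(protein_id),
                 histogram = counts / sum(counts)),
            class = "loop_descriptor")
}

#' @export
print.loop_descriptor <- function(x, ...) {
  nz <- sum(x$histogram > 0)
  cat(sprintf("LOOP descriptor '%s': 256 bins, %d occupied\n",
              x$protein_id, nz))
  invisible(x)
}

#' LOOP descriptors for a set of PSSMs
#'
#' @param pssms List of [pssm] objects (names are ignored; protein ids come
#'   from the objects).
#' @return Numeric matrix, one row per protein (rownames = protein ids),
#'   256 columns `b0..b255`.
#' @export
descriptor_matrix <- function(pssms) {
  descs <- lapply(pssms, loop_histogram)
  m <- do.call(rbind, lapply(descs, `[[`, "histogram"))
  rownames(m) <- vapply(descs, `[[`, character(1), "protein_id")
  colnames(m) <- sprintf("b%d", 0:255)
  m
}

#' Write descriptors to a tab-separated file
#'
#' One row per protein: id followed by the 256 frequencies, with a header
#' line `id b0 .. b255`. Deterministic column order.
#'
#' @param descriptors Matrix from [descriptor_matrix] (or a single
#'   `loop_descriptor`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  if (inherits(descriptors, "loop_descriptor")) {
    m <- matrix(descriptors$histogram, nrow = 1,
                dimnames = list(descriptors$protein_id, sprintf("b%d", 0:255)))
    descriptors <- m
  }
  df <- data.frame(id = rownames(descriptors), descriptors,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor table written by [write_descriptors]
#'
#' @param path Input path.
#' @return Numeric matrix with protein-id rownames and 256 columns.
#' @export
read_descriptors <- function(path) {
  if (!file.exists(path)) data_error("descriptor file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 257L) {
    data_error("descriptor table must have 257 columns (id + 256), got ",
               ncol(df))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
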