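# Sequence and PSSM input/output.
#
# A PSSM here is always a 20 x M real matrix: 20 amino-acid rows in the
# fixed PSI-BLAST order (AA_ORDER), one column per sequence position.

#' Construct a PSSM object
#'
#' @param scores Numeric matrix with exactly 20 rows (amino-acid order
#'   `ARNDCQEGHILKMFPSTWYV`) and `M >= 1` columns, all entries finite.
#' @param protein_id Protein identifier.
#' @param source Either `"psiblast"` (parsed from PSI-BLAST output) or
#'   `"pseudo"` (generated in silico).
#' @return An object of class `pssm`: a list with elements `protein_id`,
#'   `scores` and `source`.
#' @export
pssm <- function(scores, protein_id = "protein", source = c("pseudo", "psiblast")) {
  source <- match.arg(source)
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (nrow(scores) != 20L) {
    data_error("a PSSM must have exactly 20 rows, got ", nrow(scores))
  }
  if (ncol(scores) < 1L) {
    data_error("a PSSM must have at least one column")
  }
  if (!all(is.finite(scores))) {
    data_error("PSSM for '", protein_id, "' contains non-finite entries")
  }
  rownames(scores) <- AA_ORDER
  structure(list(protein_id = as.character(protein_id),
                 scores = scores, source = source),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM '%s' (%s): 20 x %d\n", x$protein_id, x$source,
              ncol(x$scores)))
  invisible(x)
}

#' @export
dim.pssm <- function(x) dim(x$scores)

normalize_residues <- function(residues, id = "?") {
  r <- toupper(residues)
  letters <- strsplit(r, "", fixed = TRUE)[[1]]
  bad <- !(letters %in% AA_ORDER)
  if (any(bad)) {
    warning(sprintf("sequence '%s': %d non-canonical residue(s) (%s) mapped to '%s'",
                    id, sum(bad),
                    paste(unique(letters[bad]), collapse = ","), AA_UNKNOWN),
            call. = FALSE)
    letters[bad] <- AA_UNKNOWN
  }
  paste(letters, collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' Residues are uppercased; letters outside the canonical 20-letter alphabet
#' (e.g. B, Z, U, O, J, *) are mapped to `X` with a warning. An empty file
#' yields an empty vector.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids, order
#'   as in the file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    data_error("FASTA file not found: ", path)
  }
  if (file.size(path) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    data_error("FASTA record(s) with empty sequence: ",
               paste(ids[empty], collapse = ", "))
  }
  seqs <- vapply(seq_along(seqs),
                 function(i) normalize_residues(seqs[i], ids[i]),
                 character(1))
  stats::setNames(seqs, ids)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the output of `psiblast -out_ascii_pssm`. Only the first 20 numeric
#' columns of each position row (the log-odds scores) are used; the file's
#' position-major layout is transposed into the package's 20 x M convention.
#'
#' @param path Path to the ASCII PSSM file.
#' @param protein_id Identifier to attach; defaults to the file name without
#'   extension.
#' @return A [pssm] with `source = "psiblast"`.
#' @export
parse_psiblast_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) {
    data_error("PSSM file not found: ", path)
  }
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  is_row <- grepl("^\\s*[0-9]+\\s+[A-Za-z*]\\s", lines)
  rows <- which(is_row)
  if (length(rows) == 0L) {
    data_error("no position rows found in PSSM file: ", path)
  }
  M <- length(rows)
  scores <- matrix(NA_real_, nrow = 20L, ncol = M)
  residues <- character(M)
  for (j in seq_len(M)) {
    ln <- rows[j]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) < 22L) {
      data_error("truncated PSSM row at line ", ln, " of ", path,
                 " (", length(fields), " fields, need >= 22)")
    }
    vals <- suppressWarnings(as.numeric(fields[3:22]))
    if (any(is.na(vals))) {
      data_error("non-numeric score cell at line ", ln, " of ", path)
    }
    residues[j] <- toupper(fields[2])
    scores[, j] <- vals
  }
  out <- pssm(scores, protein_id = protein_id, source = "psiblast")
  attr(out, "residues") <- paste(residues, collapse = "")
  out
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Produces a file that [parse_psiblast_pssm] reads back; integer scores
#' round-trip exactly. Used for fixtures and synthetic dataset directories.
#'
#' @param x A [pssm].
#' @param path Output path.
#' @param residues Optional residue string of length M for the second
#'   column; defaults to the `residues` attribute or all-`X`.
#' @return `path`, invisibly.
#' @export
write_psiblast_pssm <- function(x, path, residues = NULL) {
  stopifnot(inherits(x, "pssm"))
  M <- ncol(x$scores)
  if (is.null(residues)) {
    residues <- attr(x, "residues")
  }
  if (is.null(residues)) {
    residues <- strrep(AA_UNKNOWN, M)
  }
  res <- strsplit(residues, "", fixed = TRUE)[[1]]
  if (length(res) != M) {
    data_error("residue string length ", length(res),
               " does not match PSSM width ", M)
  }
  hdr <- c("",
           paste("Last position-specific scoring matrix computed, weighted",
                 "observed percentages rounded down, information per position,",
                 "and relative weight of gapless real matches to pseudocounts"),
           paste0("           ",
                  paste(sprintf("%3s", c(AA_ORDER, AA_ORDER)), collapse = " ")))
  fmt_score <- function(v) {
    if (all(v == round(v))) sprintf("%4d", as.integer(round(v)))
    else sprintf("%7.3f", v)
  }
  body <- vapply(seq_len(M), function(j) {
    paste0(sprintf("%5d %s ", j, res[j]),
           paste(fmt_score(x$scores[, j]), collapse = " "),
           "  ", paste(sprintf("%4d", rep(0L, 20L)), collapse = " "),
           "  0.00 0.00")
  }, character(1))
  writeLines(c(hdr, body, "", "                      K         Lambda"), path)
  invisible(path)
}

#' BLOSUM62 restricted to the 20 canonical amino acids
#'
#' Returns the BLOSUM62 substitution matrix shipped with Biostrings, subset
#' and ordered to the fixed `ARNDCQEGHILKMFPSTWYV` convention. Used as the
#' default base profile for [pseudo_pssm].
#'
#' @return A 20 x 20 numeric matrix.
#' @export
blosum62_profile <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_ORDER, AA_ORDER]
  storage.mode(m) <- "double"
  m
}

#' Read a plain-text 20 x 20 substitution matrix
#'
#' Accepts the standard BLOSUM-style layout: optional `#` comment lines, a
#' header row of amino-acid letters, then one row per amino acid. Rows and
#' columns are reordered to the package convention.
#'
#' @param path Path to the matrix file.
#' @return A 20 x 20 numeric matrix in `AA_ORDER` order.
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) data_error("substitution matrix not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labs <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) suppressWarnings(as.numeric(r[-1][seq_along(header)])),
                   numeric(length(header))))
  if (any(is.na(vals))) data_error("non-numeric cell in substitution matrix ", path)
  dimnames(vals) <- list(labs, header)
  missing <- setdiff(AA_ORDER, intersect(labs, header))
  if (length(missing)) {
    data_error("substitution matrix lacks amino acid(s): ",
               paste(missing, collapse = ","))
  }
  m <- vals[AA_ORDER, AA_ORDER]
  storage.mode(m) <- "double"
  m
}

#' Generate a deterministic pseudo-PSSM for a sequence
#'
#' Offline stand-in for PSI-BLAST: column j is the base-profile row of
#' residue j plus i.i.d. Gaussian noise. The placeholder residue `X` (any
#' non-canonical letter after normalization) receives the average of the 20
#' base-profile rows. Deterministic given `(seq, base_profile, noise_sd,
#' seed)`.
#'
#' @param seq Character string of residues, or a length-1 named character
#'   vector (the name becomes the protein id).
#' @param base_profile 20 x 20 substitution matrix in `AA_ORDER` order;
#'   default [blosum62_profile()].
#' @param noise_sd Non-negative standard deviation of the additive noise.
#' @param seed Integer seed.
#' @param protein_id Identifier; defaults to the name of `seq` or "protein".
#' @return A [pssm] with `source = "pseudo"`.
#' @export
pseudo_pssm <- function(seq, base_profile = blosum62_profile(),
                        noise_sd = 1, seed = 1L, protein_id = NULL) {
  if (is.null(protein_id)) {
    protein_id <- if (!is.null(names(seq))) names(seq)[1] else "protein"
  }
  stopifnot(noise_sd >= 0)
  residues <- normalize_residues(seq[[1]], protein_id)
  letters <- strsplit(residues, "", fixed = TRUE)[[1]]
  M <- length(letters)
  if (M == 0L) data_error("empty sequence for '", protein_id, "'")
  base_profile <- as.matrix(base_profile)
  if (!all(dim(base_profile) == c(20L, 20L))) {
    data_error("base_profile must be 20 x 20")
  }
  rownames(base_profile) <- AA_ORDER
  placeholder <- colMeans(base_profile)
  cols <- matrix(0, nrow = 20L, ncol = M)
  known <- letters %in% AA_ORDER
  if (any(known)) cols[, known] <- t(base_profile[letters[known], , drop = FALSE])
  if (any(!known)) cols[, !known] <- placeholder
  noise <- with_seed(seed, matrix(stats::rnorm(20L * M, sd = noise_sd), 20L, M))
  out <- pssm(cols + noise, protein_id = protein_id, source = "pseudo")
  attr(out, "residues") <- residues
  out
}

#' Drop sequences shorter than a minimum length
#'
#' Proteins with fewer than `min_len` residues are removed (the standard
#' quality filter for PPI gold-standard sets); order is preserved.
#'
#' @param sequences Named character vector of sequences.
#' @param min_len Minimum length to keep (default 50).
#' @return The filtered named character vector.
#' @export
min_length_filter <- function(sequences, min_len = 50L) {
  sequences[nchar(sequences) >= min_len]
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
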