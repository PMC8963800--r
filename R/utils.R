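#' @keywords internal
#' @importFrom utils head tail combn read.table write.table data
#' @importFrom stats rnorm prcomp sd setNames
"_PACKAGE"

# Canonical amino-acid row order of PSI-BLAST profiles; fixed coordinate
# convention for the 20-row texture grid throughout the package.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Placeholder letter that every non-canonical residue code collapses to.
AA_UNKNOWN <- "X"

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded helpers never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible sub-seed from a master seed and indices
#'
#' Mixes the master seed with any number of integer tags through a
#' multiplicative-congruential hash so that ensemble members, folds and
#' per-protein draws get distinct but reproducible streams. The result is
#' always a valid 32-bit R seed.
#'
#' @param seed Master integer seed.
#' @param ... Integer tags (member index, fold index, ...).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (p %% m) + 1) %% m
  }
  as.integer(h)
}

# stop() with a class so the CLI can map data errors to exit code 2
data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("plantppi_data_error", "error")))
}
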