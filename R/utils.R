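#' @keywords internal
"_PACKAGE"

## Seed handling ---------------------------------------------------------

#' Derive a stream of child seeds from a master seed
#'
#' All stochastic stages draw their per-run seeds from the master seed through
#' this helper, so the whole pipeline is a pure function of (inputs, config,
#' master seed). Seeds stay within the 32-bit integer range.
#'
#' @param master_seed single integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get_seed_state()
  on.exit(restore_seed_state(old), add = TRUE)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_seed_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Evaluate an expression with a local RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never perturbs
#' user-level randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get_seed_state()
  on.exit(restore_seed_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Vector/matrix helpers --------------------------------------------------

#' Scale matrix columns to unit L2 norm
#' @keywords internal
unit_norm_columns <- function(m) {
  nrm <- sqrt(colSums(m^2))
  if (any(nrm == 0)) stop("cannot normalize a zero column")
  sweep(m, 2L, nrm, "/")
}

#' Fix the sign of each column so its largest-magnitude entry is positive
#'
#' A deterministic, scale-free orientation convention for gene-weight vectors:
#' sign indeterminacy of ICA is resolved by requiring the dominant gene weight
#' of each component to be positive.
#' @keywords internal
fix_column_signs <- function(m) {
  for (j in seq_len(ncol(m))) {
    i <- which.max(abs(m[, j]))
    if (m[i, j] < 0) m[, j] <- -m[, j]
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
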