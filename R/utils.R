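# Internal helpers shared across modules.

#' Derive a reproducible child seed from a global seed
#'
#' All stochastic stages draw their randomness from one global seed through
#' named substreams, so that e.g. the permutation null and the Dirichlet
#' resampling stay decoupled: changing the number of draws never perturbs
#' the permutations.
#'
#' @param seed integer global seed.
#' @param stream character substream label.
#' @param index integer index within the substream (e.g. draw number).
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @keywords internal
derive_seed <- function(seed, stream, index = 0L) {
  # cheap deterministic hash; modulus keeps the result a valid 32-bit seed
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}

# Run `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopifnot_square <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
}

check_symmetric <- function(m, tol = 1e-8, name = deparse(substitute(m))) {
  stopifnot_square(m, name)
  if (max(abs(m - t(m))) > tol)
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
}

# Upper-triangle (i < j) index pairs of a K x K matrix, as a 2-column matrix.
upper_pairs <- function(K) {
  idx <- which(upper.tri(diag(K)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
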