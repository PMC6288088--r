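# Metric multidimensional scaling of TINA dissimilarities by SMACOF
# stress majorization.

#' Configuration of the SMACOF ordination
#'
#' The defaults are the analysis settings (200 random initializations,
#' up to 20,000 iterations each, convergence when the raw stress decrease
#' per iteration falls below 1e-8).  Tests and quick looks typically reduce
#' `n_init` and `max_iter`.
#'
#' @param n_components embedding dimension (default 2).
#' @param n_init number of random starts; the best (lowest-stress) result
#'   is returned.
#' @param max_iter iteration cap per start.
#' @param eps convergence threshold on the per-iteration decrease of raw
#'   stress.
#' @param seed integer seed for the random starts.
#' @return a list of class `"mds_config"`.
#' @export
mds_config <- function(n_components = 2L, n_init = 200L, max_iter = 20000L,
                       eps = 1e-8, seed = 1L) {
  if (n_init < 1) stop("'n_init' must be >= 1", call. = FALSE)
  if (eps <= 0) stop("'eps' must be > 0", call. = FALSE)
  structure(list(n_components = as.integer(n_components),
                 n_init = as.integer(n_init), max_iter = as.integer(max_iter),
                 eps = eps, seed = as.integer(seed)), class = "mds_config")
}

#' Convert a similarity matrix to a dissimilarity matrix
#'
#' `d = 1 - s` (default) or `d = sqrt(1 - s)`; the square-root transform
#' makes cosine-type similarities Euclidean-embeddable.
#'
#' @param sim similarity matrix with entries `<= 1` (e.g. from
#'   [tina_matrix()]).
#' @param method `"one_minus"` (default) or `"sqrt"`.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
to_dissimilarity <- function(sim, method = c("one_minus", "sqrt")) {
  method <- match.arg(method)
  check_symmetric(sim, name = "sim")
  if (any(sim > 1 + 1e-9))
    stop("similarity entries must not exceed 1", call. = FALSE)
  d <- pmax(1 - sim, 0)
  if (method == "sqrt") d <- sqrt(d)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' SMACOF metric multidimensional scaling
#'
#' Minimizes the raw stress
#' `sigma(X) = sum_{a<b} (d_ab - |x_a - x_b|)^2`
#' by iterated Guttman transforms from `n_init` seeded random starts.
#' Majorization guarantees the stress sequence within each start is
#' non-increasing.  The embedding is identified only up to rotation,
#' reflection and translation; compare inter-point distances, not raw
#' coordinates.
#'
#' @param d symmetric non-negative dissimilarity matrix with zero diagonal.
#' @param config an [mds_config()].
#' @return an object of class `"smacof_embedding"`: list with `coords`
#'   (n x n_components, rownames from `d`), `stress` (best raw stress),
#'   `normalized_stress` (`stress / sum(d^2)` over pairs),
#'   `stress_per_init`, `trace` (stress sequence of the best start),
#'   `config`.
#' @export
smacof_mds <- function(d, config = mds_config()) {
  check_symmetric(d, name = "d")
  if (any(d < 0)) stop("dissimilarities must be non-negative", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("dissimilarity diagonal must be zero", call. = FALSE)
  n <- nrow(d)
  p <- config$n_components
  best <- NULL
  stress_per_init <- numeric(config$n_init)
  for (init in seq_len(config$n_init)) {
    X <- with_seed(derive_seed(config$seed, "smacof-init", init), {
      matrix(stats::rnorm(n * p), n, p)
    })
    res <- smacof_single(d, X, config$max_iter, config$eps)
    stress_per_init[init] <- res$stress
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  rownames(best$X) <- rownames(d)
  structure(list(coords = best$X, stress = best$stress,
                 normalized_stress = best$stress / sum(d[upper.tri(d)]^2),
                 stress_per_init = stress_per_init, trace = best$trace,
                 config = config), class = "smacof_embedding")
}

# One majorization run from a given start configuration.
smacof_single <- function(d, X, max_iter, eps) {
  n <- nrow(d)
  dist_mat <- function(X) as.matrix(stats::dist(X))
  stress_of <- function(DX) sum((d[upper.tri(d)] - DX[upper.tri(DX)])^2)
  DX <- dist_mat(X)
  s_prev <- stress_of(DX)
  trace <- s_prev
  for (iter in seq_len(max_iter)) {
    # Guttman transform: X <- (1/n) B(X) X with b_ij = -d_ij / dist_ij
    ratio <- ifelse(DX > 0, d / DX, 0)
    diag(ratio) <- 0
    B <- -ratio
    diag(B) <- rowSums(ratio)
    X <- B %*% X / n
    DX <- dist_mat(X)
    s <- stress_of(DX)
    trace <- c(trace, s)
    if (s_prev - s < eps) { s_prev <- s; break }
    s_prev <- s
  }
  list(X = X, stress = s_prev, trace = trace)
}

#' @export
print.smacof_embedding <- function(x, ...) {
  cat("SMACOF embedding:", nrow(x$coords), "points in",
      ncol(x$coords), "dimensions; raw stress",
      format(x$stress, digits = 4), "(best of",
      length(x$stress_per_init), "starts)\n")
  invisible(x)
}
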