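# SparCC estimation of basis correlations from compositional count data.
#
# Observed fractions are compositions: closing counts to 1 makes component
# fractions negatively dependent regardless of any true association between
# the underlying absolute ("basis") abundances.  SparCC works on the
# log-ratio variation matrix t_ij = Var[log(f_i/f_j)], which is invariant to
# the closure, and solves for basis variances under a sparsity assumption
# (most pairs uncorrelated), from which basis correlations follow.
# Posterior uncertainty in the fractions themselves is propagated by
# resampling fractions from the per-sample Dirichlet posterior.

#' Configuration of the Dirichlet posterior resampling
#'
#' @param n_draws number of posterior fraction draws over which correlation
#'   estimates are aggregated (default 100).
#' @param prior_alpha symmetric Dirichlet prior parameter; 1 is the uniform
#'   prior.
#' @param seed integer seed for the draws.
#' @return a list of class `"posterior_config"`.
#' @export
posterior_config <- function(n_draws = 100L, prior_alpha = 1, seed = 1L) {
  if (n_draws < 1) stop("'n_draws' must be >= 1", call. = FALSE)
  if (prior_alpha <= 0) stop("'prior_alpha' must be > 0", call. = FALSE)
  structure(list(n_draws = as.integer(n_draws), prior_alpha = prior_alpha,
                 seed = as.integer(seed)), class = "posterior_config")
}

#' Draw posterior fractions for every sample
#'
#' For sample `j`, fractions are drawn from
#' `Dirichlet(counts[, j] + prior_alpha)` -- the posterior under multinomial
#' sampling of reads with a symmetric Dirichlet prior.  Draws are strictly
#' positive, which licenses the log-ratio transform even for zero counts.
#' The draw is a deterministic function of `(config$seed, draw_index)`.
#'
#' @param table validated count matrix.
#' @param config a [posterior_config()].
#' @param draw_index index of the draw (1-based), used to derive the
#'   per-draw seed.
#' @return fraction matrix of the same shape as `table`; columns sum to 1.
#' @export
dirichlet_draw <- function(table, config = posterior_config(), draw_index = 1L) {
  validate_count_table(table)
  with_seed(derive_seed(config$seed, "dirichlet", draw_index), {
    g <- matrix(stats::rgamma(length(table), shape = table + config$prior_alpha),
                nrow(table), ncol(table), dimnames = dimnames(table))
    sweep(g, 2, colSums(g), "/")
  })
}

#' Log-ratio variation matrix
#'
#' `t_ij = Var[log(f_i / f_j)]` across samples (sample variance, n - 1
#' denominator): the sufficient statistic of the basis-correlation model,
#' invariant to per-sample closure and depth.
#'
#' @param fractions strictly positive fraction matrix (taxa x samples) with
#'   at least two samples; use [dirichlet_draw()] to obtain positive
#'   fractions from counts with zeros.
#' @return symmetric K x K matrix with zero diagonal.
#' @export
variation_matrix <- function(fractions) {
  if (ncol(fractions) < 2)
    stop("variation matrix needs at least 2 samples", call. = FALSE)
  if (any(fractions <= 0))
    stop("fractions must be strictly positive; draw them from the Dirichlet ",
         "posterior (dirichlet_draw) rather than closing raw counts",
         call. = FALSE)
  V <- stats::cov(t(log(fractions)))
  v <- diag(V)
  Tm <- outer(v, rep(1, length(v))) + outer(rep(1, length(v)), v) - 2 * V
  Tm <- (Tm + t(Tm)) / 2
  diag(Tm) <- 0
  Tm[Tm < 0] <- 0   # numerical noise on near-identical taxa
  dimnames(Tm) <- list(rownames(fractions), rownames(fractions))
  Tm
}

# Symmetric logical matrix of active (non-excluded) off-diagonal pairs.
active_matrix <- function(K, excluded = NULL, ids = NULL) {
  act <- matrix(TRUE, K, K)
  diag(act) <- FALSE
  if (!is.null(excluded) && NROW(excluded) > 0) {
    excluded <- as.matrix(excluded)
    if (ncol(excluded) != 2)
      stop("'excluded' must be a 2-column matrix of taxon pairs", call. = FALSE)
    if (is.character(excluded)) {
      if (is.null(ids)) stop("taxon ids needed to resolve excluded pairs",
                             call. = FALSE)
      excluded <- matrix(match(excluded, ids), ncol = 2)
      if (any(is.na(excluded)))
        stop("excluded pairs contain unknown taxon ids", call. = FALSE)
    }
    if (any(excluded[, 1] == excluded[, 2]))
      stop("excluded pairs may not be self-pairs", call. = FALSE)
    act[excluded] <- FALSE
    act[excluded[, c(2, 1), drop = FALSE]] <- FALSE
  }
  act
}

#' Solve for basis variances and correlations
#'
#' Under the sparsity approximation (average basis covariance small), the
#' row sums of the variation matrix over each taxon's active partners are
#' linear in the basis variances:
#' `sum_j t_ij = m_i w_i^2 + sum_j w_j^2` over active partners `j`, with
#' `m_i` the number of partners of taxon `i`.  The K x K system is solved
#' directly; correlations follow from
#' `rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`, clipped to `[-1, 1]`.
#' Excluded pairs are dropped from the system but their `rho` is still
#' reported from the fitted variances.
#'
#' Negative variance solutions (possible in noisy or heavily excluded
#' systems) are floored at 1e-10 and flagged rather than raising an error.
#'
#' @param t variation matrix from [variation_matrix()].
#' @param excluded optional 2-column matrix (indices or taxon ids) of pairs
#'   to drop from the system.
#' @return an object of class `"basis_model"`: list with `omega2` (named
#'   basis variances), `rho` (correlation matrix, unit diagonal), `cov`
#'   (basis covariances `rho_ij w_i w_j`), `flagged` (taxa whose variance
#'   was floored), `n_active_pairs`.
#' @export
basis_correlations <- function(t, excluded = NULL) {
  check_symmetric(t, name = "t")
  K <- nrow(t)
  if (K < 4)
    stop("basis correlations need at least 4 taxa (system underdetermined)",
         call. = FALSE)
  act <- active_matrix(K, excluded, ids = rownames(t))
  A <- act * 1
  m <- rowSums(A)
  if (any(m == 0))
    stop("taxon with no active partners: system is singular", call. = FALSE)
  b <- rowSums(t * A)
  diag(A) <- m
  omega2 <- tryCatch(solve(A, b), error = function(e)
    stop("singular variance system: ", conditionMessage(e), call. = FALSE))
  flagged <- omega2 < 0
  omega2 <- pmax(omega2, 1e-10)
  om <- sqrt(omega2)
  denom <- 2 * tcrossprod(om)
  rho <- (outer(omega2, omega2, "+") - t) / denom
  rho <- pmin(pmax(rho, -1), 1)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  cov <- rho * tcrossprod(om)
  ids <- rownames(t)
  if (!is.null(ids)) {
    names(omega2) <- ids
    dimnames(rho) <- dimnames(cov) <- list(ids, ids)
  }
  structure(list(omega2 = omega2, rho = rho, cov = cov,
                 flagged = which(flagged), n_active_pairs = sum(act) / 2),
            class = "basis_model")
}

#' Full SparCC estimate with posterior resampling and refinement
#'
#' For each of `config$n_draws` Dirichlet posterior draws the pipeline runs
#' [variation_matrix()], [iterative_refinement()] (if enabled) and
#' [basis_correlations()], then aggregates the per-draw correlation matrices
#' element-wise (mean by default; the median requires keeping all draws in
#' memory).
#'
#' @param table validated, abundance-filtered count matrix.
#' @param config a [posterior_config()].
#' @param refine a [refinement_config()]; set `enabled = FALSE` for the
#'   basic (single-fit) estimator.
#' @param aggregate `"mean"` (default) or `"median"` across draws.
#' @return an object of class `"sparcc_fit"`: list with `rho_mean`
#'   (aggregated correlation matrix), `n_draws`, `excluded_pairs` (union
#'   across draws, 2-column taxon-id matrix), `traces` (per-draw refinement
#'   traces), `flagged_draws` (draws with floored variances), `config`,
#'   `refine`.
#' @seealso [permutation_pvalues()] for significance.
#' @export
sparcc_estimate <- function(table, config = posterior_config(),
                            refine = refinement_config(),
                            aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  validate_count_table(table)
  K <- nrow(table)
  ids <- rownames(table)
  acc <- matrix(0, K, K)
  draws <- if (aggregate == "median") vector("list", config$n_draws) else NULL
  excl_union <- matrix(character(0), 0, 2)
  traces <- vector("list", config$n_draws)
  flagged_draws <- integer(0)
  for (d in seq_len(config$n_draws)) {
    fr <- dirichlet_draw(table, config, d)
    Tm <- variation_matrix(fr)
    if (isTRUE(refine$enabled)) {
      rf <- iterative_refinement(Tm, refine)
      model <- rf$model
      traces[[d]] <- rf$trace
      if (nrow(rf$excluded) > 0)
        excl_union <- unique(rbind(excl_union,
                                   cbind(ids[rf$excluded[, 1]],
                                         ids[rf$excluded[, 2]])))
    } else {
      model <- basis_correlations(Tm)
      traces[[d]] <- NULL
    }
    if (length(model$flagged) > 0) flagged_draws <- c(flagged_draws, d)
    if (aggregate == "median") draws[[d]] <- model$rho else acc <- acc + model$rho
  }
  rho <- if (aggregate == "median") {
    apply(simplify2array(draws), c(1, 2), stats::median)
  } else acc / config$n_draws
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(ids, ids)
  structure(list(rho_mean = rho, n_draws = config$n_draws,
                 excluded_pairs = excl_union, traces = traces,
                 flagged_draws = unique(flagged_draws),
                 config = config, refine = refine),
            class = "sparcc_fit")
}

#' Permutation pseudo-p-values for SparCC correlations
#'
#' Each permutation independently shuffles every taxon's counts across
#' samples, destroying all between-taxon association while preserving each
#' taxon's count distribution, then re-estimates the correlation matrix
#' with a single Dirichlet draw and no refinement (the fast null; set
#' `full = TRUE` to run the complete refined pipeline per permutation).
#' Two-sided pseudo-p-values use the add-one correction
#' `p = (1 + #exceedances) / (1 + n_perm)`, bounded below by
#' `1/(n_perm + 1)`.
#'
#' @param table the count matrix that produced `rho_obs`.
#' @param rho_obs observed correlation matrix (e.g. `fit$rho_mean`).
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed for shuffles and null draws.
#' @param prior_alpha Dirichlet prior for the null re-estimates.
#' @param full run refinement and `n_draws` from `config` per permutation.
#' @param config,refine configs used when `full = TRUE`.
#' @return symmetric matrix of p-values in `(0, 1]` with unit-diagonal
#'   positions set to `NA`.
#' @export
permutation_pvalues <- function(table, rho_obs, n_perm = 100L, seed = 1L,
                                prior_alpha = 1, full = FALSE,
                                config = posterior_config(prior_alpha = prior_alpha,
                                                          seed = seed),
                                refine = refinement_config()) {
  validate_count_table(table)
  if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  if (!identical(dim(rho_obs), dim(table)[c(1, 1)]) &&
      !all(dim(rho_obs) == nrow(table)))
    stop("'rho_obs' must be K x K for the K taxa of 'table'", call. = FALSE)
  K <- nrow(table)
  exceed <- matrix(0, K, K)
  for (p in seq_len(n_perm)) {
    perm <- with_seed(derive_seed(seed, "perm-shuffle", p), {
      t(apply(table, 1, sample))
    })
    dimnames(perm) <- dimnames(table)
    if (full) {
      cfg <- posterior_config(config$n_draws, config$prior_alpha,
                              derive_seed(seed, "perm-draw", p))
      rho_null <- sparcc_estimate(perm, cfg, refine)$rho_mean
    } else {
      cfg <- posterior_config(1L, prior_alpha, derive_seed(seed, "perm-draw", p))
      fr <- dirichlet_draw(perm, cfg, 1L)
      rho_null <- basis_correlations(variation_matrix(fr))$rho
    }
    exceed <- exceed + (abs(rho_null) >= abs(rho_obs))
  }
  pv <- (1 + exceed) / (1 + n_perm)
  pv <- (pv + t(pv)) / 2
  diag(pv) <- NA_real_
  dimnames(pv) <- dimnames(table)[c(1, 1)]
  rownames(pv) <- colnames(pv) <- rownames(table)
  pv
}

#' @export
print.sparcc_fit <- function(x, ...) {
  cat("SparCC fit:", nrow(x$rho_mean), "taxa,", x$n_draws, "posterior draw(s),",
      nrow(x$excluded_pairs), "pair(s) in the exclusion union\n")
  invisible(x)
}

#' @export
print.basis_model <- function(x, ...) {
  cat("Basis model:", length(x$omega2), "taxa,", x$n_active_pairs,
      "active pairs,", length(x$flagged), "floored variance(s)\n")
  invisible(x)
}
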