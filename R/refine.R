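# Iterative exclusion of extreme-covariance pairs from the variation matrix.
#
# The basis-variance solve assumes the average basis covariance is small.
# Strongly associated pairs violate that assumption and leak into every
# taxon's variance estimate.  The refinement repeatedly removes, per
# iteration, a small batch of pairs with the highest positive and the
# highest negative fitted covariance from the linear system and refits,
# until the total covariance of the refit model stops decreasing over a
# sliding window.  Excluded pairs keep a reported correlation (from the
# final variances and their original t_ij); they are only dropped from the
# variance-estimation system.

#' Configuration of the iterative pair exclusion
#'
#' @param batch_fraction fraction of currently active pairs removed per
#'   iteration *per sign* (default 0.025%, with a minimum of one pair).
#' @param window length of the sliding convergence window in iterations.
#' @param rel_tol relative decrease of the convergence statistic over the
#'   window below which the loop stops.
#' @param max_iter hard iteration cap.
#' @param enabled `FALSE` bypasses refinement entirely (basic estimator).
#' @param signed_batches if `TRUE` (default) each iteration removes the
#'   `batch` most positive and the `batch` most negative covariance pairs;
#'   if `FALSE` it removes the `2 * batch` pairs of largest absolute
#'   covariance regardless of sign.
#' @param stop_stat series monitored by the window rule: `"model"`
#'   (default) is the total absolute basis covariance of the refit model
#'   over *all* pairs, which flattens once further exclusions stop changing
#'   the fit; `"active"` is the running sum over active pairs only, which
#'   decreases by at least the removed batch every iteration and therefore
#'   typically terminates through `max_iter` or the active-pair floor
#'   instead of the window (see the package vignette).
#' @return a list of class `"refinement_config"`.
#' @export
refinement_config <- function(batch_fraction = 0.00025, window = 10L,
                              rel_tol = 1e-3, max_iter = 500L,
                              enabled = TRUE, signed_batches = TRUE,
                              stop_stat = c("model", "active")) {
  if (batch_fraction <= 0 || batch_fraction >= 1)
    stop("'batch_fraction' must be in (0, 1)", call. = FALSE)
  if (window < 2) stop("'window' must be >= 2", call. = FALSE)
  if (rel_tol <= 0) stop("'rel_tol' must be > 0", call. = FALSE)
  if (max_iter < 1) stop("'max_iter' must be >= 1", call. = FALSE)
  structure(list(batch_fraction = batch_fraction, window = as.integer(window),
                 rel_tol = rel_tol, max_iter = as.integer(max_iter),
                 enabled = isTRUE(enabled), signed_batches = isTRUE(signed_batches),
                 stop_stat = match.arg(stop_stat)),
            class = "refinement_config")
}

#' Fitted basis covariances of a pair set, ranked
#'
#' Returns the basis covariances `c_ij = rho_ij w_i w_j` of the given pairs
#' sorted in decreasing order, ties broken lexicographically by the taxon
#' index pair so rankings are fully deterministic.
#'
#' @param model a `"basis_model"` from [basis_correlations()].
#' @param pairs 2-column index matrix of pairs to rank; `NULL` means all
#'   off-diagonal pairs.
#' @return data.frame with columns `i`, `j`, `taxon_i`, `taxon_j`, `cov`,
#'   sorted by decreasing `cov`.
#' @export
pair_covariances <- function(model, pairs = NULL) {
  stopifnot(inherits(model, "basis_model"))
  K <- length(model$omega2)
  if (is.null(pairs)) pairs <- upper_pairs(K)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop("empty pair set", call. = FALSE)
  cv <- model$cov[pairs]
  ord <- order(-cv, pairs[, 1], pairs[, 2])
  ids <- names(model$omega2)
  out <- data.frame(i = pairs[ord, 1], j = pairs[ord, 2], cov = cv[ord])
  out$taxon_i <- if (!is.null(ids)) ids[out$i] else as.character(out$i)
  out$taxon_j <- if (!is.null(ids)) ids[out$j] else as.character(out$j)
  out[, c("i", "j", "taxon_i", "taxon_j", "cov")]
}

#' Per-iteration exclusion batch size
#'
#' `ceiling(n_active_pairs * batch_fraction)`, with a minimum of one pair,
#' so refinement makes progress even on small tables (e.g. 36,315 pairs at
#' 0.025% gives batches of 10).
#'
#' @param n_active_pairs number of currently active pairs (>= 1).
#' @param batch_fraction fraction in (0, 1).
#' @return integer batch size.
#' @export
batch_size <- function(n_active_pairs, batch_fraction = 0.00025) {
  if (n_active_pairs < 1) stop("'n_active_pairs' must be >= 1", call. = FALSE)
  max(1L, as.integer(ceiling(n_active_pairs * batch_fraction)))
}

#' Total absolute basis covariance of a pair set
#'
#' `sum |c_ij|` over the given pairs -- the magnitude the sparsity
#' assumption requires to be small, and the quantity traced by the
#' refinement loop.
#'
#' @param model a `"basis_model"`.
#' @param pairs 2-column index matrix; `NULL` means all off-diagonal pairs.
#' @return non-negative scalar.
#' @export
total_covariance <- function(model, pairs = NULL) {
  stopifnot(inherits(model, "basis_model"))
  K <- length(model$omega2)
  if (is.null(pairs)) pairs <- upper_pairs(K)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop("empty pair set", call. = FALSE)
  sum(abs(model$cov[pairs]))
}

#' Iteratively exclude extreme-covariance pairs and refit
#'
#' See [refinement_config()] for the loop's tuning knobs.  The loop stops
#' when (i) the relative decrease of the convergence statistic over the
#' last `window` iterations falls below `rel_tol` (`window_converged`),
#' (ii) `max_iter` is reached (`max_iter`), or (iii) a further batch would
#' leave fewer than `3 * (K - 1)` active pairs, the solvability floor of
#' the variance system (`exhausted`).
#'
#' @param t variation matrix from [variation_matrix()].
#' @param config a [refinement_config()].
#' @return list with elements
#'   * `model`: final `"basis_model"` fit on the surviving pairs,
#'   * `excluded`: 2-column index matrix of excluded pairs (row < col),
#'   * `trace`: data.frame with one row per iteration -- `iteration`,
#'     `total_covariance` (active-pair sum, non-increasing),
#'     `model_covariance` (all-pair sum of the refit model),
#'     `n_excluded_cumulative`,
#'   * `stopped_reason`: `"window_converged"`, `"max_iter"`, `"exhausted"`,
#'     or `"disabled"`.
#' @export
iterative_refinement <- function(t, config = refinement_config()) {
  check_symmetric(t, name = "t")
  K <- nrow(t)
  all_pairs <- upper_pairs(K)
  if (!isTRUE(config$enabled)) {
    model <- basis_correlations(t)
    return(list(model = model, excluded = matrix(integer(0), 0, 2),
                trace = data.frame(iteration = 1L,
                                   total_covariance = total_covariance(model),
                                   model_covariance = total_covariance(model),
                                   n_excluded_cumulative = 0L),
                stopped_reason = "disabled"))
  }
  active <- rep(TRUE, nrow(all_pairs))
  excluded_rows <- integer(0)
  trace <- vector("list", config$max_iter)
  reason <- "max_iter"
  floor_pairs <- 3 * (K - 1)
  ids <- rownames(t)
  stat <- numeric(config$max_iter)
  k <- 0L
  while (k < config$max_iter) {
    k <- k + 1L
    act_pairs <- all_pairs[active, , drop = FALSE]
    model <- basis_correlations(t, excluded = all_pairs[!active, , drop = FALSE])
    cv <- model$cov[act_pairs]
    tot_active <- sum(abs(cv))
    tot_model <- sum(abs(model$cov[all_pairs]))
    trace[[k]] <- data.frame(iteration = k, total_covariance = tot_active,
                             model_covariance = tot_model,
                             n_excluded_cumulative = sum(!active))
    stat[k] <- if (config$stop_stat == "model") tot_model else tot_active
    if (k > config$window) {
      s0 <- stat[k - config$window]
      if (s0 <= 0 || (s0 - stat[k]) / s0 < config$rel_tol) {
        reason <- "window_converged"
        break
      }
    }
    nb <- batch_size(nrow(act_pairs), config$batch_fraction)
    if (config$signed_batches) {
      ord <- order(-cv, act_pairs[, 1], act_pairs[, 2])
      pos <- ord[cv[ord] > 0]
      neg <- rev(ord)[cv[rev(ord)] < 0]
      drop_idx <- c(utils::head(pos, nb), utils::head(neg, nb))
    } else {
      ord <- order(-abs(cv), act_pairs[, 1], act_pairs[, 2])
      drop_idx <- utils::head(ord, 2 * nb)
    }
    if (length(drop_idx) == 0) { reason <- "window_converged"; break }
    if (nrow(act_pairs) - length(drop_idx) < floor_pairs) {
      reason <- "exhausted"
      break
    }
    active[which(active)[drop_idx]] <- FALSE
  }
  excluded <- all_pairs[!active, , drop = FALSE]
  model <- basis_correlations(t, excluded = excluded)
  list(model = model, excluded = excluded,
       trace = do.call(rbind, trace[seq_len(k)]), stopped_reason = reason)
}
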