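# Per-sample diversity statistics: Chao1 richness, the coverage-adjusted
# (Chao-Shen) Shannon estimator, and the effective number of taxa.

#' Chao1 richness estimator
#'
#' Classic Chao1: `S_obs + f1^2 / (2 f2)` where `f1` and `f2` are the
#' numbers of singleton and doubleton taxa.  When no doubletons are present
#' the bias-corrected form `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` is used so
#' the estimate stays finite.
#'
#' @param counts non-negative integer vector of per-taxon counts for one
#'   sample.
#' @return estimated richness (always `>= S_obs`).
#' @export
chao1 <- function(counts) {
  counts <- check_count_vector(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Coverage-adjusted (Chao-Shen) Shannon diversity
#'
#' The nonparametric Shannon estimator: sample coverage is estimated by the
#' Good-Turing formula `C = 1 - f1/n`, abundances are shrunk to
#' `p_i = C x_i / n`, and the Horvitz-Thompson correction reweights each
#' term by its detection probability:
#' `H = -sum p_i log(p_i) / (1 - (1 - p_i)^n)`.
#' Units are nats, so `exp(H)` is the effective number of taxa.
#'
#' @param counts non-negative integer vector of per-taxon counts.
#' @return estimated Shannon entropy in nats.
#' @seealso [shannon_plugin()] for the uncorrected estimator,
#'   [effective_otus()].
#' @export
shannon_np <- function(counts) {
  counts <- check_count_vector(counts)
  x <- counts[counts > 0]
  n <- sum(x)
  f1 <- sum(x == 1)
  if (f1 == n)
    stop("all observed taxa are singletons: estimated coverage is 0 and the ",
         "coverage-adjusted Shannon estimator is undefined", call. = FALSE)
  cover <- 1 - f1 / n
  p <- cover * x / n
  -sum(p * log(p) / (1 - (1 - p)^n))
}

#' Plug-in Shannon diversity
#'
#' The maximum-likelihood estimator `-sum p log p` on observed fractions,
#' exposed for comparison with [shannon_np()]; it underestimates diversity
#' in undersampled communities.
#'
#' @inheritParams shannon_np
#' @return Shannon entropy in nats.
#' @export
shannon_plugin <- function(counts) {
  counts <- check_count_vector(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Effective number of taxa
#'
#' The Hill number of order 1: `exp(H)` for Shannon entropy `H` in nats --
#' the number of equally common taxa that would give the same entropy.
#'
#' @param shannon non-negative Shannon entropy in nats.
#' @return effective number of taxa.
#' @export
effective_otus <- function(shannon) {
  if (any(!is.finite(shannon)) || any(shannon < 0))
    stop("'shannon' must be non-negative and finite", call. = FALSE)
  exp(shannon)
}

#' Per-sample diversity summary of a count table
#'
#' @param table validated count matrix (taxa x samples).
#' @return data.frame with one row per sample: `sample_id`, `n_reads`,
#'   `s_obs`, `f1`, `f2`, `chao1`, `shannon_np`, `effective_otus`.
#' @export
diversity_table <- function(table) {
  validate_count_table(table)
  rows <- lapply(colnames(table), function(s) {
    x <- table[, s]
    h <- shannon_np(x)
    data.frame(sample_id = s, n_reads = sum(x), s_obs = sum(x > 0),
               f1 = sum(x == 1), f2 = sum(x == 2),
               chao1 = chao1(x), shannon_np = h,
               effective_otus = effective_otus(h),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

check_count_vector <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be a vector of non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("'counts' must contain at least one positive count", call. = FALSE)
  counts
}
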