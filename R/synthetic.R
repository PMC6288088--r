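# Synthetic community generator.
#
# The generative model mirrors the assumptions of the compositional
# correlation machinery downstream: latent ("basis") absolute abundances are
# log-normal with a sparse correlation structure; sequencing observes only a
# multinomial sample of the closed composition.  Closure induces exactly the
# spurious negative correlations the SparCC stage is meant to remove, so a
# generator of this form gives every stage a usable ground truth.

#' Construct a ground-truth basis model for synthetic communities
#'
#' Builds a K x K basis correlation matrix with a sparse set of planted
#' signed pairs at `+/- strength`, per-taxon log-scale variances, and
#' per-group log-scale mean profiles.  Planted pairs are sampled without
#' reusing taxa, so the matrix is block-diagonal and positive definite by
#' construction; should a caller supply a custom matrix it can be repaired
#' with [nearest_psd_correlation()].
#'
#' Group structure is expressed through log-mean shifts: `n_shifted` taxa are
#' raised by `shift` log-units in the "ciliate" group and lowered by the same
#' amount in the "gut" group, and a disjoint set of `n_shifted` taxa gets the
#' opposite pattern.  Positive pairs are planted within the shifted sets
#' (co-occurring partners of the same habitat) and negative pairs across
#' them, which is the configuration that yields two abundance blocks joined
#' by negative associations in the recovered network.
#'
#' @param K number of taxa.
#' @param n_pos_pairs,n_neg_pairs numbers of planted positive / negative
#'   correlation pairs; together they must involve at most K taxa.
#' @param strength planted correlation magnitude, in (0, 1).
#' @param seed integer seed; the truth is a deterministic function of it.
#' @param n_shifted taxa per group with a differential log-mean (0 = no
#'   group structure).
#' @param shift size of the differential log-mean, in log-units (a shift of
#'   3 is roughly a 20-fold fold-change between groups, the order of
#'   magnitude seen for habitat-signature genera).
#' @param basis_logvar per-taxon log-scale variance (scalar or length-K).
#' @param depth_range integer 2-vector, inclusive range of per-sample read
#'   depths.
#' @param base_mean_sd standard deviation of the baseline log-means drawn
#'   for all taxa (abundance heterogeneity across taxa).
#' @return an object of class `"synthetic_truth"`: list with elements `K`,
#'   `basis_corr`, `basis_logvar`, `group_means` (list `ciliate`, `gut`),
#'   `pairs` (data.frame of planted pairs with sign), `affinity`
#'   (per-taxon `"ciliate"`, `"gut"` or `"none"`), `depth_range`, `seed`.
#' @seealso [simulate_counts()], [synthetic_preset()]
#' @export
make_truth <- function(K, n_pos_pairs = 0, n_neg_pairs = 0, strength = 0.8,
                       seed = 1, n_shifted = 0, shift = 3,
                       basis_logvar = 1, depth_range = c(10000L, 122000L),
                       base_mean_sd = 1) {
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  if (strength <= 0 || strength >= 1)
    stop("'strength' must be in (0, 1)", call. = FALSE)
  if (2 * (n_pos_pairs + n_neg_pairs) > K)
    stop("too many planted pairs: ", n_pos_pairs + n_neg_pairs,
         " disjoint pairs need ", 2 * (n_pos_pairs + n_neg_pairs),
         " taxa but K = ", K, call. = FALSE)
  if (2 * n_shifted > K)
    stop("2 * n_shifted must not exceed K", call. = FALSE)
  depth_range <- as.integer(round(depth_range))
  if (length(depth_range) != 2 || any(depth_range < 1) ||
      depth_range[1] > depth_range[2])
    stop("'depth_range' must be two positive integers (min, max)", call. = FALSE)
  basis_logvar <- rep_len(basis_logvar, K)
  if (any(basis_logvar <= 0)) stop("'basis_logvar' must be positive", call. = FALSE)

  with_seed(derive_seed(seed, "truth"), {
    affinity <- rep("none", K)
    if (n_shifted > 0) {
      affinity[seq_len(n_shifted)] <- "ciliate"
      affinity[n_shifted + seq_len(n_shifted)] <- "gut"
    }
    base_mu <- stats::rnorm(K, 0, base_mean_sd)
    half <- shift / 2
    mu_cil <- base_mu + ifelse(affinity == "ciliate", half,
                               ifelse(affinity == "gut", -half, 0))
    mu_gut <- base_mu + ifelse(affinity == "gut", half,
                               ifelse(affinity == "ciliate", -half, 0))

    # plant disjoint pairs: positives within an affinity set when groups
    # exist, negatives across sets; otherwise uniformly at random
    cil_pool <- if (n_shifted > 0) which(affinity == "ciliate") else seq_len(K)
    gut_pool <- if (n_shifted > 0) which(affinity == "gut") else seq_len(K)
    used <- logical(K)
    take <- function(pool, n) {
      free <- setdiff(pool, which(used))
      if (length(free) < n)
        stop("not enough free taxa to plant the requested pairs", call. = FALSE)
      picked <- if (length(free) == 1) free else sample(free, n)
      used[picked] <<- TRUE
      picked
    }
    pairs <- data.frame(i = integer(0), j = integer(0), rho = numeric(0))
    if (n_pos_pairs > 0) {
      n_cil <- if (n_shifted > 0) ceiling(n_pos_pairs / 2) else n_pos_pairs
      n_gut <- n_pos_pairs - n_cil
      for (pool_n in list(list(cil_pool, n_cil), list(gut_pool, n_gut))) {
        if (pool_n[[2]] == 0) next
        idx <- take(pool_n[[1]], 2 * pool_n[[2]])
        m <- matrix(idx, ncol = 2, byrow = TRUE)
        pairs <- rbind(pairs, data.frame(i = pmin(m[, 1], m[, 2]),
                                         j = pmax(m[, 1], m[, 2]),
                                         rho = strength))
      }
    }
    if (n_neg_pairs > 0) {
      a <- take(cil_pool, n_neg_pairs)
      b <- take(gut_pool, n_neg_pairs)
      pairs <- rbind(pairs, data.frame(i = pmin(a, b), j = pmax(a, b),
                                       rho = -strength))
    }
    R <- diag(K)
    if (nrow(pairs) > 0) {
      R[cbind(pairs$i, pairs$j)] <- pairs$rho
      R[cbind(pairs$j, pairs$i)] <- pairs$rho
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
      R <- nearest_psd_correlation(R)

    taxon_ids <- sprintf("taxon_%03d", seq_len(K))
    dimnames(R) <- list(taxon_ids, taxon_ids)
    structure(list(
      K = K, basis_corr = R,
      basis_logvar = stats::setNames(basis_logvar, taxon_ids),
      group_means = list(ciliate = stats::setNames(mu_cil, taxon_ids),
                         gut = stats::setNames(mu_gut, taxon_ids)),
      pairs = pairs, affinity = stats::setNames(affinity, taxon_ids),
      depth_range = depth_range, seed = seed
    ), class = "synthetic_truth")
  })
}

#' Project a symmetric matrix to the nearest positive semi-definite
#' correlation matrix
#'
#' Eigenvalues below `floor` are clipped to `floor`, the matrix is
#' reassembled and rescaled to unit diagonal.  Used to repair hand-built
#' basis correlation targets that are not quite feasible.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param floor smallest admissible eigenvalue.
#' @return a symmetric positive semi-definite matrix with unit diagonal.
#' @export
nearest_psd_correlation <- function(R, floor = 1e-8) {
  check_symmetric(R, name = "R")
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(R)
  out
}

#' Simulate a count table from a ground truth
#'
#' Per sample: a log-abundance vector is drawn from a multivariate normal
#' with the sample group's mean profile and covariance
#' `diag(sigma) %*% basis_corr %*% diag(sigma)`; the vector is closed to a
#' composition by softmax; a read depth is drawn uniformly from
#' `depth_range`; counts are drawn multinomially at that depth.
#'
#' @param truth a `"synthetic_truth"` object from [make_truth()].
#' @param n_samples_per_group integer 2-vector or scalar: samples in the
#'   ciliate and gut groups (a scalar is used for both).  A group may have
#'   0 samples (single-group designs).
#' @param seed integer seed; the dataset is a deterministic function of
#'   `(truth, n_samples_per_group, seed)`.
#' @return an object of class `"synthetic_dataset"`: list with `table`
#'   (integer count matrix), `metadata` (data.frame: sample_id, group,
#'   species_label, country), and `truth`.
#' @export
simulate_counts <- function(truth, n_samples_per_group, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_per <- rep_len(as.integer(n_samples_per_group), 2)
  if (any(n_per < 0) || sum(n_per) < 1)
    stop("'n_samples_per_group' must give at least one sample in total",
         call. = FALSE)
  K <- truth$K
  sigma <- sqrt(truth$basis_logvar)
  Sig <- truth$basis_corr * tcrossprod(sigma)
  groups <- rep(c("ciliate", "gut"), n_per)
  n <- length(groups)
  species_pool <- c(ciliate = "Clevelandella_sp", gut = "hindgut_content")
  country_pool <- c("Vietnam", "Thailand", "Cambodia")

  with_seed(derive_seed(seed, "counts"), {
    counts <- matrix(0L, K, n)
    for (s in seq_len(n)) {
      mu <- truth$group_means[[groups[s]]]
      loga <- MASS::mvrnorm(1, mu, Sig)
      fr <- exp(loga - max(loga))
      fr <- fr / sum(fr)
      depth <- sample(truth$depth_range[1]:truth$depth_range[2], 1)
      counts[, s] <- stats::rmultinom(1, depth, fr)
    }
    sample_ids <- sprintf("%s%02d", ifelse(groups == "ciliate", "C", "G"),
                          stats::ave(seq_len(n), groups, FUN = seq_along))
    dimnames(counts) <- list(names(truth$group_means$ciliate), sample_ids)
    metadata <- data.frame(
      sample_id = sample_ids, group = groups,
      species_label = unname(species_pool[groups]),
      country = sample(country_pool, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    structure(list(table = counts, metadata = metadata, truth = truth),
              class = "synthetic_dataset")
  })
}

#' Predefined synthetic study designs
#'
#' Two fixed configurations used throughout the package's validation:
#'
#' * `"recovery"`: K = 50 taxa, 200 samples in one homogeneous group,
#'   5 planted positive pairs at rho = 0.8 -- the benchmark for correlation
#'   recovery.
#' * `"emulation"`: K = 100 taxa, 27 ciliate + 7 gut samples, read depths
#'   10,000-122,000, 20 taxa up-shifted in each group by 3 log-units, and
#'   planted associations (6 positive within each group's signature set,
#'   6 negative across) at rho = 0.6 -- a scaled-down analogue of a
#'   two-habitat hindgut survey with compositionally distinct groups.
#'
#' @param name `"emulation"` or `"recovery"`.
#' @param seed integer seed forwarded to [make_truth()] and
#'   [simulate_counts()].
#' @return a `"synthetic_dataset"` (see [simulate_counts()]).
#' @export
synthetic_preset <- function(name = c("emulation", "recovery"), seed = 1) {
  name <- match.arg(name)
  if (name == "recovery") {
    truth <- make_truth(K = 50, n_pos_pairs = 5, n_neg_pairs = 0,
                        strength = 0.8, seed = seed,
                        depth_range = c(10000L, 122000L))
    simulate_counts(truth, c(200L, 0L), seed = seed)
  } else {
    truth <- make_truth(K = 100, n_pos_pairs = 12, n_neg_pairs = 6,
                        strength = 0.6, seed = seed, n_shifted = 20,
                        shift = 3, depth_range = c(10000L, 122000L))
    simulate_counts(truth, c(27L, 7L), seed = seed)
  }
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth:", x$K, "taxa,",
      nrow(x$pairs), "planted pair(s),",
      sum(x$affinity != "none"), "group-shifted taxa\n")
  invisible(x)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$table), "taxa x", ncol(x$table),
      "samples (", sum(x$metadata$group == "ciliate"), "ciliate /",
      sum(x$metadata$group == "gut"), "gut )\n")
  invisible(x)
}
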