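test_that("Dirichlet draws match the closed-form posterior mean", {
  m <- matrix(c(3L, 1L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  cfg <- posterior_config(seed = 5)
  draws <- sapply(1:10000, function(d) dirichlet_draw(m, cfg, d)[, 1])
  # posterior mean (n_i + alpha) / (N + K alpha) = (4/6, 2/6)
  expect_equal(unname(rowMeans(draws)), c(4 / 6, 2 / 6), tolerance = 0.01)
})

test_that("Dirichlet draws are simplex-valued and reproducible", {
  d <- synthetic_preset("recovery", seed = 2)
  cfg <- posterior_config(seed = 9)
  fr <- dirichlet_draw(d$table, cfg, 3)
  expect_equal(unname(colSums(fr)), rep(1, ncol(fr)), tolerance = 1e-9)
  expect_true(all(fr > 0))
  expect_identical(fr, dirichlet_draw(d$table, cfg, 3))
  expect_false(identical(fr, dirichlet_draw(d$table, cfg, 4)))
})

test_that("variation matrix matches hand-computed log-ratio variances", {
  # two samples in which the a/b fraction ratio is e and e^3:
  # Var[log ratio] = var(c(1, 3)) = 2
  f1 <- c(exp(1), 1, 1); f1 <- f1 / sum(f1)
  f2 <- c(exp(3), 1, 1); f2 <- f2 / sum(f2)
  fr <- cbind(f1, f2)
  rownames(fr) <- c("a", "b", "c")
  Tm <- variation_matrix(fr)
  expect_equal(Tm["a", "b"], 2)
  expect_equal(Tm, t(Tm))
  expect_equal(unname(diag(Tm)), rep(0, 3))
  # duplicated taxon: constant log ratio, zero variation
  fr2 <- rbind(fr, d = fr["a", ])
  fr2 <- sweep(fr2, 2, colSums(fr2), "/")
  expect_equal(variation_matrix(fr2)["a", "d"], 0, tolerance = 1e-14)
  expect_error(variation_matrix(cbind(c(0, 1), c(0.5, 0.5))), "positive")
})

test_that("basis variance solve agrees with an explicit matrix oracle", {
  set.seed(31)
  K <- 5
  for (rep in 1:5) {
    om2 <- runif(K, 0.5, 2)
    # variation matrix of exactly independent taxa: t_ij = w_i^2 + w_j^2
    Tm <- outer(om2, om2, "+")
    diag(Tm) <- 0
    rownames(Tm) <- colnames(Tm) <- paste0("t", 1:K)
    excl <- rbind(c(1L, 2L))
    for (ex in list(NULL, excl)) {
      fit <- basis_correlations(Tm, excluded = ex)
      # oracle: build the linear system with explicit loops and invert
      A <- matrix(0, K, K); b <- numeric(K)
      for (i in 1:K) for (j in 1:K) {
        if (i == j) next
        if (!is.null(ex) && any((ex[, 1] == i & ex[, 2] == j) |
                                (ex[, 1] == j & ex[, 2] == i))) next
        A[i, j] <- 1
        A[i, i] <- A[i, i] + 1
        b[i] <- b[i] + Tm[i, j]
      }
      oracle <- solve(A) %*% b
      expect_equal(unname(fit$omega2), drop(oracle), tolerance = 1e-8)
    }
  }
})

test_that("correlations have unit diagonal and small tables are rejected", {
  Tm <- outer(1:3, 1:3, "+") * 1.0
  diag(Tm) <- 0
  expect_error(basis_correlations(Tm), "at least 4 taxa")
  d <- independent_counts(6, 30, seed = 1)
  fit <- basis_correlations(variation_matrix(dirichlet_draw(d,
                                                            posterior_config(seed = 1))))
  expect_equal(unname(diag(fit$rho)), rep(1, 6))
  expect_equal(fit$rho, t(fit$rho))
  expect_true(all(abs(fit$rho) <= 1))
})

test_that("null correlations are centred at zero with bounded extremes", {
  # iid log-normal taxa: bound frozen from the estimator's sampling noise,
  # sd ~ sqrt(2/(n-1)) per pair, max over ~1.2k pairs
  d <- independent_counts(50, 500, seed = 21)
  fit <- sparcc_estimate(d, posterior_config(n_draws = 5, seed = 21),
                         refinement_config(enabled = FALSE))
  off <- fit$rho_mean[upper.tri(fit$rho_mean)]
  expect_lt(mean(abs(off)), 0.06)
  expect_lt(max(abs(off)), 0.3)
})

test_that("planted correlations are recovered on synthetic data", {
  d <- synthetic_preset("recovery", seed = 4)
  fit <- sparcc_estimate(d$table, posterior_config(n_draws = 20, seed = 4))
  planted <- as.matrix(d$truth$pairs[, c("i", "j")])
  expect_true(all(abs(fit$rho_mean[planted] - 0.8) < 0.15))
  # planted pairs dominate the top of the |rho| ranking
  ut <- which(upper.tri(fit$rho_mean))
  top10 <- ut[order(-abs(fit$rho_mean[ut]))[1:10]]
  planted_flat <- (planted[, 2] - 1) * nrow(fit$rho_mean) + planted[, 1]
  expect_true(all(planted_flat %in% top10))
})

test_that("a single draw without refinement equals the basic estimator", {
  d <- independent_counts(8, 25, seed = 6)
  cfg <- posterior_config(n_draws = 1, seed = 6)
  fit <- sparcc_estimate(d, cfg, refinement_config(enabled = FALSE))
  direct <- basis_correlations(variation_matrix(dirichlet_draw(d, cfg, 1)))
  expect_equal(fit$rho_mean, direct$rho, tolerance = 1e-12)
})

test_that("estimates are invariant to sample sequencing depth", {
  d <- independent_counts(10, 40, seed = 8)
  d10 <- d
  d10[, 1] <- d10[, 1] * 10L
  cfg <- posterior_config(n_draws = 10, seed = 8)
  r1 <- sparcc_estimate(d, cfg, refinement_config(enabled = FALSE))$rho_mean
  r2 <- sparcc_estimate(d10, cfg, refinement_config(enabled = FALSE))$rho_mean
  expect_lt(max(abs(r1 - r2)), 0.05)
})

test_that("permutation p-values hit the add-one floor for a duplicated taxon", {
  d <- independent_counts(9, 40, seed = 12)
  dup <- rbind(d, dup_a = d[1, ])
  rownames(dup)[10] <- "dup_a"
  cfg <- posterior_config(n_draws = 5, seed = 12)
  fit <- sparcc_estimate(dup, cfg, refinement_config(enabled = FALSE))
  expect_gt(fit$rho_mean[1, 10], 0.9)
  pv <- permutation_pvalues(dup, fit$rho_mean, n_perm = 50, seed = 12)
  expect_equal(pv[1, 10], 1 / 51)
  off <- pv[upper.tri(pv)]
  expect_true(all(off > 0 & off <= 1))
})
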