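make_model <- function(rho, omega2 = rep(1, nrow(rho))) {
  om <- sqrt(omega2)
  structure(list(omega2 = setNames(omega2, rownames(rho)), rho = rho,
                 cov = rho * tcrossprod(om), flagged = integer(0),
                 n_active_pairs = choose(nrow(rho), 2)),
            class = "basis_model")
}

test_that("pair covariances are ranked with deterministic tie-breaks", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[1, 3] <- rho[3, 1] <- -0.9
  rownames(rho) <- colnames(rho) <- c("a", "b", "c")
  pc <- pair_covariances(make_model(rho))
  expect_equal(pc$cov, c(0.9, 0, -0.9))
  expect_equal(pc$taxon_i, c("a", "b", "a"))
  expect_equal(pc$taxon_j, c("b", "c", "c"))

  # oracle equivalence on random models
  set.seed(17)
  for (rep in 1:20) {
    K <- 6
    R <- cov2cor(crossprod(matrix(rnorm(K * K), K)))
    rownames(R) <- colnames(R) <- paste0("t", 1:K)
    m <- make_model(R, runif(K, 0.5, 2))
    pc <- pair_covariances(m)
    up <- which(upper.tri(R), arr.ind = TRUE)
    cv <- m$cov[up]
    ord <- order(-cv, up[, 1], up[, 2])
    expect_equal(pc$cov, cv[ord])
    expect_equal(pc$i, unname(up[ord, 1]))
  }
})

test_that("batch size is the ceiling with a floor of one pair", {
  expect_equal(batch_size(choose(270, 2), 0.00025), 10)  # 36315 pairs
  expect_equal(batch_size(45, 0.00025), 1)
  expect_equal(batch_size(45, 1), 45)
})

test_that("total covariance sums absolute basis covariances", {
  rho <- diag(4)
  rownames(rho) <- colnames(rho) <- paste0("t", 1:4)
  expect_equal(total_covariance(make_model(rho)), 0)
  rho[1, 2] <- rho[2, 1] <- 0.3
  rho[3, 4] <- rho[4, 3] <- -0.2
  m <- make_model(rho)
  expect_equal(total_covariance(m), 0.5)
  # removing the largest-|c| pair can only decrease the statistic
  pairs <- upper.tri(rho)
  idx <- which(pairs, arr.ind = TRUE)
  expect_lt(total_covariance(m, idx[-which.max(abs(m$cov[idx])), ]),
            total_covariance(m, idx))
  expect_error(total_covariance(m, idx[0, ]), "empty")
})

test_that("disabling refinement reduces to a single fit", {
  d <- independent_counts(10, 30, seed = 14)
  Tm <- variation_matrix(dirichlet_draw(d, posterior_config(seed = 14)))
  rr <- iterative_refinement(Tm, refinement_config(enabled = FALSE))
  expect_equal(nrow(rr$excluded), 0)
  expect_equal(rr$stopped_reason, "disabled")
  expect_equal(rr$model$rho, basis_correlations(Tm)$rho)
})

test_that("planted strong pairs are excluded within the first iterations", {
  d <- synthetic_preset("recovery", seed = 5)
  Tm <- variation_matrix(dirichlet_draw(d$table, posterior_config(seed = 5)))
  rr <- iterative_refinement(Tm, refinement_config(max_iter = 5))
  planted <- as.matrix(d$truth$pairs[, c("i", "j")])
  excl_keys <- paste(rr$excluded[, 1], rr$excluded[, 2])
  expect_true(all(paste(planted[, 1], planted[, 2]) %in% excl_keys))
})

test_that("the active-pair covariance trace is non-increasing and the loop
          terminates by the window rule on random tables", {
  for (seed in 1:5) {
    d <- independent_counts(20, 40, seed = seed)
    Tm <- variation_matrix(dirichlet_draw(d, posterior_config(seed = seed)))
    rr <- iterative_refinement(Tm)
    expect_true(all(diff(rr$trace$total_covariance) <= 1e-6))
    expect_equal(rr$stopped_reason, "window_converged")
    expect_true(all(diff(rr$trace$n_excluded_cumulative) >= 0))
  }
})

test_that("refinement never flips the sign of a planted strong correlation", {
  d <- synthetic_preset("recovery", seed = 6)
  Tm <- variation_matrix(dirichlet_draw(d$table, posterior_config(seed = 6)))
  planted <- as.matrix(d$truth$pairs[, c("i", "j")])
  basic <- basis_correlations(Tm)
  rr <- iterative_refinement(Tm)
  expect_true(all(sign(rr$model$rho[planted]) == sign(basic$rho[planted])))
  expect_true(all(rr$model$rho[planted] > 0.5))
})

test_that("the active-pair floor stops refinement on tiny tables", {
  d <- independent_counts(5, 30, seed = 3)
  Tm <- variation_matrix(dirichlet_draw(d, posterior_config(seed = 3)))
  # K = 5: 10 pairs, floor 3*(K-1) = 12 > 10, so no exclusion is possible
  rr <- iterative_refinement(Tm, refinement_config(window = 2))
  expect_equal(nrow(rr$excluded), 0)
  expect_equal(rr$stopped_reason, "exhausted")
})
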