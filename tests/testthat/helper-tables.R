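# Shared fixtures, all built in code.

toy_table <- function() {
  m <- matrix(c(10L, 0L, 5L,
                90L, 20L, 5L,
                0L, 80L, 90L), nrow = 3, byrow = TRUE,
              dimnames = list(c("taxA", "taxB", "taxC"),
                              c("s1", "s2", "s3")))
  m
}

# iid log-normal basis closed to fractions and sampled multinomially:
# no true association between taxa.
independent_counts <- function(K, n, seed, depth = c(10000L, 122000L),
                               mu_sd = 1) {
  truth <- make_truth(K = K, n_pos_pairs = 0, n_neg_pairs = 0, seed = seed,
                      depth_range = depth, base_mean_sd = mu_sd)
  simulate_counts(truth, c(n, 0L), seed = seed)$table
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
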