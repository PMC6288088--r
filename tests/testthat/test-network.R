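toy_net_inputs <- function() {
  set.seed(51)
  K <- 5
  tab <- matrix(rpois(K * 6, 50) + 1L, K, 6,
                dimnames = list(paste0("t", 1:K), paste0("s", 1:6)))
  md <- data.frame(sample_id = paste0("s", 1:6),
                   group = rep(c("ciliate", "gut"), each = 3),
                   species_label = "x", country = "y",
                   stringsAsFactors = FALSE)
  rho <- diag(K)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[1, 3] <- rho[3, 1] <- -0.7
  rho[2, 4] <- rho[4, 2] <- 0.6
  rho[3, 5] <- rho[5, 3] <- 0.5      # exactly at the threshold: excluded
  rho[4, 5] <- rho[5, 4] <- 0.95     # will get p = 1: excluded
  pv <- matrix(0.001, K, K); diag(pv) <- NA
  pv[4, 5] <- pv[5, 4] <- 1
  dimnames(rho) <- dimnames(pv) <- dimnames(tab)[c(1, 1)]
  rownames(pv) <- colnames(pv) <- rownames(tab)
  rownames(rho) <- colnames(rho) <- rownames(tab)
  list(tab = tab, md = md, rho = rho, pv = pv)
}

test_that("abundance ratios match hand-computed group means", {
  x <- toy_net_inputs()
  fr <- relative_abundances(x$tab)
  r <- abundance_ratio(x$tab, x$md, pseudocount = 0)
  hand <- (rowMeans(fr[, 1:3])) / (rowMeans(fr[, 4:6]))
  expect_equal(unname(r), unname(hand))
  # equal group means give ratio 1
  tab_eq <- cbind(x$tab[, 1:3], x$tab[, 1:3])
  colnames(tab_eq) <- paste0("s", 1:6)
  expect_equal(unname(abundance_ratio(tab_eq, x$md)), rep(1, 5))
  # absence from one group stays finite via the pseudocount
  tab0 <- x$tab; tab0[1, 4:6] <- 0L
  expect_true(is.finite(abundance_ratio(tab0, x$md)[1]))
  expect_error(abundance_ratio(x$tab, transform(x$md, group = "ciliate")),
               "both groups")
})

test_that("edge selection is strict and matches a brute-force scan", {
  x <- toy_net_inputs()
  net <- build_network(x$rho, x$pv, x$tab, x$md, taxonomy = NULL)
  # brute-force oracle over all pairs
  expected <- list()
  for (i in 1:4) for (j in (i + 1):5)
    if (abs(x$rho[i, j]) > 0.5 && x$pv[i, j] < 0.05)
      expected[[length(expected) + 1]] <- c(i, j)
  expect_equal(nrow(net$edges), length(expected))  # 3 qualifying pairs
  expect_setequal(paste(net$edges$taxon_a, net$edges$taxon_b),
                  sapply(expected, function(p) paste0("t", p[1], " t", p[2])))
  # boundary cases excluded: rho = 0.5 exactly, and p = 1
  expect_false(any(net$edges$rho == 0.5))
  expect_false("t4 t5" %in% paste(net$edges$taxon_a, net$edges$taxon_b))
  # all-p-1 network has no edges but keeps all nodes
  pv1 <- x$pv; pv1[] <- 1
  net0 <- build_network(x$rho, pv1, x$tab, x$md, NULL)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(nrow(net0$nodes), 5)
})

test_that("node attributes carry abundance, taxonomy and group ratio", {
  x <- toy_net_inputs()
  taxonomy <- c(t1 = "Proteobacteria", t2 = "Bacteroidetes")
  net <- build_network(x$rho, x$pv, x$tab, x$md, taxonomy)
  expect_equal(net$nodes$phylum,
               c("Proteobacteria", "Bacteroidetes", rep("Unclassified", 3)))
  expect_equal(net$nodes$abundance,
               unname(rowMeans(relative_abundances(x$tab))))
  expect_equal(net$nodes$log2_ratio, log2(net$nodes$group_ratio))
  bad_rho <- x$rho[5:1, 5:1]
  expect_error(build_network(bad_rho, x$pv, x$tab, x$md, NULL), "match")
})

test_that("edge counts shrink monotonically as thresholds tighten", {
  x <- toy_net_inputs()
  n_edges <- function(r_thr, p_thr)
    nrow(build_network(x$rho, x$pv, x$tab, x$md, NULL,
                       network_config(r_thr, p_thr))$edges)
  expect_true(n_edges(0.4, 0.05) >= n_edges(0.6, 0.05))
  expect_true(n_edges(0.5, 0.05) >= n_edges(0.5, 0.001))
})

test_that("GraphML export round-trips node and edge counts and attributes", {
  x <- toy_net_inputs()
  net <- build_network(x$rho, x$pv, x$tab, x$md,
                       c(t1 = "Proteobacteria"))
  gml <- tempfile(fileext = ".graphml")
  edges <- tempfile(fileext = ".tsv")
  export_network(net, gml, edges)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(sort(igraph::E(g)$rho), sort(net$edges$rho))
  expect_equal(sort(igraph::V(g)$phylum), sort(net$nodes$phylum))
  el <- read.delim(edges)
  expect_equal(nrow(el), nrow(net$edges))
  expect_equal(sort(el$rho), sort(net$edges$rho))
  # empty network still exports valid GraphML
  pv1 <- x$pv; pv1[] <- 1
  net0 <- build_network(x$rho, pv1, x$tab, x$md, NULL)
  export_network(net0, gml)
  g0 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 5)
})
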