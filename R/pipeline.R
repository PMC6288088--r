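# End-to-end orchestration: filter -> diversity -> SparCC (+ refinement)
# -> permutation p-values -> TINA -> SMACOF -> network, with one global
# seed and a JSON manifest for provenance.

#' Run the full co-occurrence analysis pipeline
#'
#' Applies the abundance filter, computes per-sample diversity, estimates
#' the refined SparCC correlation matrix with permutation significance,
#' derives the TINA sample-similarity matrix and its SMACOF ordination,
#' builds the thresholded co-occurrence network, and writes every artifact
#' plus a JSON manifest to `outdir`.  All randomness is derived from
#' `seed` through named substreams, so a rerun with identical inputs and
#' configuration reproduces every output bit-exactly.
#'
#' @param table count matrix or path to a count TSV.
#' @param metadata metadata data.frame or path to a metadata TSV.
#' @param taxonomy optional named vector taxon id -> phylum, or path to a
#'   taxonomy TSV, or `NULL`.
#' @param outdir output directory (created if needed).
#' @param filter_threshold abundance filter threshold (default 0.001).
#' @param posterior a [posterior_config()]; its seed is overridden by a
#'   substream of `seed`.
#' @param refine a [refinement_config()].
#' @param mds an [mds_config()]; seed likewise derived from `seed`.
#' @param network a [network_config()].
#' @param n_perm permutations for the significance stage.
#' @param seed global integer seed.
#' @return the manifest, invisibly: a list with parameters, per-stage
#'   counts, artifact paths and md5 checksums (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(table, metadata, taxonomy = NULL, outdir,
                         filter_threshold = 0.001,
                         posterior = posterior_config(),
                         refine = refinement_config(),
                         mds = mds_config(),
                         network = network_config(),
                         n_perm = 100L, seed = 1L) {
  if (is.character(table)) table <- read_count_table(table)
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  if (is.character(taxonomy) && length(taxonomy) == 1 &&
      is.null(names(taxonomy)))
    taxonomy <- read_taxonomy_map(taxonomy)
  validate_count_table(table)
  if (!all(colnames(table) %in% metadata$sample_id))
    stop("metadata does not cover all samples", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(outdir, f)

  n_taxa_in <- nrow(table)
  filtered <- filter_by_abundance(table, filter_threshold)
  write_count_table(filtered, path("filtered_counts.tsv"))

  div <- diversity_table(filtered)
  utils::write.table(div, path("diversity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  posterior$seed <- derive_seed(seed, "pipeline-posterior")
  fit <- sparcc_estimate(filtered, posterior, refine)
  write_square_tsv(fit$rho_mean, path("sparcc_rho.tsv"))

  pvals <- permutation_pvalues(filtered, fit$rho_mean, n_perm = n_perm,
                               seed = derive_seed(seed, "pipeline-perm"),
                               prior_alpha = posterior$prior_alpha)
  write_square_tsv(pvals, path("sparcc_pvals.tsv"))

  s <- association_similarity(fit$rho_mean)
  tina <- tina_matrix(filtered, s)
  write_square_tsv(tina, path("tina_similarity.tsv"))

  mds$seed <- derive_seed(seed, "pipeline-mds")
  emb <- smacof_mds(to_dissimilarity(tina), mds)
  coords <- data.frame(sample_id = rownames(emb$coords), emb$coords,
                       row.names = NULL)
  colnames(coords)[-1] <- paste0("dim", seq_len(ncol(emb$coords)))
  utils::write.table(coords, path("mds_coordinates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  net <- build_network(fit$rho_mean, pvals, filtered, metadata, taxonomy,
                       network)
  export_network(net, path("network.graphml"), path("network_edges.tsv"))

  artifacts <- c("filtered_counts.tsv", "diversity.tsv", "sparcc_rho.tsv",
                 "sparcc_pvals.tsv", "tina_similarity.tsv",
                 "mds_coordinates.tsv", "network.graphml",
                 "network_edges.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("cooccurnet")),
    seed = seed,
    parameters = list(filter_threshold = filter_threshold,
                      posterior = unclass(posterior),
                      refine = unclass(refine),
                      mds = unclass(mds),
                      network = unclass(network),
                      n_perm = n_perm),
    counts = list(taxa_input = n_taxa_in, taxa_after_filter = nrow(filtered),
                  samples = ncol(filtered),
                  excluded_pairs_union = nrow(fit$excluded_pairs),
                  edges = nrow(net$edges),
                  edges_negative = sum(net$edges$sign == "negative"),
                  mds_stress = emb$stress),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(vapply(artifacts, path, ""))), artifacts))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Square matrix with ids as first column; values at full precision.
write_square_tsv <- function(m, path) {
  df <- data.frame(taxon_id = rownames(m),
                   format(m, digits = 15, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- "id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
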