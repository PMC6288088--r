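# Thresholded co-occurrence networks with abundance, taxonomy and
# group-affinity node attributes.

#' Configuration of network construction
#'
#' @param r_threshold edges require `|rho| > r_threshold` (strict; default
#'   0.5).
#' @param p_threshold edges require `p < p_threshold` (strict; default
#'   0.05).  No multiple-testing correction is applied by default;
#'   `adjust = "BH"` switches the p filter to Benjamini-Hochberg adjusted
#'   values.
#' @param ratio_pseudocount symmetric pseudocount added to both group mean
#'   abundances in [abundance_ratio()] so taxa absent from one group keep a
#'   finite ratio.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a list of class `"network_config"`.
#' @export
network_config <- function(r_threshold = 0.5, p_threshold = 0.05,
                           ratio_pseudocount = 1e-6,
                           adjust = c("none", "BH")) {
  if (r_threshold < 0 || r_threshold >= 1)
    stop("'r_threshold' must be in [0, 1)", call. = FALSE)
  if (p_threshold <= 0 || p_threshold > 1)
    stop("'p_threshold' must be in (0, 1]", call. = FALSE)
  structure(list(r_threshold = r_threshold, p_threshold = p_threshold,
                 ratio_pseudocount = ratio_pseudocount,
                 adjust = match.arg(adjust)), class = "network_config")
}

#' Ciliate-to-gut abundance ratio per taxon
#'
#' `(mean relative abundance over ciliate samples + pseudocount) /
#'  (mean over gut samples + pseudocount)` -- the group-affinity statistic
#' used to colour network nodes.  Values above 1 mark taxa enriched in the
#' ciliate samples, below 1 in the ciliate-free gut content.
#'
#' @param table validated count matrix.
#' @param metadata data.frame with `sample_id` and `group` covering every
#'   sample column; both groups must be non-empty.
#' @param pseudocount symmetric pseudocount (default 1e-6).
#' @return named numeric vector of ratios, one per taxon.
#' @export
abundance_ratio <- function(table, metadata, pseudocount = 1e-6) {
  fr <- relative_abundances(table)
  groups <- metadata$group[match(colnames(table), metadata$sample_id)]
  if (any(is.na(groups)))
    stop("metadata does not cover sample(s): ",
         paste(colnames(table)[is.na(groups)], collapse = ", "), call. = FALSE)
  if (!all(c("ciliate", "gut") %in% groups))
    stop("both groups ('ciliate' and 'gut') must have at least one sample",
         call. = FALSE)
  m_cil <- rowMeans(fr[, groups == "ciliate", drop = FALSE])
  m_gut <- rowMeans(fr[, groups == "gut", drop = FALSE])
  (m_cil + pseudocount) / (m_gut + pseudocount)
}

#' Build a thresholded co-occurrence network
#'
#' Edges are the taxon pairs with `|rho| > r_threshold` and
#' `p < p_threshold`, both strict.  Every taxon is retained as a node
#' (isolated or not) with its mean relative abundance across the full
#' dataset, its phylum (via `taxonomy`, `"Unclassified"` when absent), and
#' its ciliate-to-gut abundance ratio.
#'
#' @param rho correlation matrix aligned with the taxa of `table`.
#' @param pvals p-value matrix aligned likewise (diagonal ignored).
#' @param table validated count matrix.
#' @param metadata sample metadata (see [abundance_ratio()]).
#' @param taxonomy named character vector taxon id -> phylum, or `NULL`.
#' @param config a [network_config()].
#' @return an object of class `"cooccurrence_network"`: list with `nodes`
#'   (data.frame: `taxon_id`, `abundance`, `phylum`, `group_ratio`,
#'   `log2_ratio`), `edges` (data.frame: `taxon_a`, `taxon_b`, `rho`, `p`,
#'   `sign`), and `config`.
#' @export
build_network <- function(rho, pvals, table, metadata, taxonomy = NULL,
                          config = network_config()) {
  validate_count_table(table)
  ids <- rownames(table)
  for (m in list(rho = rho, pvals = pvals)) {
    if (!all(dim(m) == length(ids)))
      stop("matrix dimensions do not match the table's taxa", call. = FALSE)
  }
  if (!is.null(rownames(rho)) && !identical(rownames(rho), ids))
    stop("taxon ids of 'rho' do not match the table: ",
         paste(utils::head(setdiff(ids, rownames(rho)), 5), collapse = ", "),
         call. = FALSE)
  if (!is.null(rownames(pvals)) && !identical(rownames(pvals), ids))
    stop("taxon ids of 'pvals' do not match the table", call. = FALSE)

  fr <- relative_abundances(table)
  ratio <- abundance_ratio(table, metadata, config$ratio_pseudocount)
  phylum <- if (is.null(taxonomy)) rep("Unclassified", length(ids)) else {
    ph <- unname(taxonomy[ids])
    ph[is.na(ph)] <- "Unclassified"
    ph
  }
  nodes <- data.frame(taxon_id = ids, abundance = rowMeans(fr),
                      phylum = phylum, group_ratio = unname(ratio),
                      log2_ratio = unname(log2(ratio)),
                      stringsAsFactors = FALSE, row.names = NULL)

  up <- upper_pairs(length(ids))
  pv <- pvals[up]
  if (config$adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  keep <- abs(rho[up]) > config$r_threshold & pv < config$p_threshold &
    !is.na(pv)
  edges <- data.frame(taxon_a = ids[up[keep, 1]], taxon_b = ids[up[keep, 2]],
                      rho = rho[up][keep], p = pv[keep],
                      sign = ifelse(rho[up][keep] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges, config = config),
            class = "cooccurrence_network")
}

#' Export a network to GraphML and an edge-list TSV
#'
#' @param net a `"cooccurrence_network"`.
#' @param graphml_path output GraphML path (node attributes: abundance,
#'   phylum, group_ratio, log2_ratio; edge attributes: rho, p, sign).
#' @param edges_path optional path for a flat edge-list TSV.
#' @return `graphml_path`, invisibly.
#' @export
export_network <- function(net, graphml_path, edges_path = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- as_igraph(net)
  igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(graphml_path)
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param net a `"cooccurrence_network"`.
#' @return an undirected `igraph` graph carrying all node and edge
#'   attributes; isolated taxa are retained as vertices.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network:", nrow(x$nodes), "taxa,", nrow(x$edges),
      "edge(s) (", sum(x$edges$sign == "positive"), "positive /",
      sum(x$edges$sign == "negative"), "negative ) at |rho| >",
      x$config$r_threshold, "and p <", x$config$p_threshold, "\n")
  invisible(x)
}
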