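# Count-table input/output, relative abundances and the abundance filter.
#
# A count table is a plain integer matrix with taxa as rows and samples as
# columns, both dimensions named.  Keeping the container a base matrix keeps
# every downstream linear-algebra step direct; validation is explicit.

#' Validate a taxa-by-sample count table
#'
#' Checks the invariants every pipeline stage relies on: named, unique taxon
#' and sample identifiers; non-negative integer counts; no zero-depth sample.
#'
#' @param table numeric matrix, taxa as rows, samples as columns.
#' @return the table, invisibly, with counts coerced to storage mode integer
#'   -- or an error describing the first violated invariant.
#' @export
validate_count_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("count table must be a numeric matrix (taxa x samples)", call. = FALSE)
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop("count table must have taxon row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(table)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(table)[duplicated(rownames(table))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(table)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(table)[duplicated(colnames(table))]),
               collapse = ", "), call. = FALSE)
  bad <- which(table < 0 | table != round(table), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("count for taxon '%s' in sample '%s' is not a non-negative integer: %s",
                 rownames(table)[bad[1, 1]], colnames(table)[bad[1, 2]],
                 format(table[bad[1, , drop = FALSE]])), call. = FALSE)
  zero <- colSums(table) == 0
  if (any(zero))
    stop("sample(s) with zero total counts: ",
         paste(colnames(table)[zero], collapse = ", "), call. = FALSE)
  storage.mode(table) <- "integer"
  invisible(table)
}

#' Read a taxa-by-sample count table from a TSV file
#'
#' Expects a tab-separated file whose header row holds sample identifiers,
#' with taxon identifiers in the first column.  Row and column order are
#' preserved exactly as in the file; nothing is re-sorted.
#'
#' @param path path to a tab-separated count file.
#' @return integer matrix (taxa x samples) with dimnames.
#' @seealso [write_count_table()], [filter_by_abundance()]
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("count table needs a taxon-id column plus at least one sample column",
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric counts in ", path, call. = FALSE)
  rownames(m) <- as.character(df[[1]])
  validate_count_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count table to a TSV file
#'
#' Inverse of [read_count_table()]; integer tables round-trip bit-exactly.
#'
#' @param table validated count matrix.
#' @param path output path.
#' @param id_column header name for the taxon-id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, id_column = "taxon_id") {
  validate_count_table(table)
  df <- data.frame(rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `group`, `species_label`, `country`.
#' `group` must be one of `"ciliate"` (host-associated ciliate isolate) or
#' `"gut"` (ciliate-free hindgut content).
#'
#' @param path path to the metadata TSV.
#' @return data.frame with the four columns above.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "group", "species_label", "country")
  missing <- setdiff(needed, colnames(df))
  if (length(missing) > 0)
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$group), c("ciliate", "gut"))
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected 'ciliate' or 'gut'", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  df[, needed]
}

#' Read a taxon-to-phylum taxonomy map
#'
#' TSV with columns `taxon_id` and `phylum`.  Lookups for taxa absent from
#' the map resolve to `"Unclassified"` (see [build_network()]).
#'
#' @param path path to the taxonomy TSV.
#' @return named character vector, taxon id -> phylum.
#' @export
read_taxonomy_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "phylum") %in% colnames(df)))
    stop("taxonomy map needs columns 'taxon_id' and 'phylum'", call. = FALSE)
  stats::setNames(as.character(df$phylum), as.character(df$taxon_id))
}

#' Relative abundances of a count table
#'
#' Closes each sample column to 1, yielding the fraction matrix all
#' similarity stages operate on.
#'
#' @param table validated count matrix.
#' @return numeric matrix of the same shape; every column sums to 1.
#' @export
relative_abundances <- function(table) {
  validate_count_table(table)
  sweep(table, 2, colSums(table), "/")
}

#' Filter taxa by mean relative abundance
#'
#' Retains exactly the taxa whose relative abundance is strictly greater
#' than `threshold` (default 0.1%), the standard pre-filter before
#' correlation and similarity analyses.  By default abundance is the mean
#' relative abundance across all samples, producing one global taxon list;
#' `method = "max"` instead keeps taxa exceeding the threshold in at least
#' one sample.
#'
#' @param table validated count matrix.
#' @param threshold abundance threshold in `[0, 1)`; the comparison is
#'   strict, so a taxon at exactly the threshold is removed.
#' @param method `"mean"` (default) or `"max"` per-taxon summary of relative
#'   abundance.
#' @return the filtered count matrix; sample set unchanged, taxon order
#'   preserved.
#' @export
filter_by_abundance <- function(table, threshold = 0.001,
                                method = c("mean", "max")) {
  method <- match.arg(method)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 1)
    stop("'threshold' must be a single value in [0, 1)", call. = FALSE)
  fr <- relative_abundances(table)
  score <- if (method == "mean") rowMeans(fr) else apply(fr, 1, max)
  table[score > threshold, , drop = FALSE]
}
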