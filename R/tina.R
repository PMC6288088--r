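# Weighted Taxa INteraction-Adjusted (TINA) similarity between samples.
#
# Classical abundance-based similarity treats taxa as unrelated.  TINA
# weights shared abundance through a taxon-taxon association similarity
# derived from the correlation matrix, so samples dominated by different
# but positively associated taxa still score as similar.

#' Taxon association similarity from a correlation matrix
#'
#' Each taxon's association profile is its row of the correlation matrix
#' (its correlations to all taxa).  Profiles are compared pairwise by
#' Pearson correlation `r*` and rescaled to a similarity
#' `s = (1 + r*) / 2` in `[0, 1]`, so downstream TINA denominators stay
#' positive.  A taxon with a constant profile (zero variance) carries no
#' association information; its similarities are set to the uninformative
#' midpoint 0.5 and the taxon is flagged.
#'
#' @param rho symmetric correlation matrix with unit diagonal.
#' @param include_diagonal compare full rows including the self-entries
#'   (default); if `FALSE`, entries at positions i and j are dropped from
#'   both profiles before correlating pair (i, j).
#' @return K x K similarity matrix of class `"matrix"`, symmetric, unit
#'   diagonal, entries in `[0, 1]`; taxa with constant profiles listed in
#'   `attr(, "flagged")`.
#' @export
association_similarity <- function(rho, include_diagonal = TRUE) {
  check_symmetric(rho, name = "rho")
  K <- nrow(rho)
  if (include_diagonal) {
    sds <- apply(rho, 1, stats::sd)
    flagged <- which(sds == 0)
    rstar <- suppressWarnings(stats::cor(t(rho)))
    rstar[!is.finite(rstar)] <- 0   # constant-profile taxa: r* undefined
  } else {
    rstar <- diag(K)
    flagged <- integer(0)
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      keep <- setdiff(seq_len(K), c(i, j))
      a <- rho[i, keep]; b <- rho[j, keep]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        flagged <- union(flagged, c(i, j)[c(stats::sd(a) == 0, stats::sd(b) == 0)])
        rstar[i, j] <- rstar[j, i] <- 0
      } else {
        rstar[i, j] <- rstar[j, i] <- stats::cor(a, b)
      }
    }
  }
  s <- (1 + rstar) / 2
  if (length(flagged) > 0) {
    s[flagged, ] <- 0.5
    s[, flagged] <- 0.5
  }
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- dimnames(rho)
  attr(s, "flagged") <- flagged
  s
}

#' Weighted TINA similarity between two composition vectors
#'
#' `TINA(a, b) = (p_a' S p_b) / sqrt((p_a' S p_a) (p_b' S p_b))` -- a
#' cosine-type similarity in the inner product induced by the taxon
#' association similarity `S`.  With `S = I` it reduces exactly to cosine
#' similarity of the two compositions, and `TINA(a, a) = 1` always.
#'
#' @param p_a,p_b relative-abundance vectors over the taxa indexing `s`;
#'   each must sum to 1.
#' @param s taxon similarity matrix from [association_similarity()].
#' @return similarity in `(0, 1]` for non-negative `s`.
#' @export
tina_weighted <- function(p_a, p_b, s) {
  if (length(p_a) != nrow(s) || length(p_b) != nrow(s))
    stop("composition vectors must match the taxa of 's'", call. = FALSE)
  if (abs(sum(p_a) - 1) > 1e-6 || abs(sum(p_b) - 1) > 1e-6)
    stop("compositions must sum to 1", call. = FALSE)
  num <- drop(crossprod(p_a, s %*% p_b))
  da <- drop(crossprod(p_a, s %*% p_a))
  db <- drop(crossprod(p_b, s %*% p_b))
  if (da <= 0 || db <= 0)
    stop("zero TINA denominator: a sample's support aligns with an all-zero ",
         "block of the similarity matrix", call. = FALSE)
  num / sqrt(da * db)
}

#' Pairwise TINA similarity matrix of a count table
#'
#' @param table validated count matrix whose taxa match `s` exactly (same
#'   ids, same order).
#' @param s taxon similarity matrix from [association_similarity()].
#' @return n x n sample similarity matrix, symmetric with unit diagonal.
#' @export
tina_matrix <- function(table, s) {
  validate_count_table(table)
  if (!is.null(rownames(table)) && !is.null(rownames(s))) {
    if (!identical(rownames(table), rownames(s))) {
      bad <- union(setdiff(rownames(table), rownames(s)),
                   setdiff(rownames(s), rownames(table)))
      stop("taxa of table and similarity matrix differ",
           if (length(bad) > 0) paste0(": ", paste(utils::head(bad, 5),
                                                   collapse = ", ")) else
             " (same ids, different order)", call. = FALSE)
    }
  } else if (nrow(table) != nrow(s)) {
    stop("taxa of table and similarity matrix differ in number", call. = FALSE)
  }
  P <- relative_abundances(table)
  M <- crossprod(P, s %*% P)          # n x n quadratic forms
  d <- diag(M)
  if (any(d <= 0)) stop("zero TINA denominator", call. = FALSE)
  tina <- M / tcrossprod(sqrt(d))
  tina <- (tina + t(tina)) / 2
  diag(tina) <- 1
  dimnames(tina) <- list(colnames(table), colnames(table))
  tina
}
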