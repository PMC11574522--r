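#' Gene-gene Pearson correlation matrix
#'
#' Pairwise Pearson correlations of log-normalized expression across a
#' chosen cell subset. Genes with zero variance over the subset yield
#' undefined correlations; these are recorded as \code{NA} and the genes
#' are listed in the \code{"flagged"} attribute rather than silently set
#' to 0.
#'
#' @param norm normalized genes x cells matrix (see [log_normalize()]).
#' @param genes character vector of genes to include (default: all rows).
#' @param cells indices or names of the cell subset (default: all).
#' @param condition optional condition label attached to the result.
#' @return A symmetric matrix of class \code{"correlation_matrix"} with
#'   unit diagonal, plus attributes \code{condition} and \code{flagged}.
#' @export
pearson_matrix <- function(norm, genes = NULL, cells = NULL, condition = NA_character_) {
  if (is.null(genes)) genes <- rownames(norm)
  if (is.null(cells)) cells <- seq_len(ncol(norm))
  missing_genes <- setdiff(genes, rownames(norm))
  if (length(missing_genes))
    stop("genes not present in matrix: ", paste(missing_genes, collapse = ", "))
  x <- t(as.matrix(norm[genes, cells, drop = FALSE]))
  if (nrow(x) < 3) stop("need at least 3 cells to compute correlations")
  sds <- apply(x, 2, stats::sd)
  flagged <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x, method = "pearson"))
  diag(r) <- 1
  structure(r, class = c("correlation_matrix", "matrix"),
            condition = condition, flagged = flagged)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("gene-gene Pearson correlation matrix: %d genes%s\n", nrow(x),
              if (is.na(attr(x, "condition"))) ""
              else paste0(" (", attr(x, "condition"), ")")))
  fl <- attr(x, "flagged")
  if (length(fl)) cat("  zero-variance genes (NA entries):",
                      paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Dendrogram leaf order of a correlation matrix
#'
#' Agglomerative hierarchical clustering with Euclidean distance between
#' the rows of the correlation matrix and complete linkage; returns the
#' dendrogram leaf order. Ties in merge heights are broken by \code{hclust}
#' deterministically (lower original index merges first), so the ordering
#' is reproducible.
#'
#' @param corr a [pearson_matrix()] result without missing entries (drop
#'   flagged genes first).
#' @param method linkage method passed to [stats::hclust()].
#' @return An object of class \code{"cluster_ordering"}: the permuted gene
#'   ids plus the source condition and linkage description.
#' @export
hierarchical_order <- function(corr, method = "complete") {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (anyNA(corr)) {
    bad <- rownames(corr)[apply(is.na(corr), 1, any)]
    stop("correlation matrix has missing entries for: ",
         paste(bad, collapse = ", "), "; drop flagged genes first")
  }
  if (nrow(corr) == 1L) {
    ord <- rownames(corr)
  } else {
    hc <- stats::hclust(stats::dist(unclass(corr), method = "euclidean"),
                        method = method)
    ord <- rownames(corr)[hc$order]
  }
  structure(list(order = ord,
                 source_condition = attr(corr, "condition"),
                 linkage = sprintf("euclidean distance on correlation rows, %s linkage",
                                   method)),
            class = "cluster_ordering")
}

#' @export
print.cluster_ordering <- function(x, ...) {
  cat(sprintf("gene ordering of %d genes from condition %s (%s)\n",
              length(x$order), x$source_condition, x$linkage))
  invisible(x)
}

#' Apply a gene ordering to a correlation matrix
#'
#' Symmetric row/column permutation; values are untouched. Used to
#' transfer the leaf order computed in one condition onto the other
#' condition's matrix so gained or lost co-expression blocks line up.
#'
#' @param corr a [pearson_matrix()] result.
#' @param ordering a [hierarchical_order()] result covering exactly the
#'   genes of \code{corr}.
#' @return The reordered \code{correlation_matrix}.
#' @export
apply_ordering <- function(corr, ordering) {
  stopifnot(inherits(corr, "correlation_matrix"),
            inherits(ordering, "cluster_ordering"))
  if (!setequal(rownames(corr), ordering$order) ||
      length(ordering$order) != nrow(corr))
    stop("ordering does not cover exactly the matrix's genes; differs by: ",
         paste(union(setdiff(rownames(corr), ordering$order),
                     setdiff(ordering$order, rownames(corr))), collapse = ", "))
  out <- unclass(corr)[ordering$order, ordering$order]
  structure(out, class = c("correlation_matrix", "matrix"),
            condition = attr(corr, "condition"),
            flagged = attr(corr, "flagged"))
}

#' Within-set and set-to-background correlation scores
#'
#' Quantifies a co-expression block: the mean off-diagonal correlation
#' among the genes of \code{gene_set}, and the mean correlation between
#' the set and all remaining genes. Missing entries are excluded and
#' counted.
#'
#' @param corr a [pearson_matrix()] result.
#' @param gene_set at least two genes, all present in \code{corr}.
#' @return A list with \code{within}, \code{between}, and the number of
#'   missing entries excluded from each average.
#' @export
block_score <- function(corr, gene_set) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (length(gene_set) < 2) stop("gene_set must contain at least 2 genes")
  missing_genes <- setdiff(gene_set, rownames(corr))
  if (length(missing_genes))
    stop("genes not in matrix: ", paste(missing_genes, collapse = ", "))
  m <- unclass(corr)
  within_block <- m[gene_set, gene_set]
  w <- within_block[upper.tri(within_block)]
  rest <- setdiff(rownames(m), gene_set)
  b <- if (length(rest)) as.vector(m[gene_set, rest]) else numeric(0)
  list(within = mean(w, na.rm = TRUE),
       between = if (length(b)) mean(b, na.rm = TRUE) else NA_real_,
       n_missing_within = sum(is.na(w)),
       n_missing_between = sum(is.na(b)))
}
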