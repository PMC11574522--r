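#' Single-cell count matrix with cell and gene metadata
#'
#' Container for a genes x cells raw integer count matrix plus per-cell
#' metadata (condition, cluster, QC covariates) and per-gene metadata
#' (half-life, mitochondrial flag). QC covariates that are absent from
#' \code{cell_data} are recomputed from the matrix: \code{nFeature} as the
#' number of detected genes, \code{nCount} as the column total, and
#' \code{percent_mito} from the genes flagged \code{is_mito}. Studies whose
#' matrix is a gene panel rather than the whole transcriptome may instead
#' carry full-transcriptome QC covariates in \code{cell_data}, as produced
#' by upstream QC before gene subsetting; supplied values are kept as-is.
#'
#' @param counts genes x cells matrix (base or \pkg{Matrix} sparse) of
#'   nonnegative integer counts, with gene rownames and cell colnames.
#' @param cell_data data.frame of per-cell metadata, one row per column of
#'   \code{counts} (may be \code{NULL}).
#' @param gene_data data.frame of per-gene metadata, one row per row of
#'   \code{counts} (may be \code{NULL}).
#' @return An object of class \code{"sc_matrix"}.
#' @export
single_cell_matrix <- function(counts, cell_data = NULL, gene_data = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be nonnegative integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  if (is.null(gene_data))
    gene_data <- data.frame(gene_id = rownames(counts))
  if (is.null(gene_data$is_mito)) gene_data$is_mito <- grepl("^MT-", gene_data$gene_id)
  if (is.null(cell_data))
    cell_data <- data.frame(barcode = colnames(counts))
  if (nrow(cell_data) != ncol(counts) || nrow(gene_data) != nrow(counts))
    stop("metadata dimensions do not match the count matrix")
  if (is.null(cell_data$nFeature))
    cell_data$nFeature <- Matrix::colSums(counts > 0)
  if (is.null(cell_data$nCount))
    cell_data$nCount <- Matrix::colSums(counts)
  if (is.null(cell_data$percent_mito)) {
    tot <- Matrix::colSums(counts)
    mito <- if (any(gene_data$is_mito))
      Matrix::colSums(counts[gene_data$is_mito, , drop = FALSE]) else 0
    cell_data$percent_mito <- ifelse(tot > 0, 100 * mito / tot, 0)
  }
  structure(list(counts = counts, cell_data = cell_data, gene_data = gene_data),
            class = "sc_matrix")
}

#' @export
print.sc_matrix <- function(x, ...) {
  cat(sprintf("single-cell count matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$cell_data$condition))
    cat("  conditions:", paste(names(table(x$cell_data$condition)),
                               table(x$cell_data$condition),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.sc_matrix <- function(x) dim(x$counts)

subset_sc <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- seq_len(nrow(m$counts))
  if (is.null(cells)) cells <- seq_len(ncol(m$counts))
  structure(list(counts = m$counts[genes, cells, drop = FALSE],
                 cell_data = m$cell_data[cells, , drop = FALSE],
                 gene_data = m$gene_data[genes, , drop = FALSE]),
            class = "sc_matrix")
}

#' Remove low-quality cells
#'
#' Keeps cells with \code{nFeature < max_features},
#' \code{nCount < max_counts} and \code{percent_mito < max_mito_pct}
#' (all strict). The defaults are the conventional thresholds for deep
#' 10x runs on large cells: 12,000 detected genes, 150,000 UMIs, 8%
#' mitochondrial reads.
#'
#' @param m an [single_cell_matrix()] object.
#' @param max_features,max_counts,max_mito_pct strict upper bounds.
#' @return The filtered \code{sc_matrix}; the number of removed cells is
#'   reported via \code{message()}.
#' @export
filter_cells <- function(m, max_features = 12000, max_counts = 150000,
                         max_mito_pct = 8) {
  stopifnot(inherits(m, "sc_matrix"))
  cd <- m$cell_data
  keep <- cd$nFeature < max_features & cd$nCount < max_counts &
    cd$percent_mito < max_mito_pct
  message(sprintf("filter_cells: removed %d of %d cells", sum(!keep), length(keep)))
  subset_sc(m, cells = which(keep))
}

#' Remove genes detected in too few cells
#'
#' Keeps genes with nonzero counts in at least \code{min_cells} cells.
#' Applied after [filter_cells()] in the standard pipeline.
#'
#' @param m an [single_cell_matrix()] object.
#' @param min_cells minimum number of cells with nonzero counts.
#' @return The filtered \code{sc_matrix}.
#' @export
filter_genes <- function(m, min_cells = 10) {
  stopifnot(inherits(m, "sc_matrix"))
  ncells <- Matrix::rowSums(m$counts > 0)
  keep <- ncells >= min_cells
  message(sprintf("filter_genes: removed %d of %d genes", sum(!keep), length(keep)))
  subset_sc(m, genes = which(keep))
}

#' Standard preprocessing: cells first, then genes
#'
#' Fixed order mirroring the usual workflow: low-quality cells are removed
#' before the gene detection filter, so a gene's detection count is taken
#' over retained cells only.
#'
#' @param m an [single_cell_matrix()] object.
#' @param ... passed to [filter_cells()] and [filter_genes()].
#' @inheritParams filter_cells
#' @inheritParams filter_genes
#' @return The filtered \code{sc_matrix}.
#' @export
preprocess_cells_then_genes <- function(m, max_features = 12000,
                                        max_counts = 150000,
                                        max_mito_pct = 8, min_cells = 10) {
  filter_genes(filter_cells(m, max_features, max_counts, max_mito_pct),
               min_cells)
}

#' Log-normalize a count matrix
#'
#' The common single-cell convention: each cell is scaled to
#' \code{scale_factor} total counts, then \code{log(1 + x)} is applied,
#' i.e. \code{ln(1 + scale_factor * count / cell_total)}.
#'
#' @param m an [single_cell_matrix()] object.
#' @param scale_factor per-cell library-size target (default 10,000).
#' @return A sparse real-valued matrix with the dimensions of the counts.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "sc_matrix"))
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0))
    stop(sprintf("cells with zero total counts cannot be normalized: %s",
                 paste(colnames(m$counts)[tot == 0], collapse = ", ")))
  x <- m$counts %*% Matrix::Diagonal(x = scale_factor / tot)
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(m$counts)
  x
}
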