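#' Fit the telegraph model to every gene of a count matrix
#'
#' Runs [telegraph_fit()] per gene on the raw count histogram over the
#' selected cells, with the degradation rate fixed from the gene's
#' half-life. Genes with no half-life entry receive the cohort median
#' half-life, with a warning listing them. Per-gene seeds are derived
#' deterministically from \code{seed} and the gene index, so a rerun with
#' the same seed reproduces every fit.
#'
#' @param m an [single_cell_matrix()] object (already filtered).
#' @param half_lives data.frame with columns \code{gene_id} and
#'   \code{half_life} (minutes); defaults to \code{m$gene_data} when it
#'   carries a \code{half_life} column.
#' @param cells cell subset (indices or names); default all cells.
#' @param condition condition label stored in the results; default taken
#'   from the cell metadata when unique.
#' @param n_alleles gene copies assumed per cell.
#' @param n_steps,burn_in,prior_bounds Metropolis-Hastings settings, see
#'   [telegraph_fit()].
#' @param seed master seed for the per-gene chains.
#' @param genes optional subset of gene ids to fit.
#' @return A data.frame of class \code{"gene_fits"}: one row per gene with
#'   posterior medians and MADs of the rates, burst size and frequency,
#'   the observed mean expression, cell and allele counts, the QC verdict
#'   and chain diagnostics.
#' @export
fit_genes <- function(m, half_lives = NULL, cells = NULL, condition = NULL,
                      n_alleles = 2L, n_steps = 3000L, burn_in = 1000L,
                      prior_bounds = c(-4, 2), seed = 1L, genes = NULL) {
  stopifnot(inherits(m, "sc_matrix"))
  if (is.null(cells)) cells <- seq_len(ncol(m$counts))
  counts <- m$counts[, cells, drop = FALSE]
  if (is.null(condition)) {
    cond <- unique(m$cell_data$condition[cells])
    condition <- if (length(cond) == 1L) cond else NA_character_
  }
  if (is.null(genes)) genes <- rownames(counts)
  if (is.null(half_lives)) {
    if (is.null(m$gene_data$half_life))
      stop("supply half_lives or store a half_life column in gene_data")
    half_lives <- data.frame(gene_id = m$gene_data$gene_id,
                             half_life = m$gene_data$half_life)
  }
  hl <- stats::setNames(half_lives$half_life, half_lives$gene_id)[genes]
  if (anyNA(hl)) {
    miss <- genes[is.na(hl)]
    warning(sprintf("no half-life for %d gene(s) (%s); using the cohort median",
                    length(miss), paste(utils::head(miss, 5), collapse = ", ")))
    hl[is.na(hl)] <- stats::median(half_lives$half_life, na.rm = TRUE)
  }
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    cnt <- as.integer(counts[g, ])
    fit <- suppressWarnings(telegraph_fit(
      cnt, half_life = hl[[g]], n_alleles = n_alleles,
      prior_bounds = prior_bounds, n_steps = n_steps, burn_in = burn_in,
      seed = gene_seed(seed, i), gene_id = g, condition = condition))
    s <- fit$summaries
    med <- stats::setNames(s$median, s$quantity)
    mads <- stats::setNames(s$mad, s$quantity)
    rows[[i]] <- data.frame(
      gene_id = g, condition = condition,
      k_on_median = med[["k_on"]], k_on_mad = mads[["k_on"]],
      k_off_median = med[["k_off"]], k_off_mad = mads[["k_off"]],
      k_eject_median = med[["k_eject"]], k_eject_mad = mads[["k_eject"]],
      burst_size_median = med[["burst_size"]], burst_size_mad = mads[["burst_size"]],
      frequency_median = med[["frequency"]], frequency_mad = mads[["frequency"]],
      k_decay = fit$k_decay, mean_expression = fit$mean_expression,
      n_cells = fit$n_cells, n_alleles = fit$n_alleles,
      qc_pass = fit$qc_pass, acceptance_rate = fit$acceptance_rate,
      ess = fit$ess)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_fits", "data.frame")
  out
}

# deterministic 32-bit sub-seed from (master seed, index)
gene_seed <- function(seed, i) {
  (as.integer(seed) * 1103L + i * 12347L) %% 2147483629L
}

#' Write per-gene fit results to TSV and JSON
#'
#' @param fits a [fit_genes()] result.
#' @param path_tsv flat TSV output path (one row per gene).
#' @param path_json optional JSON output path (one record per gene).
#' @return \code{path_tsv}, invisibly.
#' @export
write_gene_fits <- function(fits, path_tsv, path_json = NULL) {
  utils::write.table(fits, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(fits, path_json, dataframe = "rows", digits = NA)
  invisible(path_tsv)
}
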