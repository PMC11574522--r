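#' Per-gene log2 fold changes between two fitted conditions
#'
#' For each gene passing QC in both conditions, computes
#' \code{log2(treated/control)} of three quantities: observed mean
#' expression, burst frequency (posterior median of the ON rate) and burst
#' size (posterior median of eject/OFF). Genes failing QC in either
#' condition are excluded; genes with a nonpositive control median are
#' skipped with a message.
#'
#' @param fits_treated,fits_control [fit_genes()] results keyed by
#'   \code{gene_id}.
#' @return A data.frame with one row per retained gene:
#'   \code{log2FC_expression}, \code{log2FC_frequency},
#'   \code{log2FC_burst_size}, and \code{qc_pass_both} (always TRUE for
#'   emitted rows).
#' @export
log2_fold_changes <- function(fits_treated, fits_control) {
  common <- intersect(fits_treated$gene_id, fits_control$gene_id)
  tr <- fits_treated[match(common, fits_treated$gene_id), ]
  ct <- fits_control[match(common, fits_control$gene_id), ]
  keep <- tr$qc_pass & ct$qc_pass
  tr <- tr[keep, ]; ct <- ct[keep, ]
  bad <- ct$mean_expression <= 0 | ct$frequency_median <= 0 |
    ct$burst_size_median <= 0 | tr$mean_expression <= 0
  if (any(bad))
    message(sprintf("skipping %d gene(s) with nonpositive control medians: %s",
                    sum(bad), paste(utils::head(tr$gene_id[bad], 5), collapse = ", ")))
  tr <- tr[!bad, ]; ct <- ct[!bad, ]
  data.frame(
    gene_id = tr$gene_id,
    log2FC_expression = log2(tr$mean_expression / ct$mean_expression),
    log2FC_frequency = log2(tr$frequency_median / ct$frequency_median),
    log2FC_burst_size = log2(tr$burst_size_median / ct$burst_size_median),
    qc_pass_both = TRUE)
}

#' Rank-sum comparison of a gene signature against the background
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test comparing a quantity's
#' log2 fold changes between the signature genes and all other genes in
#' \code{records}. The exact null distribution is used for combined sample
#' sizes up to 25 without ties; otherwise the normal approximation with
#' tie correction.
#'
#' @param records a [log2_fold_changes()] result.
#' @param signature character vector of signature gene ids.
#' @param quantity one of \code{"expression"}, \code{"frequency"},
#'   \code{"burst_size"}.
#' @return A list of class \code{"geneset_comparison"}: group sizes, the
#'   rank-sum statistic, the two-sided p-value, and each group's median
#'   log2 fold change.
#' @export
wilcoxon_geneset <- function(records, signature,
                             quantity = c("expression", "frequency", "burst_size")) {
  quantity <- match.arg(quantity)
  col <- paste0("log2FC_", quantity)
  in_sig <- records$gene_id %in% signature
  x <- records[[col]][in_sig]
  y <- records[[col]][!in_sig]
  if (length(x) < 2 || length(y) < 2)
    stop(sprintf("need at least 2 genes per group (signature %d, background %d)",
                 length(x), length(y)))
  use_exact <- (length(x) + length(y) <= 25) && !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                           correct = !use_exact)
  structure(list(
    quantity = quantity, signature = signature,
    n_signature = length(x), n_background = length(y),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    exact = use_exact,
    median_signature = stats::median(x), median_background = stats::median(y)),
    class = "geneset_comparison")
}

#' @export
print.geneset_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum, log2FC(%s): signature n=%d (median %.3f) vs background n=%d (median %.3f)\n",
              x$quantity, x$n_signature, x$median_signature,
              x$n_background, x$median_background))
  cat(sprintf("  W = %g, two-sided p = %.3g (%s)\n", x$statistic, x$p_value,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' Ploidy sensitivity of the burst-size comparison
#'
#' Refits the treated condition assuming each allele count in
#' \code{allele_grid} (the control stays at \code{control_alleles}),
#' recomputes fold changes, and repeats the signature-vs-background
#' rank-sum test for each quantity. Used to check that the burst-size
#' conclusion does not hinge on the assumed ploidy of treated cells.
#'
#' @param m_treated,m_control filtered [single_cell_matrix()] objects for
#'   the two conditions.
#' @param signature signature gene ids.
#' @param half_lives data.frame with \code{gene_id}, \code{half_life}.
#' @param allele_grid treated-cell allele counts to assume.
#' @param control_alleles allele count for the control fits.
#' @param seed master seed (shared across refits so the allele assumption
#'   is the only difference).
#' @param ... further arguments passed to [fit_genes()].
#' @return A data.frame with one row per (allele count, quantity):
#'   p-values, medians and group sizes, plus attribute
#'   \code{"burst_size_invariant"} stating whether the signature shows a
#'   significantly larger burst size at every ploidy assumption.
#' @export
ploidy_sensitivity <- function(m_treated, m_control, signature,
                               half_lives = NULL, allele_grid = c(2, 4, 8, 16),
                               control_alleles = 2L, seed = 1L, ...) {
  fits_control <- fit_genes(m_control, half_lives = half_lives,
                            n_alleles = control_alleles, seed = seed, ...)
  rows <- list()
  for (al in allele_grid) {
    fits_treated <- fit_genes(m_treated, half_lives = half_lives,
                              n_alleles = as.integer(al), seed = seed, ...)
    fc <- log2_fold_changes(fits_treated, fits_control)
    for (q in c("expression", "frequency", "burst_size")) {
      cmp <- wilcoxon_geneset(fc, signature, q)
      rows[[length(rows) + 1L]] <- data.frame(
        n_alleles_treated = al, quantity = q, p_value = cmp$p_value,
        median_signature = cmp$median_signature,
        median_background = cmp$median_background,
        n_signature = cmp$n_signature, n_background = cmp$n_background)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bs <- out[out$quantity == "burst_size", ]
  attr(out, "burst_size_invariant") <-
    all(bs$p_value < 0.05 & bs$median_signature > bs$median_background)
  out
}
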