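#' Configuration of a synthetic two-condition bursting study
#'
#' Parameters of the generator in [generate_study()], emulating a
#' two-condition (untreated vs drug-treated) single-cell experiment on the
#' proliferative cell cluster, in which a small interferon-related gene
#' signature is upregulated in the treated condition through an increase
#' in transcriptional burst size and is coupled cell-to-cell by a shared
#' extrinsic factor.
#'
#' @param n_genes_background number of unperturbed background genes.
#' @param signature_genes ids of the signature genes (defaults to the
#'   twelve interferon-stimulated genes of the U-ISGF3 signature).
#' @param n_cells cells per condition.
#' @param burst_size_multiplier factor applied to the signature genes'
#'   ejection rate (hence burst size) in the treated condition.
#' @param coupling_strength log-scale standard deviation of the shared
#'   per-cell extrinsic factor multiplying signature ejection rates in the
#'   treated condition (0 disables coupling).
#' @param dropout_rate optional binomial capture loss applied to all
#'   counts (0 disables).
#' @param halflife_meanlog,halflife_sdlog log-normal parameters of the
#'   per-gene mRNA half-life distribution, minutes (median 300 min).
#' @param ploidy gene copies per cell used to draw counts.
#' @param aberrant_fraction fraction of cells planted to violate exactly
#'   one cell-QC threshold each.
#' @param k_on_range,burst_size_range log-uniform draw ranges for the
#'   activation rate (per minute) and burst size.
#' @param mean_range log-uniform range of each gene's target mean
#'   expression (counts per cell); capped at 80% of the mean attainable
#'   given the gene's drawn activation rate and burst size.
#' @param seed master seed; a fixed seed yields a bit-identical study.
#' @return A validated list of class \code{"study_config"}.
#' @export
study_config <- function(n_genes_background = 300L,
                         signature_genes = c("DDX58", "DDX60", "EPSTI1",
                                             "HERC5", "HERC6", "IFI27",
                                             "IFI35", "IFIH1", "IRF7",
                                             "OASL", "PLSCR1", "STAT1"),
                         n_cells = 3000L,
                         burst_size_multiplier = 3,
                         coupling_strength = 0.5,
                         dropout_rate = 0,
                         halflife_meanlog = log(300), halflife_sdlog = 0.4,
                         ploidy = 2L,
                         aberrant_fraction = 0.05,
                         k_on_range = c(0.003, 0.3),
                         burst_size_range = c(1, 20),
                         mean_range = c(0.5, 50),
                         seed = 1L) {
  cfg <- list(n_genes_background = as.integer(n_genes_background),
              signature_genes = signature_genes,
              n_cells = as.integer(n_cells),
              burst_size_multiplier = burst_size_multiplier,
              coupling_strength = coupling_strength,
              dropout_rate = dropout_rate,
              halflife_meanlog = halflife_meanlog,
              halflife_sdlog = halflife_sdlog,
              ploidy = as.integer(ploidy),
              aberrant_fraction = aberrant_fraction,
              k_on_range = k_on_range, burst_size_range = burst_size_range,
              mean_range = mean_range, seed = as.integer(seed))
  if (cfg$n_genes_background < 1 || cfg$n_cells < 10)
    stop("need at least 1 background gene and 10 cells")
  if (cfg$burst_size_multiplier <= 0) stop("burst_size_multiplier must be > 0")
  if (cfg$coupling_strength < 0) stop("coupling_strength must be >= 0")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (cfg$aberrant_fraction < 0 || cfg$aberrant_fraction > 0.5)
    stop("aberrant_fraction must be in [0, 0.5]")
  if (cfg$ploidy < 1) stop("ploidy must be >= 1")
  for (nm in c("k_on_range", "burst_size_range", "mean_range"))
    if (any(cfg[[nm]] <= 0) || diff(cfg[[nm]]) < 0)
      stop(nm, " must be positive and increasing")
  structure(cfg, class = "study_config")
}

mito_decoy_genes <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                      "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                      "MT-ND5", "MT-ND6", "MT-CYB")

runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate a synthetic two-condition bursting study with known truth
#'
#' Draws per-gene telegraph rates once and shares them across conditions;
#' signature genes additionally get their ejection rate multiplied by
#' \code{burst_size_multiplier} in the treated condition (burst size scales
#' accordingly, OFF rate fixed) and, in the treated condition only, share a
#' per-cell log-normal extrinsic factor on the ejection rate that induces
#' positive pairwise co-expression. Counts are drawn per allele from the
#' stationary Beta-Poisson law. Mitochondrial decoy genes are included so
#' the mitochondrial fraction is computable from the panel, and a planted
#' fraction of cells violates exactly one cell-QC threshold each.
#'
#' Because the gene panel is small, the per-cell QC covariates
#' (\code{nFeature}, \code{nCount}, \code{percent_mito}) are carried as
#' full-transcriptome metadata of the kind upstream QC produces before
#' gene subsetting; the planted violators exceed one threshold each in
#' that metadata (mito violators also get their panel mito counts
#' inflated).
#'
#' @param config a [study_config()].
#' @return A list of class \code{"burst_study"}: \code{untreated} and
#'   \code{treated} [single_cell_matrix()] objects, \code{half_lives}
#'   (data.frame), and \code{ground_truth} (per-gene rates per condition,
#'   signature membership, per-cell extrinsic factors, planted aberrant
#'   cells).
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  n_sig <- length(config$signature_genes)
  genes <- c(sprintf("GENE%04d", seq_len(config$n_genes_background)),
             config$signature_genes, mito_decoy_genes)
  n_genes <- length(genes)
  is_sig <- genes %in% config$signature_genes
  is_mito <- genes %in% mito_decoy_genes

  half_life <- stats::rlnorm(n_genes, config$halflife_meanlog, config$halflife_sdlog)
  k_decay <- decay_from_halflife(half_life)
  burst <- runif_log(n_genes, config$burst_size_range)
  mean_target <- runif_log(n_genes, config$mean_range)
  # mito decoys: modest stable expression so the mito fraction sits at a
  # few percent in normal cells
  burst[is_mito] <- runif_log(sum(is_mito), c(1, 2))
  mean_target[is_mito] <- runif_log(sum(is_mito), c(2, 6))
  # OFF-dominated promoters (k_off several-fold above k_on), the regime
  # live-cell imaging and transcriptome-wide kinetic fits report for
  # mammalian genes; the activation rate is then set by the target mean
  # within its draw range, mean = ploidy * burst * k_on/k_decay * b/(a+b)
  off_ratio <- runif_log(n_genes, c(3, 30))
  f_on <- 1 / (1 + off_ratio)
  k_on_needed <- mean_target * k_decay /
    (config$ploidy * burst * off_ratio * f_on)
  k_on <- pmin(pmax(k_on_needed, config$k_on_range[1]), config$k_on_range[2])
  k_off <- off_ratio * k_on
  k_eject <- burst * k_off

  rates_control <- data.frame(gene_id = genes, k_on = k_on, k_off = k_off,
                              k_eject = k_eject, k_decay = k_decay,
                              burst_size = k_eject / k_off,
                              mean_expression = config$ploidy *
                                (k_eject / k_decay) * k_on / (k_on + k_off))
  rates_treated <- rates_control
  rates_treated$k_eject[is_sig] <- rates_treated$k_eject[is_sig] *
    config$burst_size_multiplier
  rates_treated$burst_size <- rates_treated$k_eject / rates_treated$k_off
  rates_treated$mean_expression <- config$ploidy *
    (rates_treated$k_eject / rates_treated$k_decay) *
    rates_treated$k_on / (rates_treated$k_on + rates_treated$k_off)

  draw_condition <- function(rates, condition, extrinsic) {
    n_cells <- config$n_cells
    counts <- matrix(0L, n_genes, n_cells,
                     dimnames = list(genes,
                                     sprintf("%s_cell%04d", condition, seq_len(n_cells))))
    for (g in seq_len(n_genes)) {
      f <- if (is_sig[g] && !is.null(extrinsic)) extrinsic else NULL
      counts[g, ] <- bp_sample(rates$k_on[g] / rates$k_decay[g],
                               rates$k_off[g] / rates$k_decay[g],
                               rates$k_eject[g] / rates$k_decay[g],
                               n_cells, config$ploidy, f)
    }
    if (config$dropout_rate > 0) {
      kept <- stats::rbinom(length(counts), as.vector(counts),
                            1 - config$dropout_rate)
      counts <- matrix(kept, n_genes, n_cells, dimnames = dimnames(counts))
    }
    counts
  }

  plant_aberrant <- function(counts, condition) {
    n_cells <- ncol(counts)
    n_ab <- round(config$aberrant_fraction * n_cells)
    ab_idx <- if (n_ab > 0) sort(sample.int(n_cells, n_ab)) else integer(0)
    ab_type <- rep(c("feature", "count", "mito"), length.out = n_ab)
    nFeature <- round(stats::runif(n_cells, 7000, 11000))
    nCount <- round(nFeature * stats::runif(n_cells, 6, 12))
    percent_mito <- stats::runif(n_cells, 1, 5)
    nFeature[ab_idx[ab_type == "feature"]] <-
      round(stats::runif(sum(ab_type == "feature"), 12000, 16000))
    nCount[ab_idx[ab_type == "count"]] <-
      round(stats::runif(sum(ab_type == "count"), 150000, 250000))
    percent_mito[ab_idx[ab_type == "mito"]] <-
      stats::runif(sum(ab_type == "mito"), 9, 20)
    # point the panel's own mito signal the same way for mito violators
    mito_cells <- ab_idx[ab_type == "mito"]
    if (length(mito_cells))
      counts[is_mito, mito_cells] <- counts[is_mito, mito_cells] * 10L
    cell_data <- data.frame(
      barcode = colnames(counts), condition = condition, cluster = "1",
      nFeature = nFeature, nCount = nCount, percent_mito = percent_mito,
      aberrant = seq_len(n_cells) %in% ab_idx,
      aberrant_type = ifelse(seq_len(n_cells) %in% ab_idx,
                             ab_type[match(seq_len(n_cells), ab_idx)], "none"))
    list(counts = counts, cell_data = cell_data)
  }

  gene_data <- data.frame(gene_id = genes, half_life = half_life,
                          is_mito = is_mito, is_signature = is_sig)

  cu <- draw_condition(rates_control, "untreated", NULL)
  au <- plant_aberrant(cu, "untreated")
  extrinsic <- if (config$coupling_strength > 0)
    stats::rlnorm(config$n_cells, -config$coupling_strength^2 / 2,
                  config$coupling_strength)
  else NULL
  ct <- draw_condition(rates_treated, "dox", extrinsic)
  at <- plant_aberrant(ct, "dox")

  untreated <- single_cell_matrix(Matrix::Matrix(au$counts, sparse = TRUE),
                                  au$cell_data, gene_data)
  treated <- single_cell_matrix(Matrix::Matrix(at$counts, sparse = TRUE),
                                at$cell_data, gene_data)
  truth <- list(
    rates_control = rates_control, rates_treated = rates_treated,
    signature_genes = config$signature_genes, mito_genes = mito_decoy_genes,
    extrinsic_factor_treated = extrinsic,
    aberrant_untreated = au$cell_data$barcode[au$cell_data$aberrant],
    aberrant_treated = at$cell_data$barcode[at$cell_data$aberrant],
    config = unclass(config))
  structure(list(untreated = untreated, treated = treated,
                 half_lives = data.frame(gene_id = genes, half_life = half_life),
                 ground_truth = truth, config = config),
            class = "burst_study")
}

#' @export
print.burst_study <- function(x, ...) {
  cat(sprintf("synthetic bursting study: %d genes (%d signature, %d mito decoys), %d cells/condition, seed %d\n",
              nrow(x$untreated$counts), length(x$config$signature_genes),
              length(x$ground_truth$mito_genes), x$config$n_cells,
              x$config$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Layout: one directory per condition (\code{untreated/}, \code{dox/})
#' with \code{matrix.mtx}, \code{features.tsv} and \code{barcodes.tsv};
#' plus \code{cell_metadata.tsv}, \code{gene_metadata.tsv},
#' \code{half_lives.tsv} and \code{ground_truth.json} at the top level.
#' Output is byte-identical for a fixed study.
#'
#' @param study a [generate_study()] result.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @seealso [read_study()]
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "burst_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, path) utils::write.table(d, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  for (cond in c("untreated", "treated")) {
    m <- study[[cond]]
    sub <- file.path(out_dir, if (cond == "treated") "dox" else "untreated")
    dir.create(sub, showWarnings = FALSE)
    Matrix::writeMM(m$counts, file.path(sub, "matrix.mtx"))
    writeLines(rownames(m$counts), file.path(sub, "features.tsv"))
    writeLines(colnames(m$counts), file.path(sub, "barcodes.tsv"))
  }
  tsv(rbind(study$untreated$cell_data, study$treated$cell_data),
      file.path(out_dir, "cell_metadata.tsv"))
  tsv(study$untreated$gene_data, file.path(out_dir, "gene_metadata.tsv"))
  tsv(study$half_lives, file.path(out_dir, "half_lives.tsv"))
  jsonlite::write_json(study$ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir directory produced by [write_study()].
#' @return A list with \code{untreated} and \code{treated}
#'   [single_cell_matrix()] objects and the \code{half_lives} data.frame.
#' @export
read_study <- function(dir) {
  cell_data <- utils::read.delim(file.path(dir, "cell_metadata.tsv"))
  gene_data <- utils::read.delim(file.path(dir, "gene_metadata.tsv"))
  half_lives <- utils::read.delim(file.path(dir, "half_lives.tsv"))
  read_one <- function(sub, cond) {
    counts <- methods::as(Matrix::readMM(file.path(sub, "matrix.mtx")), "CsparseMatrix")
    rownames(counts) <- readLines(file.path(sub, "features.tsv"))
    colnames(counts) <- readLines(file.path(sub, "barcodes.tsv"))
    cd <- cell_data[cell_data$condition == cond, , drop = FALSE]
    cd <- cd[match(colnames(counts), cd$barcode), , drop = FALSE]
    rownames(cd) <- NULL
    single_cell_matrix(counts, cd, gene_data)
  }
  list(untreated = read_one(file.path(dir, "untreated"), "untreated"),
       treated = read_one(file.path(dir, "dox"), "dox"),
       half_lives = half_lives)
}
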