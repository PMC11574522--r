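# Expensive end-to-end objects are computed once per test run and shared
# across test files (test_dir runs everything in one process).
.burstfit_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .burstfit_cache))
    assign(name, expr, envir = .burstfit_cache)
  get(name, envir = .burstfit_cache)
}

# the default synthetic study pushed through the whole workflow
default_study_result <- function() {
  cached("study_result",
         suppressWarnings(suppressMessages(
           run_bursting_study(study_config(seed = 42), seed = 7))))
}

# the parameter-recovery suite at its standard settings
recovery_result <- function() {
  cached("recovery", suppressWarnings(recovery_suite(seed = 3)))
}

# small two-condition study for the ploidy refits
ploidy_result <- function() {
  cached("ploidy", {
    cfg <- study_config(n_genes_background = 60L, n_cells = 1000L, seed = 5)
    study <- generate_study(cfg)
    mu <- suppressMessages(preprocess_cells_then_genes(study$untreated))
    mt <- suppressMessages(preprocess_cells_then_genes(study$treated))
    panel <- setdiff(intersect(rownames(mu$counts), rownames(mt$counts)),
                     study$ground_truth$mito_genes)
    suppressWarnings(suppressMessages(ploidy_sensitivity(
      mt, mu, cfg$signature_genes, half_lives = study$half_lives,
      allele_grid = c(2, 4, 8, 16), seed = 9, n_steps = 2400L,
      burn_in = 1200L, genes = panel)))
  })
}

# longest run of consecutive leaf positions occupied by the gene set
longest_contiguous <- function(ordering, genes) {
  pos <- sort(match(genes, ordering))
  if (!length(pos)) return(0L)
  runs <- rle(c(TRUE, diff(pos) == 1))
  max(runs$lengths[runs$values])
}

# tiny sc_matrix builder for filter fixtures
make_sc <- function(counts, nFeature = NULL, nCount = NULL, pmito = NULL,
                    condition = "untreated") {
  cd <- data.frame(barcode = colnames(counts), condition = condition,
                   cluster = "1")
  if (!is.null(nFeature)) cd$nFeature <- nFeature
  if (!is.null(nCount)) cd$nCount <- nCount
  if (!is.null(pmito)) cd$percent_mito <- pmito
  single_cell_matrix(counts, cd)
}
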