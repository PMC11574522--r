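small_config <- function(...) {
  study_config(n_genes_background = 40L, n_cells = 400L, seed = 11, ...)
}

test_that("configuration validation rejects out-of-range settings", {
  expect_error(study_config(dropout_rate = 1), "dropout")
  expect_error(study_config(burst_size_multiplier = 0), "multiplier")
  expect_error(study_config(aberrant_fraction = 0.9), "aberrant")
  expect_error(study_config(k_on_range = c(0.3, 0.003)), "k_on_range")
})

test_that("a fixed seed yields a bit-identical study and identical files", {
  s1 <- generate_study(small_config())
  s2 <- generate_study(small_config())
  expect_identical(s1$untreated$counts, s2$untreated$counts)
  expect_identical(s1$treated$counts, s2$treated$counts)
  expect_identical(s1$ground_truth$rates_treated, s2$ground_truth$rates_treated)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  write_study(s1, d1)
  write_study(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("generated counts match the telegraph means they were drawn from", {
  cfg <- study_config(n_genes_background = 50L, n_cells = 2000L, seed = 19,
                      aberrant_fraction = 0)
  study <- generate_study(cfg)
  truth <- study$ground_truth$rates_control
  idx <- which(!study$untreated$gene_data$is_mito)[1:20]
  for (i in idx) {
    d <- dimensionless_rates(telegraph_rates(truth$k_on[i], truth$k_off[i],
                                             truth$k_eject[i], truth$k_decay[i]))
    mom <- burstfit:::telegraph_moments(d$a, d$b, d$lam)
    se <- sqrt(cfg$ploidy * mom$var / cfg$n_cells)
    obs <- mean(study$untreated$counts[i, ])
    expect_lt(abs(obs - cfg$ploidy * mom$mean), 3.5 * se)
  }
})

test_that("planted aberrant cells are exactly the cells the QC filter removes", {
  study <- generate_study(small_config())
  for (cond in c("untreated", "treated")) {
    m <- study[[cond]]
    kept <- suppressMessages(filter_cells(m))
    removed <- setdiff(colnames(m$counts), colnames(kept$counts))
    expect_setequal(removed, m$cell_data$barcode[m$cell_data$aberrant])
  }
})

test_that("a written study round-trips losslessly through the reader", {
  study <- generate_study(small_config())
  dir <- file.path(tempdir(), "roundtrip")
  write_study(study, dir)
  back <- read_study(dir)
  expect_equal(as.matrix(back$untreated$counts),
               as.matrix(study$untreated$counts))
  expect_equal(as.matrix(back$treated$counts),
               as.matrix(study$treated$counts))
  expect_identical(back$untreated$cell_data$barcode,
                   study$untreated$cell_data$barcode)
  expect_equal(back$half_lives$half_life, study$half_lives$half_life,
               tolerance = 1e-9)
  # features file covers background + signature + mito decoys
  n_genes <- length(readLines(file.path(dir, "untreated", "features.tsv")))
  expect_identical(n_genes, nrow(study$untreated$counts))
  # ground truth is valid JSON with the promised fields
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_true(all(c("rates_control", "rates_treated", "signature_genes",
                    "aberrant_untreated", "config") %in% names(gt)))
})

test_that("without coupling the signature shows no co-expression block", {
  cfg <- study_config(n_genes_background = 50L, n_cells = 800L, seed = 23,
                      coupling_strength = 0, aberrant_fraction = 0)
  study <- generate_study(cfg)
  sig <- cfg$signature_genes
  for (cond in c("untreated", "treated")) {
    corr <- pearson_matrix(log_normalize(study[[cond]]))
    expect_lte(abs(block_score(corr, sig)$within), 0.05)
  }
})

test_that("binomial dropout thins observed means by 1 - rate", {
  cfg <- study_config(n_genes_background = 40L, n_cells = 2000L, seed = 29,
                      dropout_rate = 0.3, aberrant_fraction = 0)
  study <- generate_study(cfg)
  truth <- study$ground_truth$rates_control
  idx <- which(!study$untreated$gene_data$is_mito)[1:15]
  for (i in idx) {
    d <- dimensionless_rates(telegraph_rates(truth$k_on[i], truth$k_off[i],
                                             truth$k_eject[i], truth$k_decay[i]))
    mom <- burstfit:::telegraph_moments(d$a, d$b, d$lam)
    se <- sqrt(cfg$ploidy * mom$var / cfg$n_cells)
    obs <- mean(study$untreated$counts[i, ])
    expect_lt(abs(obs - 0.7 * cfg$ploidy * mom$mean), 3.5 * se)
  }
})
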