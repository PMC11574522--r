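make_fits <- function(genes, expr, freq, burst, qc = TRUE) {
  data.frame(gene_id = genes, condition = "x",
             mean_expression = expr, frequency_median = freq,
             burst_size_median = burst,
             qc_pass = rep_len(qc, length(genes)))
}

test_that("log2 fold changes follow their definition and QC gating", {
  ctl <- make_fits(c("a", "b", "c"), c(2, 4, 1), c(0.1, 0.2, 0.3),
                   c(2, 2, 2))
  trt <- make_fits(c("a", "b", "c"), c(2, 8, 1), c(0.1, 0.2, 0.3),
                   c(2, 4, 2), qc = c(TRUE, TRUE, FALSE))
  fc <- log2_fold_changes(trt, ctl)
  expect_identical(fc$gene_id, c("a", "b"))       # c failed QC in treated
  expect_equal(fc$log2FC_expression, c(0, 1))
  expect_equal(fc$log2FC_burst_size, c(0, 1))
  expect_equal(fc$log2FC_frequency, c(0, 0))
})

test_that("swapping condition labels negates every fold change", {
  set.seed(5)
  g <- paste0("g", 1:20)
  f1 <- make_fits(g, runif(20, 1, 10), runif(20, 0.01, 1), runif(20, 1, 20))
  f2 <- make_fits(g, runif(20, 1, 10), runif(20, 0.01, 1), runif(20, 1, 20))
  fc <- log2_fold_changes(f1, f2)
  rev_fc <- log2_fold_changes(f2, f1)
  expect_equal(fc$log2FC_expression, -rev_fc$log2FC_expression)
  expect_equal(fc$log2FC_frequency, -rev_fc$log2FC_frequency)
  expect_equal(fc$log2FC_burst_size, -rev_fc$log2FC_burst_size)
})

test_that("genes with nonpositive control medians are skipped, not propagated", {
  ctl <- make_fits(c("a", "b"), c(2, 0), c(0.1, 0.2), c(2, 2))
  trt <- make_fits(c("a", "b"), c(4, 4), c(0.1, 0.2), c(2, 2))
  expect_message(fc <- log2_fold_changes(trt, ctl), "skipping")
  expect_identical(fc$gene_id, "a")
})

test_that("rank-sum test matches exact enumeration on tiny groups", {
  rec <- data.frame(gene_id = c("s1", "s2", "b1", "b2"),
                    log2FC_burst_size = c(1, 2, 3, 4))
  cmp <- wilcoxon_geneset(rec, c("s1", "s2"), "burst_size")
  expect_equal(cmp$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(cmp$exact)
  # identical multisets are maximally non-significant
  rec2 <- data.frame(gene_id = c("s1", "s2", "s3", "b1", "b2", "b3"),
                     log2FC_frequency = c(1, 2, 3, 1, 2, 3))
  cmp2 <- wilcoxon_geneset(rec2, c("s1", "s2", "s3"), "frequency")
  expect_equal(cmp2$p_value, 1.0)
  expect_error(wilcoxon_geneset(rec, c("s1", "s2", "b1", "b2"), "burst_size"),
               "at least 2")
})

test_that("rank-sum p-value is invariant under monotone transforms", {
  set.seed(9)
  rec <- data.frame(gene_id = paste0("g", 1:30),
                    log2FC_expression = rnorm(30, c(rep(1, 8), rep(0, 22))))
  sig <- paste0("g", 1:8)
  p1 <- wilcoxon_geneset(rec, sig, "expression")$p_value
  rec2 <- rec
  rec2$log2FC_expression <- exp(rec$log2FC_expression) * 7 - 2
  p2 <- wilcoxon_geneset(rec2, sig, "expression")$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("exact and approximate rank-sum agree on untied n = 20", {
  set.seed(3)
  x <- rnorm(10, 0.8)
  y <- rnorm(10)
  pe <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  rec <- data.frame(gene_id = paste0("g", 1:20), log2FC_burst_size = c(x, y))
  pa <- wilcoxon_geneset(rec, paste0("g", 1:10), "burst_size")$p_value
  expect_lt(abs(pa - pe) / pe, 0.1)
})

test_that("ploidy table at two alleles reproduces the direct pipeline", {
  set.seed(21)
  genes <- paste0("g", 1:6)
  k_decay <- 0.02
  counts_t <- t(vapply(1:6, function(i) {
    r <- telegraph_rates(0.02, 0.2, 2 + i, k_decay)
    betapoisson_counts(r, 250, n_alleles = 2, seed = 100 + i)
  }, integer(250)))
  counts_c <- t(vapply(1:6, function(i) {
    r <- telegraph_rates(0.02, 0.2, 2, k_decay)
    betapoisson_counts(r, 250, n_alleles = 2, seed = 200 + i)
  }, integer(250)))
  dimnames(counts_t) <- dimnames(counts_c) <- list(genes, paste0("c", 1:250))
  hl <- data.frame(gene_id = genes, half_life = log(2) / k_decay)
  mt <- make_sc(counts_t, condition = "dox")
  mc <- make_sc(counts_c)
  ps <- suppressWarnings(ploidy_sensitivity(
    mt, mc, signature = c("g5", "g6"), half_lives = hl, allele_grid = 2,
    seed = 31, n_steps = 800, burn_in = 400))
  ft <- suppressWarnings(fit_genes(mt, half_lives = hl, n_alleles = 2L,
                                   n_steps = 800, burn_in = 400, seed = 31))
  fc <- suppressWarnings(fit_genes(mc, half_lives = hl, n_alleles = 2L,
                                   n_steps = 800, burn_in = 400, seed = 31))
  direct <- wilcoxon_geneset(log2_fold_changes(ft, fc), c("g5", "g6"),
                             "burst_size")
  expect_identical(ps$p_value[ps$quantity == "burst_size"], direct$p_value)
  expect_identical(ps$median_signature[ps$quantity == "burst_size"],
                   direct$median_signature)
})

test_that("assuming more alleles shifts inferred frequency down monotonically", {
  r <- telegraph_rates(0.04, 0.4, 4, 0.02)     # clearly bursty, mean ~ 18
  counts <- betapoisson_counts(r, 1500, n_alleles = 2, seed = 17)
  freqs <- vapply(c(1L, 2L, 4L), function(al) {
    fit <- telegraph_fit(counts, k_decay = 0.02, n_alleles = al,
                         n_steps = 4800, burn_in = 2400, seed = 23)
    coef(fit)[["frequency"]]
  }, 0.0)
  expect_true(all(diff(freqs) < 0))
})
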