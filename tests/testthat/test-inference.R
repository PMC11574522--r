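test_that("log-likelihood contracts: empty data, certainty at zero, -Inf", {
  r <- rates_from_dimensionless(1, 1, 10, 0.01)
  expect_identical(log_likelihood(r, integer(0)), 0)
  r0 <- rates_from_dimensionless(1, 1, 1e-12, 0.01)
  expect_gte(log_likelihood(r0, 0L), -1e-9)
  bad <- list(k_on = -1, k_off = 1, k_eject = 1, k_decay = 0.01)
  expect_identical(log_likelihood(bad, c(0L, 1L)), -Inf)
  expect_error(log_likelihood(r, c(-1L)), "nonnegative")
})

test_that("log-likelihood equals the term-wise closed-form sum", {
  r <- rates_from_dimensionless(1, 1, 10, 0.01)
  d <- steady_state_closed_form(r)
  expect_equal(log_likelihood(r, c(0L, 1L, 2L)),
               sum(log(d$probs[1:3])), tolerance = 1e-10)
  # multiplicities and two alleles, against the convolved distribution
  d2 <- convolve_alleles(d, 2)
  cnt <- c(0L, 0L, 3L, 5L, 5L, 5L)
  expect_equal(log_likelihood(r, cnt, n_alleles = 2),
               sum(log(d2$probs[cnt + 1L])), tolerance = 1e-10)
})

test_that("fits are deterministic under a fixed seed", {
  r <- telegraph_rates(0.05, 0.5, 2.5, 0.02)
  counts <- betapoisson_counts(r, 300, n_alleles = 1, seed = 11)
  f1 <- telegraph_fit(counts, k_decay = 0.02, n_alleles = 1,
                      n_steps = 1200, burn_in = 600, seed = 5)
  f2 <- telegraph_fit(counts, k_decay = 0.02, n_alleles = 1,
                      n_steps = 1200, burn_in = 600, seed = 5)
  expect_identical(f1$summaries, f2$summaries)
  expect_identical(f1$qc_pass, f2$qc_pass)
})

test_that("a gene simulated from known rates recovers its burst size", {
  r <- telegraph_rates(0.05, 0.5, 2.5, 0.02)   # burst size 5
  counts <- betapoisson_counts(r, 2000, n_alleles = 1, seed = 11)
  fit <- telegraph_fit(counts, k_decay = 0.02, n_alleles = 1, seed = 5)
  b <- coef(fit)[["burst_size"]]
  expect_gt(b, 5 / 1.5)
  expect_lt(b, 5 * 1.5)
  expect_gt(coef(fit)[["frequency"]], 0.05 / 1.5)
  expect_lt(coef(fit)[["frequency"]], 0.05 * 1.5)
  expect_true(fit$qc_pass)
  # posterior median of the model mean tracks the observed mean
  mm <- (fit$samples[, "k_eject"] / 0.02) * fit$samples[, "k_on"] /
    (fit$samples[, "k_on"] + fit$samples[, "k_off"])
  expect_lt(abs(stats::median(mm) / mean(counts) - 1), 0.15)
})

test_that("all-zero histograms give a flagged degenerate fit", {
  fit <- suppressWarnings(telegraph_fit(rep(0L, 200), k_decay = 0.005,
                                        n_alleles = 2, n_steps = 1200,
                                        burn_in = 600, seed = 1))
  expect_false(fit$qc_pass)
  expect_equal(fit$mean_expression, 0)
  # the fitted model is certain of zero
  expect_gt(predict(fit, n = 0), 0.99)
})

test_that("fit methods expose the model sensibly", {
  r <- telegraph_rates(0.03, 0.3, 3, 0.02)
  counts <- betapoisson_counts(r, 800, n_alleles = 2, seed = 2)
  fit <- telegraph_fit(counts, k_decay = 0.02, n_alleles = 2,
                       n_steps = 2400, burn_in = 1200, seed = 3,
                       gene_id = "DEMO")
  expect_named(coef(fit), c("k_on", "k_off", "k_eject", "k_decay",
                            "burst_size", "frequency"))
  expect_output(print(fit), "burst size")
  expect_output(print(summary(fit)), "rel_mad")
  p <- predict(fit)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  res <- residuals(fit)
  expect_equal(sum(res), 0, tolerance = 0.05)
  sim <- simulate(fit, nsim = 500, seed = 4)
  expect_length(sim, 500)
  expect_lt(abs(mean(sim) / mean(counts) - 1), 0.35)
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})

test_that("qc_filter verdict is reproducible from stored summaries", {
  r <- telegraph_rates(0.03, 0.3, 3, 0.02)
  counts <- betapoisson_counts(r, 500, n_alleles = 2, seed = 8)
  fit <- telegraph_fit(counts, k_decay = 0.02, n_alleles = 2,
                       n_steps = 1200, burn_in = 600, seed = 3)
  s <- fit$summaries
  again <- qc_filter(kon_median = s$median[s$quantity == "k_on"],
                     kon_mad = s$mad[s$quantity == "k_on"],
                     burst_median = s$median[s$quantity == "burst_size"],
                     burst_mad = s$mad[s$quantity == "burst_size"],
                     mean_expression = fit$mean_expression)
  expect_identical(fit$qc_pass, again)
})

test_that("fit_genes imputes missing half-lives and is rerun-stable", {
  r <- telegraph_rates(0.03, 0.3, 3, 0.02)
  counts <- rbind(g1 = betapoisson_counts(r, 300, n_alleles = 2, seed = 1),
                  g2 = betapoisson_counts(r, 300, n_alleles = 2, seed = 2))
  m <- single_cell_matrix(counts)
  hl <- data.frame(gene_id = c("g1", "g2"),
                   half_life = c(log(2) / 0.02, NA))
  expect_warning(
    fits <- fit_genes(m, half_lives = hl, n_steps = 800, burn_in = 400,
                      seed = 4),
    "half-life")
  expect_equal(fits$k_decay[2], 0.02, tolerance = 1e-12)
  fits2 <- suppressWarnings(fit_genes(m, half_lives = hl, n_steps = 800,
                                      burn_in = 400, seed = 4))
  expect_identical(fits, fits2)
})
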