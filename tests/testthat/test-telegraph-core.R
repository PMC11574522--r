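test_that("rate constructors enforce positivity and units", {
  expect_error(telegraph_rates(0, 1, 1, 1), "k_on")
  expect_error(telegraph_rates(1, -1, 1, 1), "k_off")
  expect_error(telegraph_rates(1, 1, Inf, 1), "k_eject")
  expect_error(telegraph_rates(1, 1, 1, NA), "k_decay")
  r <- telegraph_rates(0.02, 0.2, 1, 0.005)
  d <- dimensionless_rates(r)
  expect_equal(d$a, 4)
  expect_equal(d$b, 40)
  expect_equal(d$lam, 200)
  r2 <- rates_from_dimensionless(d$a, d$b, d$lam, 0.005)
  expect_equal(unclass(r2), unclass(r))
})

test_that("half-life conversion is ln(2)/t and self-inverse", {
  expect_equal(decay_from_halflife(log(2)), 1.0)
  expect_equal(decay_from_halflife(60), log(2) / 60, tolerance = 1e-12)
  expect_equal(decay_from_halflife(decay_to_halflife(0.03)), 0.03)
  expect_error(decay_from_halflife(0), "positive")
  expect_error(decay_to_halflife(-1), "positive")
})

test_that("closed form reduces to Poisson when OFF switching vanishes", {
  r <- rates_from_dimensionless(50, 0.001, 10, 0.01)
  d <- steady_state_closed_form(r)
  tv <- 0.5 * sum(abs(d$probs - stats::dpois(0:d$n_max, 10)))
  expect_lt(tv, 1e-3)
})

test_that("no production concentrates all mass at zero", {
  r <- rates_from_dimensionless(1, 1, 1e-12, 0.01)
  d <- steady_state_closed_form(r, 5)
  expect_gte(d$probs[1], 1 - 1e-9)
})

test_that("closed-form and master-equation routes are mutual oracles", {
  r <- rates_from_dimensionless(1, 1, 10, 0.01)
  d1 <- steady_state_closed_form(r)
  d2 <- cme_steady_state(r, n_max = d1$n_max)
  expect_lt(abs(d1$probs[1] - d2$probs[1]), 1e-8)
  expect_lt(max(abs(d1$probs - d2$probs)), 1e-8)
  expect_lt(abs(sum(d2$probs) - 1), 1e-10)
  # known stationary mean, analytically forced
  r3 <- rates_from_dimensionless(0.5, 2, 20, 0.01)
  expect_equal(mean(cme_steady_state(r3)), 4.0, tolerance = 1e-6)
})

test_that("insufficient truncation raises an error naming the needed n_max", {
  r <- rates_from_dimensionless(5, 0.5, 40, 0.01)
  expect_error(steady_state_closed_form(r, 10), "n_max >= ")
  expect_error(cme_steady_state(r, 10), "n_max >= ")
  # and the advertised n_max is sufficient
  need <- as.integer(sub(".*n_max >= (\\d+).*", "\\1",
                         tryCatch(cme_steady_state(r, 10),
                                  error = conditionMessage)))
  expect_s3_class(cme_steady_state(r, need), "count_distribution")
})

test_that("allele convolution is identity at 1 and additive for Poisson", {
  r <- rates_from_dimensionless(1, 1, 5, 0.01)
  d <- cme_steady_state(r)
  expect_identical(convolve_alleles(d, 1), d)
  pois <- count_distribution(stats::dpois(0:80, 4) /
                               sum(stats::dpois(0:80, 4)))
  d2 <- convolve_alleles(pois, 2)
  expect_lt(max(abs(d2$probs - stats::dpois(0:d2$n_max, 8))), 1e-8)
  # convolution doubles the mean
  expect_equal(mean(convolve_alleles(d, 2)), 2 * mean(d), tolerance = 1e-6)
  expect_error(convolve_alleles(d, 0), "n_alleles")
  expect_warning(convolve_alleles(d, 3), "unusual")
})

test_that("burst statistics follow their definitions", {
  r <- telegraph_rates(0.5, 1, 2, 0.1)
  expect_equal(burst_statistics(r)$burst_size, 2.0)
  r2 <- telegraph_rates(0.5, 1.7, 1.7, 0.1)
  expect_equal(burst_statistics(r2)$burst_size, 1.0)
  # mean expression equals the distribution mean, allele-convolved
  r3 <- telegraph_rates(0.1, 1, 10, 0.5)
  bs <- burst_statistics(r3, n_alleles = 2)
  expect_equal(bs$mean_expression, 2 * 20 * 0.1 / 1.1, tolerance = 1e-12)
  d <- convolve_alleles(cme_steady_state(r3), 2)
  expect_equal(bs$mean_expression, mean(d), tolerance = 1e-4)
  expect_equal(bs$frequency, 0.1)
})

test_that("Poisson and bursty limits of the model hold", {
  # b -> 0: Fano factor -> 1
  r <- rates_from_dimensionless(10, 0.001, 10, 0.01)
  d <- cme_steady_state(r)
  expect_equal(distribution_var(d) / mean(d), 1, tolerance = 1e-3)
  # a << b, lam >> 1: mean ~ burst size x frequency / decay
  r2 <- rates_from_dimensionless(0.01, 10, 100, 0.01)
  bs <- burst_statistics(r2)
  expect_equal(bs$mean_expression,
               bs$burst_size * bs$frequency / r2$k_decay,
               tolerance = 0.05)
})

test_that("distributions export as two-column TSV and read back", {
  r <- rates_from_dimensionless(1, 2, 8, 0.01)
  d <- cme_steady_state(r)
  path <- tempfile(fileext = ".tsv")
  write_distribution_tsv(d, path)
  back <- utils::read.delim(path)
  expect_identical(names(back), c("n", "probability"))
  expect_equal(back$probability, d$probs, tolerance = 1e-12)
})
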