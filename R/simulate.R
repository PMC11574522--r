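#' Exact stochastic simulation of telegraph-model cells
#'
#' Simulates each cell's mRNA copy number by the Gillespie algorithm for
#' the reaction scheme OFF -> ON (\code{k_on}), ON -> OFF (\code{k_off}),
#' ON -> ON + mRNA (\code{k_eject}), mRNA decay (\code{k_decay} per
#' molecule). Alleles are simulated independently from an OFF, zero-mRNA
#' start and their counts summed; each cell is run for
#' \code{burn_in_halflives} decay half-lives so the sample is effectively
#' stationary (the relaxation time is of order \code{1/k_decay}).
#'
#' @param rates a [telegraph_rates()] object.
#' @param n_cells number of cells to simulate.
#' @param n_alleles gene copies per cell.
#' @param seed RNG seed; a fixed seed makes the output reproducible.
#' @param burn_in_halflives how many decay half-lives to simulate before
#'   reading off the count (default 10; residual bias ~ 2^-10).
#' @return Integer vector of length \code{n_cells}.
#' @seealso [betapoisson_counts()] for the fast stationary sampler.
#' @export
gillespie_counts <- function(rates, n_cells, n_alleles = 1L, seed = 1L,
                             burn_in_halflives = 10) {
  stopifnot(inherits(rates, "telegraph_rates"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (n_alleles < 1) stop("n_alleles must be >= 1")
  t_end <- burn_in_halflives * log(2) / rates$k_decay
  set.seed(seed)
  .gillespie_cpp(rates$k_on, rates$k_off, rates$k_eject, rates$k_decay,
                 as.integer(n_alleles), as.integer(n_cells), t_end)
}

#' Stationary Beta-Poisson sampler for telegraph-model cells
#'
#' Draws exact stationary counts without trajectory simulation: per allele,
#' the promoter activity is Beta(a, b)-distributed (a = k_on/k_decay,
#' b = k_off/k_decay) and the count is Poisson with intensity
#' \code{lam * p}; allele counts are summed. Equivalent in distribution to
#' [gillespie_counts()] at stationarity, but orders of magnitude faster.
#'
#' @inheritParams gillespie_counts
#' @param intensity_factor optional per-cell multiplier on the Poisson
#'   intensity (length \code{n_cells}), used to inject extrinsic cell-level
#'   variability; default 1 for all cells.
#' @return Integer vector of length \code{n_cells}.
#' @export
betapoisson_counts <- function(rates, n_cells, n_alleles = 1L, seed = 1L,
                               intensity_factor = NULL) {
  stopifnot(inherits(rates, "telegraph_rates"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (n_alleles < 1) stop("n_alleles must be >= 1")
  set.seed(seed)
  d <- dimensionless_rates(rates)
  bp_sample(d$a, d$b, d$lam, as.integer(n_cells), as.integer(n_alleles),
            intensity_factor)
}

# core Beta-Poisson draw; consumes the current RNG stream (no seeding here)
bp_sample <- function(a, b, lam, n_cells, n_alleles, intensity_factor = NULL) {
  if (is.null(intensity_factor)) intensity_factor <- rep(1, n_cells)
  stopifnot(length(intensity_factor) == n_cells)
  total <- integer(n_cells)
  for (al in seq_len(n_alleles)) {
    p <- stats::rbeta(n_cells, a, b)
    total <- total + stats::rpois(n_cells, lam * p * intensity_factor)
  }
  total
}
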