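#' Construct a truncated mRNA copy-number distribution
#'
#' Light container used by the stationary-distribution solvers and the
#' likelihood: probabilities for copy numbers \code{0..n_max}.
#'
#' @param probs numeric vector of probabilities for n = 0, 1, ..., n_max.
#' @return An object of class \code{"count_distribution"}.
#' @export
count_distribution <- function(probs) {
  if (any(!is.finite(probs)) || any(probs < -1e-12))
    stop("probabilities must be finite and nonnegative")
  probs <- pmax(probs, 0)
  s <- sum(probs)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("probabilities sum to %.8f, not 1 (tolerance 1e-6)", s))
  structure(list(n_max = length(probs) - 1L, probs = probs),
            class = "count_distribution")
}

#' @export
print.count_distribution <- function(x, ...) {
  cat(sprintf("mRNA copy-number distribution on 0..%d (mean %.4g, var %.4g)\n",
              x$n_max, mean(x), distribution_var(x)))
  invisible(x)
}

#' @export
mean.count_distribution <- function(x, ...) {
  sum(seq(0L, x$n_max) * x$probs)
}

#' Variance of a count distribution
#' @param dist a [count_distribution()].
#' @return The variance of the copy number.
#' @export
distribution_var <- function(dist) {
  n <- seq(0L, dist$n_max)
  m <- sum(n * dist$probs)
  sum((n - m)^2 * dist$probs)
}

# adaptive truncation point: start at mean + 10 sd of the analytic moments,
# double until the closed-form tail mass drops below tol
adaptive_nmax <- function(a, b, lam, tol = 1e-8) {
  mom <- telegraph_moments(a, b, lam)
  n <- max(10L, as.integer(ceiling(mom$mean + 10 * sqrt(mom$var))))
  repeat {
    lp <- closed_form_logpmf(a, b, lam, n)
    if (1 - sum(exp(lp)) < tol) return(n)
    if (n > 2e6) stop("failed to locate a truncation point with small tail mass")
    n <- n * 2L
  }
}

# log pmf of the single-allele stationary distribution via the classical
# confluent-hypergeometric solution, assembled in log space:
#   P(n) = lam^n/n! * (a)_n/(a+b)_n * e^{-lam} * 1F1(b; a+b+n; lam)
# (Kummer-transformed so the series has all-positive terms).
closed_form_logpmf <- function(a, b, lam, n_max) {
  n <- seq(0L, n_max)
  n * log(lam) - lgamma(n + 1) +
    lgamma(a + n) - lgamma(a) - (lgamma(a + b + n) - lgamma(a + b)) -
    lam + vapply(n, function(k) log_kummer_series(b, a + b + k, lam), 0.0)
}

# log 1F1(p; q; x) for p, q, x > 0 by direct summation of the (all positive)
# series, with rescaling to dodge overflow for large x
log_kummer_series <- function(p, q, x) {
  term <- 1.0
  s <- 1.0
  off <- 0.0
  j <- 0
  repeat {
    term <- term * (p + j) * x / ((q + j) * (j + 1))
    s <- s + term
    if (s > 1e280) {
      term <- term / 1e280
      s <- s / 1e280
      off <- off + 280 * log(10)
    }
    j <- j + 1
    if (term < s * 1e-17 || j > 1e6) break
  }
  log(s) + off
}

tail_error <- function(which, n_max, required) {
  stop(sprintf(
    "truncation error in %s: tail mass beyond n_max = %d exceeds 1e-8; use n_max >= %d",
    which, n_max, required), call. = FALSE)
}

#' Stationary distribution of the telegraph model (closed form)
#'
#' Evaluates the classical stationary solution of the two-state telegraph
#' model for a single allele: a Poisson law whose intensity is modulated by
#' a Beta-distributed promoter activity, computed in log space through the
#' confluent hypergeometric function for numerical stability.
#'
#' The returned vector covers copy numbers \code{0..n_max} and is
#' renormalized after verifying that the truncated tail mass is below
#' \code{1e-8}; an insufficient \code{n_max} raises an error naming the
#' required truncation point.
#'
#' @param rates a [telegraph_rates()] object.
#' @param n_max largest copy number to represent; \code{NULL} (default)
#'   chooses it adaptively from the analytic moments.
#' @return A [count_distribution()].
#' @seealso [cme_steady_state()] for the independent master-equation solver.
#' @export
steady_state_closed_form <- function(rates, n_max = NULL) {
  stopifnot(inherits(rates, "telegraph_rates"))
  d <- dimensionless_rates(rates)
  required <- adaptive_nmax(d$a, d$b, d$lam)
  if (is.null(n_max)) n_max <- required
  if (n_max < 0) stop("n_max must be >= 0")
  lp <- closed_form_logpmf(d$a, d$b, d$lam, n_max)
  p <- exp(lp)
  if (1 - sum(p) >= 1e-8)
    tail_error("steady_state_closed_form", n_max, required)
  count_distribution(p / sum(p))
}

#' Stationary distribution of the telegraph model (truncated master equation)
#'
#' Solves the stationary linear system of the chemical master equation over
#' the states \{OFF, ON\} x \{0..n_top\} by block elimination and
#' marginalizes the promoter state. This route is independent of the
#' closed-form solution in [steady_state_closed_form()]; the two serve as
#' mutual oracles and agree to near machine precision.
#'
#' @inheritParams steady_state_closed_form
#' @return A [count_distribution()] over \code{0..n_max}, renormalized
#'   after verifying tail mass beyond \code{n_max} is below \code{1e-8}.
#' @export
cme_steady_state <- function(rates, n_max = NULL) {
  stopifnot(inherits(rates, "telegraph_rates"))
  d <- dimensionless_rates(rates)
  required <- adaptive_nmax(d$a, d$b, d$lam)
  if (is.null(n_max)) n_max <- required
  if (n_max < 0) stop("n_max must be >= 0")
  n_top <- max(n_max, required) + 30L
  p <- .cme_pmf_cpp(d$a, d$b, d$lam, n_top)
  if (abs(sum(p) - 1) > 1e-10)
    stop("master-equation solve lost probability mass; system ill-conditioned")
  tail <- if (n_max + 2L <= length(p)) sum(p[(n_max + 2L):length(p)]) else 0
  if (tail >= 1e-8)
    tail_error("cme_steady_state", n_max, required)
  p <- p[seq_len(n_max + 1L)]
  count_distribution(p / sum(p))
}

#' Copy-number distribution of several independent identical alleles
#'
#' The total mRNA of \code{n_alleles} independent, identically behaving
#' gene copies is the n-fold self-convolution of the single-allele law.
#'
#' @param dist a single-allele [count_distribution()].
#' @param n_alleles number of gene copies (ploidy); values outside
#'   \{1, 2, 4, 8, 16\} are allowed but trigger a warning.
#' @return A [count_distribution()] with support extended accordingly.
#' @export
convolve_alleles <- function(dist, n_alleles) {
  stopifnot(inherits(dist, "count_distribution"))
  if (n_alleles < 1) stop("n_alleles must be >= 1")
  n_alleles <- as.integer(n_alleles)
  if (!n_alleles %in% c(1L, 2L, 4L, 8L, 16L))
    warning(sprintf("unusual allele count %d (expected 1, 2, 4, 8 or 16)", n_alleles))
  if (n_alleles == 1L) return(dist)
  p <- dist$probs
  out <- p
  for (i in seq_len(n_alleles - 1L)) out <- .conv_pmf_cpp(out, p)
  count_distribution(out / sum(out))
}

#' Write a count distribution as a two-column TSV
#'
#' @param dist a [count_distribution()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_distribution_tsv <- function(dist, path) {
  stopifnot(inherits(dist, "count_distribution"))
  utils::write.table(
    data.frame(n = seq(0L, dist$n_max), probability = dist$probs),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
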