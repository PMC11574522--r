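#' Log-likelihood of a count histogram under the telegraph model
#'
#' Sums, over cells, the log stationary probability of each observed count
#' under the given rates, using the master-equation stationary distribution
#' convolved over alleles. Counts beyond the default truncation extend the
#' solve; they are never clipped. Invalid (nonpositive or nonfinite) rates
#' return \code{-Inf} rather than raising, so a sampler can treat them as
#' ordinary rejections.
#'
#' @param rates a [telegraph_rates()] object, or a plain list with the four
#'   rate components (not validated, so that invalid proposals return
#'   \code{-Inf}).
#' @param counts integer vector of observed mRNA counts, one per cell
#'   (an empty vector gives 0).
#' @param n_alleles gene copies assumed per cell.
#' @return The log-likelihood (a single number, possibly \code{-Inf}).
#' @export
log_likelihood <- function(rates, counts, n_alleles = 1L) {
  if (length(counts) == 0) return(0)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  ok <- vapply(c("k_on", "k_off", "k_eject", "k_decay"), function(nm) {
    v <- rates[[nm]]
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0
  }, logical(1))
  if (!all(ok)) return(-Inf)
  tab <- table(counts)
  .telegraph_loglik_cpp(as.integer(names(tab)), as.numeric(tab),
                        rates$k_on, rates$k_off, rates$k_eject,
                        rates$k_decay, as.integer(n_alleles))
}

mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

#' Fit the telegraph model to a single gene's count histogram
#'
#' Bayesian Metropolis-Hastings sampling of the log10 rates (\code{k_on},
#' \code{k_off}, \code{k_eject}) with independent uniform priors on the
#' log10 scale; the degradation rate is fixed from the gene's measured mRNA
#' half-life, which anchors the sampler's timescale so rates come out in
#' per-minute units. Sampling uses an affine-invariant walker ensemble
#' (stretch moves) rather than a single random-walk chain: count
#' histograms often constrain only the mean and overdispersion, leaving a
#' long curved likelihood ridge in rate space along which a single chain
#' mixes far too slowly and understates the posterior spread that the
#' MAD-based QC filter depends on. Walkers start uniform over the prior
#' box, so the pooled posterior is initialization-free. Posterior medians
#' and raw median absolute deviations (MADs) are reported for the three
#' free rates and for the derived burst size (\code{k_eject/k_off},
#' computed per posterior sample) and burst frequency (\code{k_on}).
#'
#' @param counts integer vector of observed mRNA counts, one per cell.
#' @param k_decay fixed degradation rate (per minute); alternatively give
#'   \code{half_life}.
#' @param half_life mRNA half-life in minutes (used if \code{k_decay} is
#'   missing).
#' @param n_alleles gene copies assumed per cell (2 for a diploid line).
#' @param prior_bounds length-2 numeric, bounds of the uniform prior on
#'   log10 of each free rate (per minute).
#' @param n_steps posterior draws kept, pooled across the ensemble.
#' @param burn_in draws discarded before pooling (also pooled count).
#' @param seed RNG seed; identical seeds give identical fits.
#' @param gene_id,condition optional labels stored in the result.
#' @return An object of class \code{"telegraph_fit"} with posterior
#'   samples, summaries (median and MAD per quantity), the observed mean
#'   expression, the QC verdict from [qc_filter()], and chain diagnostics.
#' @seealso [qc_filter()], [fit_genes()] for fitting a whole matrix.
#' @examples
#' rates <- telegraph_rates(0.01, 0.1, 1, 0.002)
#' counts <- betapoisson_counts(rates, 400, n_alleles = 1, seed = 1)
#' fit <- telegraph_fit(counts, k_decay = 0.002, n_alleles = 1,
#'                      n_steps = 500, burn_in = 200, seed = 1)
#' coef(fit)
#' @export
telegraph_fit <- function(counts, k_decay = NULL, half_life = NULL,
                          n_alleles = 2L, prior_bounds = c(-4, 2),
                          n_steps = 10000L, burn_in = 2000L, seed = 1L,
                          gene_id = NA_character_, condition = NA_character_) {
  if (is.null(k_decay)) {
    if (is.null(half_life)) stop("supply k_decay or half_life")
    k_decay <- decay_from_halflife(half_life)
  }
  if (!is.finite(k_decay) || k_decay <= 0) stop("k_decay must be positive")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (length(counts) < 50)
    warning(sprintf("only %d cells; posterior summaries will be unstable below ~50",
                    length(counts)))
  lo <- prior_bounds[1]; hi <- prior_bounds[2]
  tab <- table(counts)
  set.seed(seed)
  res <- .mh_fit_cpp(as.integer(names(tab)), as.numeric(tab), k_decay,
                     as.integer(n_alleles), lo, hi, numeric(3),
                     as.integer(n_steps), as.integer(burn_in), 0.3)
  s <- 10^res$samples                      # columns: k_on, k_off, k_eject
  colnames(s) <- c("k_on", "k_off", "k_eject")
  draws <- list(k_on = s[, 1], k_off = s[, 2], k_eject = s[, 3],
                burst_size = s[, 3] / s[, 2], frequency = s[, 1])
  summaries <- data.frame(
    quantity = names(draws),
    median = vapply(draws, stats::median, 0.0),
    mad = vapply(draws, mad_raw, 0.0),
    row.names = NULL)
  fit <- structure(list(
    gene_id = gene_id, condition = condition,
    samples = s, k_decay = k_decay, n_alleles = as.integer(n_alleles),
    summaries = summaries,
    mean_expression = if (length(counts)) mean(counts) else 0,
    n_cells = length(counts),
    counts_table = tab,
    acceptance_rate = res$acceptance_rate,
    ess = ess_proxy(log(draws$burst_size)),
    n_walkers = res$n_walkers,
    prior_bounds = prior_bounds, seed = seed,
    call = match.call()), class = "telegraph_fit")
  fit$qc_pass <- qc_filter(fit)
  fit
}

# effective-sample-size proxy from the lag autocorrelation of one chain
ess_proxy <- function(x, max_lag = 100L) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(max_lag, n - 1), plot = FALSE)$acf[-1]
  pos <- ac[ac > 0.05]
  n / (1 + 2 * sum(pos))
}

#' Quality-control filter on posterior summaries
#'
#' A fit passes QC iff the relative posterior uncertainty of the burst
#' frequency and of the burst size are both small and the gene is
#' expressed: \code{MAD(k_on)/median(k_on) < 0.75},
#' \code{MAD(burst_size)/median(burst_size) < 0.75} and mean expression
#' \code{> 0.01} (all inequalities strict). A zero median fails the
#' corresponding ratio test.
#'
#' @param fit a [telegraph_fit()] object; alternatively supply the raw
#'   summaries via the remaining arguments.
#' @param kon_median,kon_mad,burst_median,burst_mad,mean_expression raw
#'   posterior summaries (used when \code{fit} is missing).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
qc_filter <- function(fit = NULL, kon_median = NULL, kon_mad = NULL,
                      burst_median = NULL, burst_mad = NULL,
                      mean_expression = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "telegraph_fit"))
    s <- fit$summaries
    kon_median <- s$median[s$quantity == "k_on"]
    kon_mad <- s$mad[s$quantity == "k_on"]
    burst_median <- s$median[s$quantity == "burst_size"]
    burst_mad <- s$mad[s$quantity == "burst_size"]
    mean_expression <- fit$mean_expression
  }
  if (kon_median <= 0 || burst_median <= 0) return(FALSE)
  (kon_mad / kon_median < 0.75) &&
    (burst_mad / burst_median < 0.75) &&
    (mean_expression > 0.01)
}

#' @export
print.telegraph_fit <- function(x, ...) {
  cat(sprintf("Telegraph-model fit%s%s: %d cells, %d alleles, k_decay = %.4g /min\n",
              if (is.na(x$gene_id)) "" else paste0(" for ", x$gene_id),
              if (is.na(x$condition)) "" else paste0(" (", x$condition, ")"),
              x$n_cells, x$n_alleles, x$k_decay))
  cat(sprintf("  burst size %.3g (MAD %.3g), frequency %.3g /min (MAD %.3g)\n",
              x$summaries$median[x$summaries$quantity == "burst_size"],
              x$summaries$mad[x$summaries$quantity == "burst_size"],
              x$summaries$median[x$summaries$quantity == "frequency"],
              x$summaries$mad[x$summaries$quantity == "frequency"]))
  cat(sprintf("  mean expression %.3g counts/cell; QC %s; acceptance %.2f\n",
              x$mean_expression, if (x$qc_pass) "pass" else "FAIL",
              x$acceptance_rate))
  invisible(x)
}

#' @export
coef.telegraph_fit <- function(object, ...) {
  s <- object$summaries
  out <- stats::setNames(s$median, s$quantity)
  c(out[c("k_on", "k_off", "k_eject")], k_decay = object$k_decay,
    out[c("burst_size", "frequency")])
}

#' @export
summary.telegraph_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.telegraph_fit")
}

#' @export
print.summary.telegraph_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  tab <- f$summaries
  tab$rel_mad <- tab$mad / tab$median
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("effective samples (burst size, proxy): %.0f of %d\n",
              f$ess, nrow(f$samples)))
  invisible(x)
}

#' Posterior-predictive count distribution of a fitted gene
#'
#' Averages the stationary copy-number distribution over a thinned subset
#' of posterior draws (the posterior predictive), rather than plugging in
#' point estimates: the componentwise posterior medians of correlated rate
#' posteriors need not form a representative joint rate set.
#'
#' @param object a [telegraph_fit()].
#' @param n copy numbers at which to evaluate (default: the full support
#'   of the averaged distribution).
#' @param ndraws number of posterior draws averaged over.
#' @param ... unused.
#' @return Named vector of probabilities.
#' @export
predict.telegraph_fit <- function(object, n = NULL, ndraws = 150L, ...) {
  s <- object$samples
  idx <- unique(round(seq(1L, nrow(s), length.out = min(ndraws, nrow(s)))))
  pmfs <- lapply(idx, function(i) {
    stationary_pmf_fast(s[i, "k_on"] / object$k_decay,
                        s[i, "k_off"] / object$k_decay,
                        s[i, "k_eject"] / object$k_decay, object$n_alleles)
  })
  len <- max(vapply(pmfs, length, 0L))
  avg <- rowMeans(vapply(pmfs, function(p) c(p, rep(0, len - length(p))),
                         numeric(len)))
  avg <- avg / sum(avg)
  if (is.null(n)) n <- seq(0L, len - 1L)
  p <- ifelse(n < len, avg[n + 1L], 0)
  stats::setNames(p, n)
}

posterior_median_rates <- function(fit) {
  s <- fit$summaries
  telegraph_rates(k_on = s$median[s$quantity == "k_on"],
                  k_off = s$median[s$quantity == "k_off"],
                  k_eject = s$median[s$quantity == "k_eject"],
                  k_decay = fit$k_decay)
}

#' @export
residuals.telegraph_fit <- function(object, type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  maxc <- max(as.integer(names(object$counts_table)))
  obs <- numeric(maxc + 1L)
  obs[as.integer(names(object$counts_table)) + 1L] <-
    as.numeric(object$counts_table) / object$n_cells
  fitted <- predict(object, n = 0:maxc)
  res <- obs - fitted
  if (type == "pearson")
    res <- res / sqrt(pmax(fitted, 1e-12) / object$n_cells)
  stats::setNames(res, 0:maxc)
}

#' @export
simulate.telegraph_fit <- function(object, nsim = object$n_cells, seed = 1L, ...) {
  betapoisson_counts(posterior_median_rates(object), n_cells = nsim,
                     n_alleles = object$n_alleles, seed = seed)
}

#' @export
plot.telegraph_fit <- function(x, ...) {
  maxc <- max(as.integer(names(x$counts_table)))
  obs <- numeric(maxc + 1L)
  obs[as.integer(names(x$counts_table)) + 1L] <-
    as.numeric(x$counts_table) / x$n_cells
  fitted <- predict(x, n = 0:maxc)
  graphics::barplot(obs, names.arg = 0:maxc, col = "grey85", border = NA,
                    xlab = "mRNA per cell", ylab = "frequency",
                    main = if (is.na(x$gene_id)) "telegraph fit" else x$gene_id, ...)
  bp <- graphics::barplot(obs, plot = FALSE)
  graphics::lines(bp, fitted, lwd = 2, col = "firebrick")
  graphics::points(bp, fitted, pch = 16, col = "firebrick", cex = 0.6)
  invisible(x)
}

# moment-truncated stationary pmf of n_alleles summed copies, C++ path;
# internal fast route for posterior-predictive averaging
stationary_pmf_fast <- function(a, b, lam, n_alleles) {
  mom <- telegraph_moments(a, b, lam)
  n_top <- max(10L, as.integer(ceiling(mom$mean + 10 * sqrt(mom$var))) + 30L)
  p <- .cme_pmf_cpp(a, b, lam, n_top)
  out <- p
  if (n_alleles > 1L)
    for (i in seq_len(n_alleles - 1L)) out <- .conv_pmf_cpp(out, p)
  out / sum(out)
}
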