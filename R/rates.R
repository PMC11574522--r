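#' Kinetic rates of the two-state telegraph model
#'
#' Bundles the four rate constants of the telegraph model of transcription:
#' the promoter switches from the inactive (OFF) to the active (ON) state at
#' rate \code{k_on} (the burst frequency), back at rate \code{k_off}, emits
#' mRNA while ON at rate \code{k_eject}, and each mRNA molecule decays at
#' rate \code{k_decay}. All rates are per minute.
#'
#' @param k_on promoter activation rate (per minute).
#' @param k_off promoter inactivation rate (per minute).
#' @param k_eject mRNA production rate while active (per minute).
#' @param k_decay mRNA degradation rate (per minute); typically obtained
#'   from a measured half-life via [decay_from_halflife()].
#'
#' @return An object of class \code{"telegraph_rates"}: a named list with
#'   the four rates.
#' @seealso [dimensionless_rates()], [burst_statistics()],
#'   [steady_state_closed_form()]
#' @examples
#' telegraph_rates(k_on = 0.02, k_off = 0.2, k_eject = 1, k_decay = 0.0023)
#' @export
telegraph_rates <- function(k_on, k_off, k_eject, k_decay) {
  r <- list(k_on = k_on, k_off = k_off, k_eject = k_eject, k_decay = k_decay)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a single strictly positive finite number", nm))
  }
  structure(r, class = "telegraph_rates")
}

#' @export
print.telegraph_rates <- function(x, ...) {
  cat("Telegraph-model rates (per minute):\n")
  cat(sprintf("  k_on    = %.6g   (burst frequency)\n", x$k_on))
  cat(sprintf("  k_off   = %.6g\n", x$k_off))
  cat(sprintf("  k_eject = %.6g\n", x$k_eject))
  cat(sprintf("  k_decay = %.6g   (half-life %.4g min)\n",
              x$k_decay, decay_to_halflife(x$k_decay)))
  invisible(x)
}

#' Nondimensionalize telegraph rates by the decay rate
#'
#' Rescales time by the mRNA lifetime, giving \code{a = k_on/k_decay},
#' \code{b = k_off/k_decay} and \code{lam = k_eject/k_decay}. The stationary
#' copy-number distribution depends on the rates only through these three
#' unitless numbers.
#'
#' @param rates a [telegraph_rates()] object.
#' @return A named list with components \code{a}, \code{b}, \code{lam},
#'   of class \code{"dimensionless_rates"}.
#' @export
dimensionless_rates <- function(rates) {
  stopifnot(inherits(rates, "telegraph_rates"))
  structure(list(a = rates$k_on / rates$k_decay,
                 b = rates$k_off / rates$k_decay,
                 lam = rates$k_eject / rates$k_decay),
            class = "dimensionless_rates")
}

#' Rebuild per-minute rates from dimensionless rates and a decay rate
#'
#' Inverse of [dimensionless_rates()] given \code{k_decay}.
#'
#' @param a,b,lam dimensionless rates (k_on, k_off, k_eject divided by
#'   k_decay).
#' @param k_decay mRNA degradation rate, per minute.
#' @return A [telegraph_rates()] object.
#' @export
rates_from_dimensionless <- function(a, b, lam, k_decay) {
  telegraph_rates(k_on = a * k_decay, k_off = b * k_decay,
                  k_eject = lam * k_decay, k_decay = k_decay)
}

#' Convert an mRNA half-life to a degradation rate
#'
#' First-order decay: \code{k_decay = log(2) / t_half}. The half-life
#' anchors the model's timescale so that inferred rates are in per-minute
#' units.
#'
#' @param t_half mRNA half-life in minutes.
#' @return Degradation rate per minute.
#' @export
decay_from_halflife <- function(t_half) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0))
    stop("half-life must be strictly positive and finite (minutes)")
  log(2) / t_half
}

#' @rdname decay_from_halflife
#' @param k_decay degradation rate per minute.
#' @export
decay_to_halflife <- function(k_decay) {
  if (!is.numeric(k_decay) || any(!is.finite(k_decay)) || any(k_decay <= 0))
    stop("decay rate must be strictly positive and finite (per minute)")
  log(2) / k_decay
}

#' Burst statistics implied by telegraph rates
#'
#' Burst size is the mean number of mRNA produced per ON period,
#' \code{k_eject / k_off}; burst frequency is the activation rate
#' \code{k_on} (bursts per minute); mean expression is the stationary mean
#' mRNA per cell,
#' \code{n_alleles * (k_eject/k_decay) * k_on/(k_on + k_off)}.
#'
#' @param rates a [telegraph_rates()] object.
#' @param n_alleles number of independent identical gene copies.
#' @return A list of class \code{"burst_statistics"} with components
#'   \code{burst_size}, \code{frequency}, \code{mean_expression}.
#' @export
burst_statistics <- function(rates, n_alleles = 1L) {
  stopifnot(inherits(rates, "telegraph_rates"))
  if (n_alleles < 1) stop("n_alleles must be >= 1")
  structure(list(
    burst_size = rates$k_eject / rates$k_off,
    frequency = rates$k_on,
    mean_expression = n_alleles * (rates$k_eject / rates$k_decay) *
      rates$k_on / (rates$k_on + rates$k_off)
  ), class = "burst_statistics")
}

#' @export
print.burst_statistics <- function(x, ...) {
  cat(sprintf("burst size %.4g mRNA/burst, frequency %.4g /min, mean expression %.4g\n",
              x$burst_size, x$frequency, x$mean_expression))
  invisible(x)
}

# stationary mean and variance of a single telegraph allele (dimensionless)
telegraph_moments <- function(a, b, lam) {
  m <- lam * a / (a + b)
  v <- m + lam^2 * a * b / ((a + b)^2 * (a + b + 1))
  list(mean = m, var = v)
}
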