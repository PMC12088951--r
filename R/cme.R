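#' Invert observables into entry and exit rates
#'
#' The birth-death description of exchange between a region of interest
#' (ROI) and its surroundings relaxes exponentially at the turnover rate
#' `k_t = k_in + k_out` toward a stationary interior fraction `n_in_bar`.
#' Under the model's inversion convention the stationary fraction is tied to
#' the exit rate, `n_in_bar = k_out / k_t`, so the two observables of a
#' FRAP/FLAP experiment determine both rates:
#' `k_out = n_in_bar * k_t`, `k_in = k_t - k_out`.
#'
#' @param k_t Turnover rate, /s, positive.
#' @param n_in_bar Stationary interior fraction, in `[0, 1]`.
#' @return Named numeric vector `c(k_in =, k_out =)`, both nonnegative,
#'   summing exactly to `k_t`.
#' @seealso [stationary_fraction()], [dynamic_rates()]
#' @export
#' @examples
#' invert_rates(0.01129, 0.562)  # tensin-like: k_out ~ 6.35e-3, k_in ~ 4.94e-3
invert_rates <- function(k_t, n_in_bar) {
  if (!is.numeric(k_t) || length(k_t) != 1L || !is.finite(k_t) || k_t <= 0)
    stop("`k_t` must be a positive scalar")
  if (!is.numeric(n_in_bar) || length(n_in_bar) != 1L ||
      n_in_bar < 0 || n_in_bar > 1)
    stop("`n_in_bar` must lie in [0, 1]")
  k_out <- n_in_bar * k_t
  c(k_in = k_t - k_out, k_out = k_out)
}

#' Stationary interior fraction from the rates
#'
#' Inverse companion of [invert_rates()]: `k_out / (k_in + k_out)`.
#'
#' @param k_in,k_out Nonnegative rates, /s, not both zero.
#' @return Fraction in `[0, 1]`.
#' @export
stationary_fraction <- function(k_in, k_out) {
  if (any(c(k_in, k_out) < 0)) stop("rates must be nonnegative")
  if (k_in + k_out <= 0) stop("at least one of the rates must be positive")
  k_out / (k_in + k_out)
}

#' Construct a dynamic-rates record
#'
#' Holds the full parameter set for one protein: the measured turnover rate
#' and stationary interior fraction, the inverted entry/exit rates, and
#' first-order propagated uncertainties.  The internal consistency
#' `k_in + k_out == k_t` and `n_in_bar == k_out / k_t` is guaranteed by
#' construction.
#'
#' @param k_t Turnover rate, /s.
#' @param n_in_bar Stationary interior fraction in `[0, 1]`.
#' @param sigma_k_t,sigma_n_in_bar Nonnegative 1-sigma uncertainties of the
#'   observables (same units as their parents); default 0.
#' @param protein Label.
#' @return Object of class `dynamic_rates` with fields `k_t`, `k_in`,
#'   `k_out`, `n_in_bar`, the four `sigma_*` values, and `protein`.
#' @export
dynamic_rates <- function(k_t, n_in_bar, sigma_k_t = 0, sigma_n_in_bar = 0,
                          protein = "protein") {
  k <- invert_rates(k_t, n_in_bar)
  s <- propagate_uncertainty(k_t, sigma_k_t, n_in_bar, sigma_n_in_bar)
  structure(
    list(k_t = k_t, k_in = unname(k[["k_in"]]), k_out = unname(k[["k_out"]]),
         n_in_bar = n_in_bar,
         sigma_k_t = sigma_k_t, sigma_k_in = unname(s[["sigma_k_in"]]),
         sigma_k_out = unname(s[["sigma_k_out"]]),
         sigma_n_in_bar = sigma_n_in_bar,
         protein = as.character(protein)[[1L]]),
    class = "dynamic_rates")
}

#' Dynamic rates from entry/exit components
#'
#' Convenience constructor when the entry and exit rates themselves are the
#' starting point: `k_t = k_in + k_out`, `n_in_bar = k_out / k_t`.
#'
#' @param k_in,k_out Nonnegative rates, /s, not both zero.
#' @param protein Label.
#' @return A [dynamic_rates()] object.
#' @export
rates_from_in_out <- function(k_in, k_out, protein = "protein") {
  dynamic_rates(k_t = k_in + k_out,
                n_in_bar = stationary_fraction(k_in, k_out),
                protein = protein)
}

#' @export
print.dynamic_rates <- function(x, ...) {
  cat(sprintf("<dynamic_rates> %s\n", x$protein))
  cat(sprintf("  k_t      = %7.3f e-3 /s  (+/- %.3f)\n", 1e3 * x$k_t, 1e3 * x$sigma_k_t))
  cat(sprintf("  k_in     = %7.3f e-3 /s  (+/- %.3f)\n", 1e3 * x$k_in, 1e3 * x$sigma_k_in))
  cat(sprintf("  k_out    = %7.3f e-3 /s  (+/- %.3f)\n", 1e3 * x$k_out, 1e3 * x$sigma_k_out))
  cat(sprintf("  n_in_bar = %7.3f        (+/- %.3f)\n", x$n_in_bar, x$sigma_n_in_bar))
  invisible(x)
}

#' Initial interior/exterior state for the closed-form solution
#'
#' @param n_in_0,n_out_0 Nonnegative initial interior and exterior
#'   concentrations; their sum is the conserved total.
#' @param t0 Reference time, seconds (default 0).
#' @return Object of class `initial_state` with `n_in_0`, `n_out_0`, `t0`,
#'   `n_tot`.
#' @export
initial_state <- function(n_in_0, n_out_0, t0 = 0) {
  if (n_in_0 < 0 || n_out_0 < 0) stop("initial concentrations must be nonnegative")
  structure(list(n_in_0 = n_in_0, n_out_0 = n_out_0, t0 = t0,
                 n_tot = n_in_0 + n_out_0),
            class = "initial_state")
}

#' Closed-form interior concentration over time
#'
#' Exact solution of the one-compartment exchange model: the interior
#' concentration relaxes monotonically from its initial value toward the
#' stationary value `n_tot * k_out / k_t` with rate `k_t = k_in + k_out`:
#' \deqn{n_{in}(t) = \frac{n_{in}(t_0)\,[k_{out} + k_{in} e^{-k_T (t-t_0)}]
#'   + n_{out}(t_0)\, k_{out}\,[1 - e^{-k_T (t-t_0)}]}{k_T}.}
#'
#' @param rates A [dynamic_rates()] object (or any list with `k_in`,
#'   `k_out`).
#' @param init An [initial_state()].
#' @param times Numeric vector of times, all `>= init$t0`.
#' @return Numeric vector of interior concentrations at `times`.
#' @export
analytic_trace <- function(rates, init, times) {
  stopifnot(inherits(init, "initial_state"))
  k_in <- rates$k_in
  k_out <- rates$k_out
  if (is.null(k_in) || is.null(k_out) || k_in < 0 || k_out < 0 ||
      k_in + k_out <= 0)
    stop("`rates` must provide nonnegative k_in, k_out with positive sum")
  if (any(times < init$t0)) stop("all `times` must be >= t0")
  k_t <- k_in + k_out
  e <- exp(-k_t * (times - init$t0))
  (init$n_in_0 * (k_out + k_in * e) + init$n_out_0 * k_out * (1 - e)) / k_t
}

#' Predicted FRAP and FLAP signals on a time grid
#'
#' `predict_frap()` is the interior recovery after a full interior bleach
#' (initial state `(0, n_tot)`): it rises from 0 to the stationary fraction.
#' `predict_flap()` is the measured loss signal of a fully photo-labelled
#' interior pool; it starts at `n_tot`, decays at the same turnover rate and
#' plateaus at the exterior stationary value `n_tot - n_in_bar` — the
#' complement of the recovery curve, matching the convention of
#' [stationary_concentration()] for FLAP traces.
#'
#' @param rates A [dynamic_rates()] object.
#' @param times Time grid, seconds (default 0 to 300 s in 10-s steps).
#' @param n_tot Conserved total concentration (default 1, normalized data).
#' @return Numeric vector of predicted intensities.
#' @export
predict_frap <- function(rates, times = seq(0, 300, by = 10), n_tot = 1) {
  analytic_trace(rates, initial_state(0, n_tot), times)
}

#' @rdname predict_frap
#' @export
predict_flap <- function(rates, times = seq(0, 300, by = 10), n_tot = 1) {
  n_tot - analytic_trace(rates, initial_state(0, n_tot), times)
}

#' First-order uncertainty propagation for the inverted rates
#'
#' Propagates independent Gaussian 1-sigma uncertainties of the observables
#' through the inversion `k_out = n_in_bar * k_t`, `k_in = (1 - n_in_bar) * k_t`:
#' `sigma_k_out = sqrt((n_in_bar * sigma_k_t)^2 + (k_t * sigma_n_in_bar)^2)`
#' and analogously for `k_in` with `1 - n_in_bar`.
#'
#' @param k_t,n_in_bar Observables.
#' @param sigma_k_t,sigma_n_in_bar Nonnegative 1-sigma uncertainties.
#' @return Named vector `c(sigma_k_in =, sigma_k_out =)`.
#' @export
propagate_uncertainty <- function(k_t, sigma_k_t, n_in_bar, sigma_n_in_bar) {
  if (sigma_k_t < 0 || sigma_n_in_bar < 0) stop("sigmas must be nonnegative")
  c(sigma_k_in = sqrt(((1 - n_in_bar) * sigma_k_t)^2 + (k_t * sigma_n_in_bar)^2),
    sigma_k_out = sqrt((n_in_bar * sigma_k_t)^2 + (k_t * sigma_n_in_bar)^2))
}
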