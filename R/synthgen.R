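#' Specification for the synthetic trace generator
#'
#' Describes a ground-truth exchange process and an acquisition protocol.
#' Defaults emulate the standard FRAP protocol for focal adhesion proteins:
#' 10-s sampling for 5 minutes, additive i.i.d. Gaussian intensity noise of
#' 0.02 on the normalized scale.
#'
#' @param k_in,k_out Ground-truth entry/exit rates, /s, positive sum.
#' @param modality `"FRAP"` or `"FLAP"`.
#' @param n_traces Number of replicates (default 20).
#' @param duration Acquisition length, seconds (default 300).
#' @param dt Sampling interval, seconds (default 10, `dt < duration`).
#' @param noise_sigma Gaussian noise standard deviation on the normalized
#'   intensity scale (default 0.02; 0 gives noiseless traces).
#' @param seed Integer seed (default 1).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(k_in, k_out, modality = c("FRAP", "FLAP"),
                           n_traces = 20L, duration = 300, dt = 10,
                           noise_sigma = 0.02, seed = 1L) {
  modality <- match.arg(toupper(modality[[1L]]), c("FRAP", "FLAP"))
  if (k_in < 0 || k_out < 0 || k_in + k_out <= 0)
    stop("rates must be nonnegative with positive sum")
  if (n_traces < 1L) stop("`n_traces` must be at least 1")
  if (dt <= 0 || duration <= 0 || dt >= duration)
    stop("need 0 < dt < duration")
  if (noise_sigma < 0) stop("`noise_sigma` must be nonnegative")
  structure(
    list(k_in = k_in, k_out = k_out, modality = modality,
         n_traces = as.integer(n_traces), duration = duration, dt = dt,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf(
    "<generator_spec> %s, k_in %.4g /s, k_out %.4g /s, %d traces, 0..%g s by %g s, sigma %.3g, seed %d\n",
    x$modality, x$k_in, x$k_out, x$n_traces, x$duration, x$dt,
    x$noise_sigma, x$seed))
  invisible(x)
}

.generator_signal <- function(spec, times) {
  rates <- rates_from_in_out(spec$k_in, spec$k_out, protein = "synthetic")
  if (spec$modality == "FRAP") predict_frap(rates, times)
  else predict_flap(rates, times)
}

#' Generate synthetic replicate traces with known ground truth
#'
#' Each replicate is the closed-form modality-appropriate signal on the
#' regular grid `0, dt, ..., duration` plus independent Gaussian noise.
#' Reproducible given the spec's seed; exactly equal to the model curve when
#' `noise_sigma = 0`.
#'
#' @param spec A [generator_spec()].
#' @return A [trace_set()] labelled `synthetic-01`, `synthetic-02`, ...
#' @export
generate_traces <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  times <- seq(0, spec$duration, by = spec$dt)
  signal <- .generator_signal(spec, times)
  set.seed(spec$seed)
  traces <- lapply(seq_len(spec$n_traces), function(i)
    intensity_trace(times,
                    signal + stats::rnorm(length(times), 0, spec$noise_sigma),
                    modality = spec$modality,
                    label = sprintf("synthetic-%02d", i)))
  trace_set(traces, protein = "synthetic")
}

#' Generate traces with planted fast/slow outlier replicates
#'
#' Appends `n_outliers` replicates whose ground-truth rates are scaled by
#' `rate_multiplier` (same stationary fraction, turnover multiplied), with
#' labels `outlier-01`, ... so tests can verify that the interquartile
#' fences flag exactly the planted curves.
#'
#' @param spec A [generator_spec()] for the regular replicates.
#' @param n_outliers Number of planted outliers (0 reduces to
#'   [generate_traces()]).
#' @param rate_multiplier Positive factor, different from 1.
#' @return A [trace_set()]; the attribute `"planted"` holds the outlier
#'   labels.
#' @export
generate_outlier_set <- function(spec, n_outliers = 1L, rate_multiplier = 10) {
  stopifnot(inherits(spec, "generator_spec"))
  if (rate_multiplier <= 0 || rate_multiplier == 1)
    stop("`rate_multiplier` must be positive and different from 1")
  if (n_outliers < 0L) stop("`n_outliers` must be nonnegative")
  times <- seq(0, spec$duration, by = spec$dt)
  signal <- .generator_signal(spec, times)
  out_spec <- spec
  out_spec$k_in <- spec$k_in * rate_multiplier
  out_spec$k_out <- spec$k_out * rate_multiplier
  out_signal <- .generator_signal(out_spec, times)
  set.seed(spec$seed)
  regular <- lapply(seq_len(spec$n_traces), function(i)
    intensity_trace(times,
                    signal + stats::rnorm(length(times), 0, spec$noise_sigma),
                    modality = spec$modality,
                    label = sprintf("synthetic-%02d", i)))
  planted <- lapply(seq_len(n_outliers), function(i)
    intensity_trace(times,
                    out_signal + stats::rnorm(length(times), 0, spec$noise_sigma),
                    modality = spec$modality,
                    label = sprintf("outlier-%02d", i)))
  out <- trace_set(c(regular, planted), protein = "synthetic")
  attr(out, "planted") <- vapply(planted, `[[`, character(1L), "label")
  out
}
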