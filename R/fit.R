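#' Fit the exchange model to a set of replicate FRAP/FLAP traces
#'
#' The main entry point of the package.  Runs the full inference pipeline on
#' one protein's replicates:
#' \enumerate{
#'   \item each replicate is fitted with the single-exponential model
#'     ([fit_exponential()]);
#'   \item replicates whose exponential rate falls outside the Tukey
#'     interquartile fences are discarded ([remove_outliers()]; skipped when
#'     fewer than 4 replicates are available or `outliers = FALSE`);
#'   \item the retained replicates are averaged pointwise
#'     ([average_trace()]) and the average curve is fitted;
#'   \item the observables — turnover rate `k_t = |R0|` and stationary
#'     interior fraction from the plateau ([stationary_concentration()]) —
#'     are inverted into the entry and exit rates with first-order
#'     uncertainty propagation ([dynamic_rates()]).
#' }
#' The uncertainty of `k_t` is the least-squares standard error of `R0` on
#' the average curve; the plateau uncertainty is the standard error of the
#' `m` trailing points when `m > 1`, else the residual standard deviation of
#' the average-curve fit.
#'
#' @param traces A [trace_set()], or a file path readable by
#'   [read_traces()].
#' @param modality `"FRAP"` or `"FLAP"`; required when `traces` is a path,
#'   otherwise taken from the set.
#' @param m Trailing points averaged for the plateau (default 1, the
#'   literal final intensity).
#' @param outliers Apply interquartile outlier removal (default TRUE).
#' @param n_tot Conserved total concentration (default 1, normalized data).
#' @param protein Optional label override.
#' @return An object of class `fa_fit` with components `rates`
#'   ([dynamic_rates()]), `average_fit` (`exp_fit` of the average curve),
#'   `replicate_fits`, `outlier_bounds`, `removed` (labels), `average`
#'   (the averaged trace), `traces`, `modality`, `m`, `n_tot`, `call`.
#'   Supported methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#' @export
#' @examples
#' spec <- generator_spec(k_in = 0.00494, k_out = 0.00635, "FRAP",
#'                        n_traces = 8, noise_sigma = 0.01, seed = 7)
#' fit <- fa_fit(generate_traces(spec))
#' fit
#' coef(fit)
fa_fit <- function(traces, modality = NULL, m = 1L, outliers = TRUE,
                   n_tot = 1, protein = NULL) {
  cl <- match.call()
  if (is.character(traces)) {
    if (is.null(modality))
      stop("`modality` is required when `traces` is a file path")
    traces <- read_traces(traces, modality = modality)
  }
  stopifnot(inherits(traces, "trace_set"))
  if (!is.null(protein)) traces$protein <- protein

  rep_fits <- lapply(traces$traces, fit_exponential)
  bounds <- NULL
  removed_lab <- character()
  kept <- traces
  if (isTRUE(outliers) && length(rep_fits) >= 4L) {
    sel <- remove_outliers(rep_fits)
    bounds <- sel$bounds
    if (length(sel$removed)) {
      removed_lab <- vapply(traces$traces[sel$removed], `[[`, character(1L),
                            "label")
      kept <- traces[-sel$removed]
    }
  }

  avg <- average_trace(kept)
  avg_fit <- fit_exponential(avg)
  k_t <- turnover_rate(avg_fit)
  n_in_bar <- stationary_concentration(avg, m = m, n_tot = n_tot)

  sigma_k_t <- avg_fit$se[["R0"]]
  if (!is.finite(sigma_k_t)) sigma_k_t <- 0
  sigma_plateau <- if (m > 1L) {
    nlast <- utils::tail(avg$intensities, m)
    stats::sd(nlast) / sqrt(m)
  } else {
    df <- max(avg_fit$n_points - 3L, 1L)
    sqrt(avg_fit$residual_sse / df)
  }

  rates <- dynamic_rates(k_t = k_t, n_in_bar = n_in_bar,
                         sigma_k_t = sigma_k_t,
                         sigma_n_in_bar = sigma_plateau / n_tot,
                         protein = traces$protein)
  structure(
    list(rates = rates, average_fit = avg_fit, replicate_fits = rep_fits,
         outlier_bounds = bounds, removed = removed_lab, average = avg,
         traces = traces, modality = traces$modality, m = m, n_tot = n_tot,
         call = cl),
    class = "fa_fit")
}

#' @export
print.fa_fit <- function(x, ...) {
  r <- x$rates
  cat(sprintf("Exchange-model fit: %s (%s, %d replicate(s), %d removed)\n",
              r$protein, x$modality, length(x$traces),
              length(x$removed)))
  cat(sprintf("  k_t      = %8.3f e-3 /s  (+/- %.3f)\n",
              1e3 * r$k_t, 1e3 * r$sigma_k_t))
  cat(sprintf("  k_in     = %8.3f e-3 /s  (+/- %.3f)\n",
              1e3 * r$k_in, 1e3 * r$sigma_k_in))
  cat(sprintf("  k_out    = %8.3f e-3 /s  (+/- %.3f)\n",
              1e3 * r$k_out, 1e3 * r$sigma_k_out))
  cat(sprintf("  n_in_bar = %8.3f         (+/- %.3f)\n",
              r$n_in_bar, r$sigma_n_in_bar))
  invisible(x)
}

#' @export
summary.fa_fit <- function(object, ...) {
  reps <- data.frame(
    label = vapply(object$replicate_fits, `[[`, character(1L), "label"),
    y0 = vapply(object$replicate_fits, `[[`, numeric(1L), "y0"),
    A = vapply(object$replicate_fits, `[[`, numeric(1L), "A"),
    R0 = vapply(object$replicate_fits, `[[`, numeric(1L), "R0"),
    sse = vapply(object$replicate_fits, `[[`, numeric(1L), "residual_sse"),
    kept = !(vapply(object$replicate_fits, `[[`, character(1L), "label")
             %in% object$removed),
    stringsAsFactors = FALSE)
  structure(list(fit = object, replicates = reps), class = "summary.fa_fit")
}

#' @export
print.summary.fa_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$outlier_bounds)) {
    cat("Replicate R0 fences: ")
    print(x$fit$outlier_bounds)
  }
  cat("Replicate fits:\n")
  print(x$replicates, row.names = FALSE, digits = 4)
  af <- x$fit$average_fit
  cat(sprintf("Average-curve fit: y0 = %.4g, A = %.4g, R0 = %.4g /s, SSE = %.3g\n",
              af$y0, af$A, af$R0, af$residual_sse))
  invisible(x)
}

#' @export
coef.fa_fit <- function(object, ...) {
  r <- object$rates
  c(k_t = r$k_t, k_in = r$k_in, k_out = r$k_out, n_in_bar = r$n_in_bar)
}

#' Predicted signal from a fitted exchange model
#'
#' @param object An `fa_fit`.
#' @param times Time grid (defaults to the averaged-trace grid).
#' @param type `"signal"` (modality-appropriate measured intensity, the
#'   default) or `"interior"` (interior concentration from the closed form
#'   with FRAP-like initial state).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.fa_fit <- function(object, times = object$average$times,
                           type = c("signal", "interior"), ...) {
  type <- match.arg(type)
  if (type == "interior" || object$modality == "FRAP")
    predict_frap(object$rates, times = times, n_tot = object$n_tot)
  else
    predict_flap(object$rates, times = times, n_tot = object$n_tot)
}

#' @export
fitted.fa_fit <- function(object, ...) predict(object)

#' @export
residuals.fa_fit <- function(object, ...) {
  object$average$intensities - predict(object)
}

#' Plot a fitted exchange model
#'
#' Replicates in grey, the average curve in black and the model prediction
#' from the inverted rates as a line.
#'
#' @param x An `fa_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fa_fit <- function(x, ...) {
  xs <- x$average$times
  ylim <- range(unlist(lapply(x$traces$traces, `[[`, "intensities")))
  graphics::plot(xs, x$average$intensities, type = "n", ylim = ylim,
                 xlab = "time (s)", ylab = "normalized intensity",
                 main = sprintf("%s (%s)", x$rates$protein, x$modality), ...)
  for (tr in x$traces$traces)
    graphics::lines(tr$times, tr$intensities,
                    col = grDevices::grey(0.8))
  graphics::points(xs, x$average$intensities, pch = 16, cex = 0.6)
  fine <- seq(min(xs), max(xs), length.out = 200L)
  graphics::lines(fine, predict(x, times = fine), lwd = 2)
  invisible(x)
}

#' Simulate stochastic trajectories from a fitted exchange model
#'
#' Draws `nsim` exact Gillespie trajectories of the base birth-death model
#' calibrated to the fitted rates, sampled on a regular grid and returned as
#' interior fractions.
#'
#' @param object An `fa_fit`.
#' @param nsim Number of trajectories (default 1).
#' @param seed Optional integer seed.
#' @param n_tot Molecule count for the jump process (default 1000).
#' @param t_max,dt Grid definition (defaults: the fitted trace horizon and
#'   its median sampling step).
#' @param ... Unused.
#' @return A `data.frame` with column `time` and one column `simi` per
#'   trajectory.
#' @export
simulate.fa_fit <- function(object, nsim = 1L, seed = NULL, n_tot = 1000L,
                            t_max = max(object$average$times),
                            dt = stats::median(diff(object$average$times)),
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- build_base(object$rates, n_tot = n_tot)
  grid <- seq(0, t_max, by = dt)
  init <- if (object$modality == "FRAP") 0L else model$n_tot
  out <- data.frame(time = grid)
  for (i in seq_len(nsim))
    out[[paste0("sim", i)]] <- .ssa_grid(model, grid, init) / model$n_tot
  out
}
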