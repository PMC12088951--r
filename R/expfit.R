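#' Fit the single-exponential recovery/loss model to a trace
#'
#' Fits `y = y0 + A * exp(R0 * t)` by Levenberg-Marquardt least squares
#' (via \pkg{minpack.lm}).  Initialization is deterministic: `y0` starts at
#' the last intensity, `A` at first minus last, and `R0` at the slope of
#' `log|y - y0|` over the first half of the points; up to `max_restarts`
#' deterministic restarts rescale the starting `R0` by {0.5, 2, 0.25, 4}.
#' The exponential term must decay (`R0 < 0`) for both modalities; the sign
#' of `A` distinguishes recovery (`A < 0`, FRAP) from loss (`A > 0`, FLAP),
#' and a fit whose `A` sign contradicts the trace modality triggers a
#' warning and is flagged, not rejected.
#'
#' @param trace An [intensity_trace()] with at least 4 points and
#'   non-constant intensities.
#' @param max_restarts Maximum number of restarts (default 5 starts total).
#' @return An object of class `exp_fit`: list with `y0`, `A`, `R0`, their
#'   standard errors `se` (from the least-squares covariance; `NA` when the
#'   covariance is singular, e.g. a perfect fit), `residual_sse`,
#'   `n_points`, `modality`, `label`, `converged`, `sign_ok`.
#' @export
#' @examples
#' t <- seq(0, 300, 10)
#' tr <- intensity_trace(t, 0.56 - 0.56 * exp(-0.0113 * t), "FRAP")
#' fit_exponential(tr)
fit_exponential <- function(trace, max_restarts = 5L) {
  stopifnot(inherits(trace, "intensity_trace"))
  t <- trace$times
  y <- trace$intensities
  n <- length(y)
  if (diff(range(y)) < .Machine$double.eps * 100)
    stop("constant trace: the exponential model is unidentifiable")

  y0_0 <- y[n]
  A_0 <- y[1L] - y[n]
  half <- seq_len(max(3L, n %/% 2L))
  dy <- abs(y[half] - y0_0)
  usable <- dy > 1e-8 * max(abs(y), 1)
  R0_0 <- if (sum(usable) >= 3L) {
    stats::coef(stats::lm(log(dy[usable]) ~ t[half][usable]))[[2L]]
  } else {
    -log(2) / (0.3 * diff(range(t)))
  }
  if (!is.finite(R0_0) || R0_0 >= 0) R0_0 <- -log(2) / (0.3 * diff(range(t)))

  dat <- data.frame(t = t, y = y)
  factors <- c(1, 0.5, 2, 0.25, 4)[seq_len(max(1L, min(5L, max_restarts)))]
  fit <- NULL
  for (f in factors) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + A * exp(R0 * t), data = dat,
        start = list(y0 = y0_0, A = A_0, R0 = R0_0 * f),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("exponential fit did not converge after deterministic restarts")

  cf <- stats::coef(fit)
  if (cf[["R0"]] >= 0)
    stop("fitted R0 is nonnegative: the ", trace$modality,
         " signal must relax exponentially (R0 < 0)")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(y0 = NA_real_, A = NA_real_, R0 = NA_real_))

  expect_A_neg <- trace$modality == "FRAP"
  sign_ok <- if (expect_A_neg) cf[["A"]] < 0 else cf[["A"]] > 0
  if (!sign_ok)
    warning(sprintf("amplitude sign (A = %.3g) contradicts %s modality",
                    cf[["A"]], trace$modality), call. = FALSE)

  structure(
    list(y0 = unname(cf[["y0"]]), A = unname(cf[["A"]]), R0 = unname(cf[["R0"]]),
         se = c(y0 = unname(se[["y0"]]), A = unname(se[["A"]]),
                R0 = unname(se[["R0"]])),
         residual_sse = sum(stats::residuals(fit)^2),
         n_points = n, modality = trace$modality, label = trace$label,
         converged = TRUE, sign_ok = sign_ok),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> %s (%s): y0 = %.4g, A = %.4g, R0 = %.4g /s (SSE %.3g, n = %d)\n",
    x$label, x$modality, x$y0, x$A, x$R0, x$residual_sse, x$n_points))
  invisible(x)
}

#' Turnover rate from an exponential fit
#'
#' The turnover rate is the magnitude of the fitted exponential rate,
#' `k_t = |R0|`, in /s.
#'
#' @param fit An `exp_fit` object.
#' @return Positive scalar, /s.
#' @export
turnover_rate <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  if (fit$R0 == 0) stop("R0 is zero: no turnover can be extracted")
  abs(fit$R0)
}

#' Stationary mobile concentration from a normalized trace
#'
#' Reads the plateau as the mean of the last `m` intensities.  For FRAP the
#' plateau is the stationary interior concentration directly; for FLAP the
#' measured plateau is the exterior stationary value and the interior
#' stationary concentration is its complement, `n_tot - plateau`.
#'
#' @param trace A normalized [intensity_trace()].
#' @param m Number of trailing points averaged (default 1, the literal last
#'   point; larger `m` is more robust to plateau noise).
#' @param n_tot Total (conserved) concentration after normalization,
#'   default 1.
#' @return The stationary interior concentration `n_in_bar`, clamped to
#'   `[0, n_tot]`; values outside that range by more than 0.1 * n_tot are an
#'   error (the trace is probably not normalized).
#' @export
stationary_concentration <- function(trace, m = 1L, n_tot = 1) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$times)
  if (!is.numeric(m) || m < 1L || m > n)
    stop("`m` must be between 1 and the trace length (", n, ")")
  plateau <- mean(trace$intensities[seq.int(n - m + 1L, n)])
  val <- if (trace$modality == "FLAP") n_tot - plateau else plateau
  if (val < -0.1 * n_tot || val > 1.1 * n_tot)
    stop(sprintf("stationary concentration %.3g outside [0, %g] beyond tolerance; is the trace normalized?",
                 val, n_tot))
  min(max(val, 0), n_tot)
}

#' Interquartile-range outlier fences for replicate fits
#'
#' Computes Tukey fences on the fitted exponential rates `R0` of a sample of
#' replicate fits (quartiles by linear interpolation, type 7) and drops the
#' replicates falling outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#'
#' @param fits List of at least 4 `exp_fit` objects.
#' @return List with `kept` (the retained fits, order preserved), `bounds`
#'   (an `outlier_bounds` object with `q1`, `q3`, `iqr`, `lcl`, `ucl`) and
#'   `removed` (integer indices of the dropped fits).
#' @export
remove_outliers <- function(fits) {
  if (inherits(fits, "exp_fit")) fits <- list(fits)
  if (!is.list(fits) || length(fits) < 4L)
    stop("outlier detection needs at least 4 replicate fits")
  ok <- vapply(fits, inherits, logical(1L), what = "exp_fit")
  if (!all(ok)) stop("`fits` must be a list of exp_fit objects")
  r0 <- vapply(fits, `[[`, numeric(1L), "R0")
  q <- stats::quantile(r0, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[[2L]] - q[[1L]]
  bounds <- structure(
    list(q1 = q[[1L]], q3 = q[[2L]], iqr = iqr,
         lcl = q[[1L]] - 1.5 * iqr, ucl = q[[2L]] + 1.5 * iqr),
    class = "outlier_bounds")
  keep <- r0 >= bounds$lcl & r0 <= bounds$ucl
  list(kept = fits[keep], bounds = bounds, removed = which(!keep))
}

#' @export
print.outlier_bounds <- function(x, ...) {
  cat(sprintf(
    "<outlier_bounds> Q1 = %.4g, Q3 = %.4g, IQR = %.4g, fences [%.4g, %.4g]\n",
    x$q1, x$q3, x$iqr, x$lcl, x$ucl))
  invisible(x)
}

#' Pointwise average of replicate traces
#'
#' All traces must share an identical time grid after truncation to the
#' common (shortest) length; the result is the pointwise mean intensity on
#' that grid, with modality preserved.
#'
#' @param traces A [trace_set()].
#' @param label Label for the averaged trace.
#' @return An [intensity_trace()].
#' @export
average_trace <- function(traces, label = NULL) {
  stopifnot(inherits(traces, "trace_set"))
  n_min <- min(vapply(traces$traces, function(tr) length(tr$times), integer(1L)))
  if (n_min < 4L) stop("common prefix of the time grids is shorter than 4 points")
  grid <- traces$traces[[1L]]$times[seq_len(n_min)]
  same <- vapply(traces$traces, function(tr)
    isTRUE(all.equal(tr$times[seq_len(n_min)], grid, tolerance = 1e-8)),
    logical(1L))
  if (!all(same))
    stop("incompatible time grids: replicates share no common prefix")
  mat <- vapply(traces$traces, function(tr) tr$intensities[seq_len(n_min)],
                numeric(n_min))
  intensity_trace(grid, rowMeans(mat), modality = traces$modality,
                  label = label %||% paste0(traces$protein, "-average"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
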