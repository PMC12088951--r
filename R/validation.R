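#' Mean absolute percentage error
#'
#' `100 * mean(|predicted - observed| / |observed|)` over the retained
#' points.  Observations with `|observed| < 1e-12` are excluded before
#' averaging (under the exchange model the FRAP signal is exactly 0 at the
#' bleach time, where a relative error is undefined).
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return MAPE in percent (nonnegative scalar).
#' @export
mape <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 1L)
    stop("`predicted` and `observed` must be nonempty and of equal length")
  keep <- abs(observed) > 1e-12
  if (!any(keep)) stop("all observed points were excluded as zero")
  100 * mean(abs(predicted[keep] - observed[keep]) / abs(observed[keep]))
}

#' Root-mean-square error
#'
#' @param predicted,observed Equal-length nonempty numeric vectors.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 1L)
    stop("`predicted` and `observed` must be nonempty and of equal length")
  sqrt(mean((predicted - observed)^2))
}

#' Qualitative interpretation of a MAPE value
#'
#' Standard forecasting bands: below 10% highly accurate, 10-20% good,
#' 20-50% reasonable, 50% and above inaccurate.  Band edges are half-open
#' with the lower edge inclusive.
#'
#' @param m MAPE in percent, nonnegative.
#' @return One of `"Highly accurate"`, `"Good"`, `"Reasonable"`,
#'   `"Inaccurate"`.
#' @export
interpret_mape <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0)
    stop("`m` must be a nonnegative scalar")
  if (m < 10) "Highly accurate"
  else if (m < 20) "Good"
  else if (m < 50) "Reasonable"
  else "Inaccurate"
}

#' Repeated K-fold cross-validation of the exchange model
#'
#' For each repetition the replicate traces are shuffled with the seeded
#' generator and split into `k` folds (sizes differing by at most one).
#' For every fold the remaining traces are averaged ([average_trace()]),
#' fitted ([fit_exponential()]), reduced to observables (`k_t = |R0|`,
#' plateau via [stationary_concentration()]), inverted ([dynamic_rates()])
#' and used to predict the modality-appropriate signal on the validation
#' grid; the prediction is scored by [mape()] against the held-out fold's
#' average curve (or against each held-out replicate with
#' `score = "replicate"`).  The repetition MAPE is the mean over folds.
#'
#' @param traces A [trace_set()] with at least `k` replicates on one grid.
#' @param k Number of folds, `>= 2`.
#' @param reps Number of repetitions (default 100).
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @param m Trailing points used for the plateau (see
#'   [stationary_concentration()]).
#' @param n_tot Conserved total concentration (default 1).
#' @param score `"average"` (default) or `"replicate"`.
#' @return Object of class `cv_result`: `k`, `reps`, `per_rep_mape`,
#'   `mape_mean`, `mape_se` (standard error over repetitions).
#' @export
kfold_cv <- function(traces, k, reps = 100L, seed = 1L, m = 1L, n_tot = 1,
                     score = c("average", "replicate")) {
  stopifnot(inherits(traces, "trace_set"))
  score <- match.arg(score)
  n <- length(traces)
  if (k < 2L) stop("`k` must be at least 2")
  if (n < k) stop("number of traces (", n, ") must be at least k (", k, ")")
  if (reps < 1L) stop("`reps` must be at least 1")
  set.seed(seed)
  fold_id <- rep(seq_len(k), length.out = n)
  per_rep <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n)
    fold_mape <- numeric(k)
    for (j in seq_len(k)) {
      val_idx <- idx[fold_id == j]
      train_idx <- idx[fold_id != j]
      avg_train <- average_trace(traces[train_idx])
      fit <- fit_exponential(avg_train)
      rates <- dynamic_rates(k_t = turnover_rate(fit),
                             n_in_bar = stationary_concentration(avg_train, m = m,
                                                                 n_tot = n_tot),
                             protein = traces$protein)
      avg_val <- average_trace(traces[val_idx])
      pred <- if (traces$modality == "FRAP")
        predict_frap(rates, times = avg_val$times, n_tot = n_tot)
      else
        predict_flap(rates, times = avg_val$times, n_tot = n_tot)
      fold_mape[j] <- if (score == "average") {
        mape(pred, avg_val$intensities)
      } else {
        mean(vapply(traces[val_idx]$traces, function(tr)
          mape(pred[seq_along(tr$intensities)], tr$intensities), numeric(1L)))
      }
    }
    per_rep[r] <- mean(fold_mape)
  }
  structure(
    list(k = k, reps = reps, per_rep_mape = per_rep,
         mape_mean = mean(per_rep),
         mape_se = if (reps > 1L) stats::sd(per_rep) / sqrt(reps) else NA_real_,
         protein = traces$protein),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  se <- if (is.na(x$mape_se)) "" else sprintf(" +/- %.3g", x$mape_se)
  cat(sprintf("<cv_result> %s: K = %d, %d repetition(s), MAPE = %.3g%s%% (%s)\n",
              x$protein, x$k, x$reps, x$mape_mean, se,
              interpret_mape(x$mape_mean)))
  invisible(x)
}

#' Tabulate cross-validation results across fold counts
#'
#' Convenience wrapper running [kfold_cv()] for several values of `k` and
#' returning one report row per value, with the interpretation band.
#'
#' @param traces A [trace_set()].
#' @param k_values Integer vector of fold counts (default `c(3, 5, 10)`).
#' @param reps,seed,m,n_tot,score Passed to [kfold_cv()].
#' @return A `data.frame` with columns `protein`, `k`, `mape`, `se`,
#'   `interpretation`.
#' @export
cv_report <- function(traces, k_values = c(3L, 5L, 10L), reps = 100L,
                      seed = 1L, m = 1L, n_tot = 1,
                      score = c("average", "replicate")) {
  score <- match.arg(score)
  rows <- lapply(k_values, function(k) {
    res <- kfold_cv(traces, k = k, reps = reps, seed = seed, m = m,
                    n_tot = n_tot, score = score)
    data.frame(protein = res$protein, k = k, mape = res$mape_mean,
               se = res$mape_se, interpretation = interpret_mape(res$mape_mean),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
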