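#' Construct an interaction network model for one focal protein
#'
#' The focal protein's exchange with the region of interest is a birth-death
#' jump process on the interior copy number `n`: an entry channel with
#' propensity `entry * (n_tot - n)` and an exit channel with propensity
#' `exit * n`.  Partner proteins couple through their own entry rates with
#' propensities proportional to the focal interior count: a partner with
#' `sign = +1` (recruitment/retention) adds a gain channel `k_p * n`
#' (capped so the interior never exceeds `n_tot`), a partner with
#' `sign = -1` (destabilization) adds a loss channel `k_p * n`.
#'
#' The mean interior fraction relaxes with effective rate
#' `lambda = entry + exit - sum(gain partners) + sum(loss partners)` toward
#' the fixed point `entry / lambda`; `lambda > 0` is required at
#' construction (stability).
#'
#' @param entry,exit Nonnegative per-capita channel coefficients, /s.
#' @param partners `NULL`, or a `data.frame`/list of lists with fields
#'   `label`, `k_in` (nonnegative, /s) and `sign` (`+1` or `-1`).
#' @param n_tot Integer system size (molecule count), `>= 1`.
#' @param protein Label of the focal protein.
#' @return Object of class `network_model` with the channel coefficients,
#'   the partner table, `lambda` (effective relaxation rate, /s) and
#'   `steady_state` (mean-field interior fraction).
#' @seealso [build_base()], [gillespie_run()], [mean_field_solution()]
#' @export
network_model <- function(entry, exit, partners = NULL, n_tot = 1000L,
                          protein = "protein") {
  if (entry < 0 || exit < 0) stop("channel coefficients must be nonnegative")
  if (!is.numeric(n_tot) || n_tot < 1 || n_tot != round(n_tot))
    stop("`n_tot` must be a positive integer molecule count")
  if (is.null(partners)) {
    partners <- data.frame(label = character(), k_in = numeric(),
                           sign = numeric(), stringsAsFactors = FALSE)
  } else if (!is.data.frame(partners)) {
    partners <- do.call(rbind, lapply(partners, function(p)
      data.frame(label = p$label, k_in = p$k_in, sign = p$sign,
                 stringsAsFactors = FALSE)))
  }
  if (nrow(partners)) {
    if (any(partners$k_in < 0)) stop("partner rates must be nonnegative")
    if (!all(partners$sign %in% c(-1, 1))) stop("partner sign must be +1 or -1")
    partners <- partners[partners$k_in > 0, , drop = FALSE]
  }
  gain <- sum(partners$k_in[partners$sign > 0])
  loss <- sum(partners$k_in[partners$sign < 0])
  if (entry + exit - gain <= 0)
    stop(sprintf(
      "unstable model: entry + exit - partner gain = %.3g <= 0 /s",
      entry + exit - gain))
  lambda <- entry + exit - gain + loss
  structure(
    list(entry = entry, exit = exit, partners = partners,
         partner_gain = gain, partner_loss = loss,
         n_tot = as.integer(round(n_tot)), protein = as.character(protein)[[1L]],
         lambda = lambda, steady_state = entry / lambda),
    class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %s: entry %.4g /s, exit %.4g /s, n_tot = %d\n",
              x$protein, x$entry, x$exit, x$n_tot))
  if (nrow(x$partners))
    for (i in seq_len(nrow(x$partners)))
      cat(sprintf("  partner %s: k_in %.4g /s (%s)\n",
                  x$partners$label[i], x$partners$k_in[i],
                  if (x$partners$sign[i] > 0) "gain" else "loss"))
  cat(sprintf("  effective rate %.4g /s, mean-field steady state %.4g\n",
              x$lambda, x$steady_state))
  invisible(x)
}

#' Base single-protein exchange model
#'
#' Calibrates the two-channel birth-death process to the protein's measured
#' observables, so that its mean trajectory is exactly the closed-form
#' intensity curve ([analytic_trace()]): the entry coefficient is
#' `n_in_bar * k_t` and the exit coefficient `(1 - n_in_bar) * k_t`.
#'
#' @param rates A [dynamic_rates()] object.
#' @param n_tot Integer system size (default 1000 molecules).
#' @return A [network_model()] with no partners.
#' @export
build_base <- function(rates, n_tot = 1000L) {
  stopifnot(inherits(rates, "dynamic_rates"))
  entry <- rates$n_in_bar * rates$k_t
  network_model(entry = entry, exit = rates$k_t - entry, partners = NULL,
                n_tot = n_tot, protein = rates$protein)
}

#' Partner-loss perturbation (vinculin-type coupling removed)
#'
#' Models the destabilization of the focal protein when a stabilizing
#' partner interaction is removed: the partner's entry rate feeds an
#' additional interior-loss channel `k_in_partner * n`, so the effective
#' turnover `lambda = k_t + k_in_partner` is faster than the base model and
#' the stationary interior fraction is lowered.
#'
#' @param rates Focal-protein [dynamic_rates()] (e.g. talin).
#' @param k_in_partner Partner entry rate, /s, nonnegative (e.g. vinculin's).
#' @param n_tot Integer system size.
#' @param label Partner label.
#' @return A [network_model()]; with `k_in_partner = 0` it is identical to
#'   [build_base()].
#' @export
build_vinculin_loss <- function(rates, k_in_partner, n_tot = 1000L,
                                label = "vinculin") {
  stopifnot(inherits(rates, "dynamic_rates"))
  if (k_in_partner < 0) stop("`k_in_partner` must be nonnegative")
  base <- build_base(rates, n_tot = n_tot)
  network_model(entry = base$entry, exit = base$exit,
                partners = list(list(label = label, k_in = k_in_partner,
                                     sign = -1)),
                n_tot = n_tot, protein = rates$protein)
}

#' Partner-gain perturbation (actomyosin-type retention)
#'
#' Models increased retention through a constitutive cytoskeletal coupling:
#' the partner's entry rate feeds an additional interior-gain channel
#' `k_in_partner * n` (zero at the `n = n_tot` boundary), slowing the
#' effective turnover to `lambda = k_t - k_in_partner` and raising the
#' stationary interior fraction.  Requires `k_t > k_in_partner` (stability).
#'
#' @inheritParams build_vinculin_loss
#' @return A [network_model()]; with `k_in_partner = 0` it is identical to
#'   [build_base()].
#' @export
build_actin_gain <- function(rates, k_in_partner, n_tot = 1000L,
                             label = "alpha-actinin") {
  stopifnot(inherits(rates, "dynamic_rates"))
  if (k_in_partner < 0) stop("`k_in_partner` must be nonnegative")
  base <- build_base(rates, n_tot = n_tot)
  network_model(entry = base$entry, exit = base$exit,
                partners = list(list(label = label, k_in = k_in_partner,
                                     sign = +1)),
                n_tot = n_tot, protein = rates$protein)
}

#' Three-protein interaction model
#'
#' Two recruiting partners acting on the focal protein; by linearity of the
#' propensities this is equivalent to a single gain partner with the summed
#' rate.
#'
#' @param rates Focal-protein [dynamic_rates()].
#' @param p2_k_in,p3_k_in Nonnegative partner entry rates, /s.
#' @param n_tot Integer system size.
#' @return A [network_model()].
#' @export
build_three_protein <- function(rates, p2_k_in, p3_k_in, n_tot = 1000L) {
  stopifnot(inherits(rates, "dynamic_rates"))
  if (p2_k_in < 0 || p3_k_in < 0) stop("partner rates must be nonnegative")
  base <- build_base(rates, n_tot = n_tot)
  network_model(entry = base$entry, exit = base$exit,
                partners = list(
                  list(label = "partner2", k_in = p2_k_in, sign = +1),
                  list(label = "partner3", k_in = p3_k_in, sign = +1)),
                n_tot = n_tot, protein = rates$protein)
}

# Exact SSA sampled onto a regular grid by last-observation-carried-forward
# (the exact semantics of a piecewise-constant jump process). Returns integer
# interior counts at the grid times.
.ssa_grid <- function(model, grid, n0) {
  entry <- model$entry
  exit_plus_loss <- model$exit + model$partner_loss
  pgain <- model$partner_gain
  n_tot <- model$n_tot
  ng <- length(grid)
  out <- integer(ng)
  n <- n0
  t <- grid[[1L]]
  gi <- 1L
  repeat {
    g <- entry * (n_tot - n) + if (n < n_tot) pgain * n else 0
    a <- g + exit_plus_loss * n
    if (a <= 0) { # absorbing state: pad the remaining grid with the last state
      out[gi:ng] <- n
      break
    }
    t <- t + stats::rexp(1L, a)
    while (grid[[gi]] < t) {
      out[[gi]] <- n
      gi <- gi + 1L
      if (gi > ng) break
    }
    if (gi > ng) break
    n <- n + if (stats::runif(1L) * a < g) 1L else -1L
  }
  out
}

#' Exact Gillespie simulation of a network model
#'
#' Stochastic simulation algorithm: exponential waiting times with the total
#' propensity, channel choice proportional to propensity, unit state
#' updates.  The trajectory terminates early in an absorbing state (all
#' propensities zero).
#'
#' @param model A [network_model()].
#' @param t_max Simulated horizon, seconds, positive.
#' @param init_fraction Initial interior fraction in `[0, 1]` (default 1,
#'   FLAP-like full interior labelling; use 0 for FRAP-like).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `trajectory`: `event_times` (seconds, first
#'   element the start time 0), `states` (integer interior counts,
#'   piecewise constant between events), `n_tot`.
#' @export
gillespie_run <- function(model, t_max, init_fraction = 1, seed = NULL) {
  stopifnot(inherits(model, "network_model"))
  if (t_max <= 0) stop("`t_max` must be positive")
  if (init_fraction < 0 || init_fraction > 1)
    stop("`init_fraction` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  entry <- model$entry
  exit_plus_loss <- model$exit + model$partner_loss
  pgain <- model$partner_gain
  n_tot <- model$n_tot
  n <- as.integer(round(init_fraction * n_tot))
  cap <- 4096L
  times <- numeric(cap)
  states <- integer(cap)
  times[[1L]] <- 0
  states[[1L]] <- n
  m <- 1L
  t <- 0
  repeat {
    g <- entry * (n_tot - n) + if (n < n_tot) pgain * n else 0
    a <- g + exit_plus_loss * n
    if (a <= 0) break
    t <- t + stats::rexp(1L, a)
    if (t > t_max) break
    n <- n + if (stats::runif(1L) * a < g) 1L else -1L
    m <- m + 1L
    if (m > cap) {
      cap <- cap * 2L
      length(times) <- cap
      length(states) <- cap
    }
    times[[m]] <- t
    states[[m]] <- n
  }
  structure(list(event_times = times[seq_len(m)], states = states[seq_len(m)],
                 n_tot = n_tot),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d events, final state %d / %d molecules\n",
              length(x$event_times) - 1L, x$states[[length(x$states)]], x$n_tot))
  invisible(x)
}

#' Ensemble statistics of repeated Gillespie runs
#'
#' Runs the SSA `n_runs` times, samples each trajectory onto a regular grid
#' (last observation carried forward), normalizes by the system size and
#' returns the pointwise mean and standard error of the mean.  Per-run seeds
#' are drawn up front from the seeded generator so the whole ensemble is
#' reproducible.
#'
#' @param model A [network_model()].
#' @param n_runs Number of runs, `>= 2` (default 1000).
#' @param t_max Horizon, seconds.
#' @param grid_dt Grid step, seconds (default 10).
#' @param init_fraction Initial interior fraction (default 1, FLAP-like).
#' @param seed Optional integer seed.
#' @return Object of class `ensemble_result`: `times`, `mean`, `stderr`
#'   (fractions of `n_tot`), `n_runs`, `n_tot`.
#' @export
ensemble <- function(model, n_runs = 1000L, t_max = 300, grid_dt = 10,
                     init_fraction = 1, seed = NULL) {
  stopifnot(inherits(model, "network_model"))
  if (n_runs < 2L) stop("`n_runs` must be at least 2")
  if (t_max <= 0 || grid_dt <= 0) stop("`t_max` and `grid_dt` must be positive")
  if (init_fraction < 0 || init_fraction > 1)
    stop("`init_fraction` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  grid <- seq(0, t_max, by = grid_dt)
  n0 <- as.integer(round(init_fraction * model$n_tot))
  mat <- matrix(0L, nrow = n_runs, ncol = length(grid))
  for (i in seq_len(n_runs)) {
    set.seed(run_seeds[[i]])
    mat[i, ] <- .ssa_grid(model, grid, n0)
  }
  frac <- mat / model$n_tot
  structure(
    list(times = grid, mean = colMeans(frac),
         stderr = apply(frac, 2L, stats::sd) / sqrt(n_runs),
         n_runs = n_runs, n_tot = model$n_tot, protein = model$protein),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> %s: %d runs, %d grid points, final mean %.4g +/- %.2g\n",
    x$protein, x$n_runs, length(x$times), x$mean[[length(x$mean)]],
    x$stderr[[length(x$stderr)]]))
  invisible(x)
}

#' @export
as.data.frame.ensemble_result <- function(x, ...) {
  data.frame(time = x$times, mean = x$mean, stderr = x$stderr)
}

#' Mean-field solution of a network model
#'
#' The expected interior fraction obeys the linear ODE
#' `d n/dt = entry * (1 - n) - (exit - gain + loss) * n` (fractions of
#' `n_tot`), whose closed form is exponential relaxation toward the fixed
#' point `entry / lambda` with the effective rate `lambda`.  For a base
#' model this reduces exactly to [analytic_trace()].
#'
#' @param model A [network_model()].
#' @param times Time grid, seconds.
#' @param init_fraction Initial interior fraction (default 1).
#' @return Numeric vector of interior fractions.
#' @export
mean_field_solution <- function(model, times, init_fraction = 1) {
  stopifnot(inherits(model, "network_model"))
  if (any(times < 0)) stop("`times` must be nonnegative")
  nstar <- model$steady_state
  nstar + (init_fraction - nstar) * exp(-model$lambda * times)
}
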