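test_that("network models are calibrated to the measured observables", {
  r <- tensin_rates()
  m <- build_base(r, n_tot = 1000)
  expect_equal(m$entry, r$n_in_bar * r$k_t)
  expect_equal(m$exit, r$k_t - m$entry)
  expect_equal(m$lambda, r$k_t)
  expect_equal(m$steady_state, r$n_in_bar)
  expect_error(build_base(r, n_tot = 0), "positive integer")
})

test_that("null perturbations reduce exactly to the base model", {
  r <- talin_rates()
  base <- build_base(r)
  expect_equal(build_vinculin_loss(r, 0), base)
  expect_equal(build_actin_gain(r, 0), base)
  expect_equal(build_three_protein(r, 0, 0), base)
})

test_that("partner couplings shift the effective rate and fixed point as expected", {
  r <- talin_rates()
  base <- build_base(r)
  vloss <- build_vinculin_loss(r, 0.0052)
  again <- build_actin_gain(r, 0.0061)

  # losing a stabilizing partner speeds turnover and lowers retention
  expect_equal(vloss$lambda, r$k_t + 0.0052)
  expect_lt(vloss$steady_state, base$steady_state)
  # constitutive cytoskeletal binding slows turnover and raises retention
  expect_equal(again$lambda, r$k_t - 0.0061)
  expect_gt(again$steady_state, base$steady_state)
  # ordering of effective relaxation rates
  expect_gt(vloss$lambda, base$lambda)
  expect_gt(base$lambda, again$lambda)

  # gain at the stability boundary is rejected
  expect_error(build_actin_gain(r, r$k_t), "unstable")
})

test_that("two recruiting partners are equivalent to one with the summed rate", {
  r <- talin_rates()
  m2 <- build_three_protein(r, 0.002, 0.003)
  m1 <- build_actin_gain(r, 0.005)
  expect_equal(m2$lambda, m1$lambda)
  expect_equal(m2$steady_state, m1$steady_state)
  expect_equal(m2$partner_gain, 0.005)
})

test_that("gillespie trajectories respect state bounds and absorbing states", {
  # all rates zero is not constructible (unstable); a pure-death model with a
  # zero-entry channel empties and then stays put
  m <- network_model(entry = 0, exit = 0.05, n_tot = 50)
  traj <- gillespie_run(m, t_max = 1e4, init_fraction = 1, seed = 1)
  expect_true(all(traj$states >= 0 & traj$states <= 50))
  expect_equal(traj$states[[length(traj$states)]], 0)
  expect_true(all(diff(traj$event_times) > 0))

  # a trajectory started in the absorbing state never moves
  traj0 <- gillespie_run(m, t_max = 100, init_fraction = 0, seed = 2)
  expect_equal(traj0$states, 0L)
})

test_that("pure-death ensembles follow the analytic decay law", {
  k <- 0.02
  m <- network_model(entry = 0, exit = k, n_tot = 400)
  ens <- ensemble(m, n_runs = 300, t_max = 100, grid_dt = 25,
                  init_fraction = 1, seed = 11)
  expected <- exp(-k * ens$times)
  dev <- abs(ens$mean - expected)
  expect_true(all(dev[-1L] <= 3 * ens$stderr[-1L]))
  expect_equal(ens$mean[[1L]], 1)
})

test_that("ensembles are seed-reproducible and tighten like 1/sqrt(n_runs)", {
  m <- build_base(tensin_rates(), n_tot = 200)
  a <- ensemble(m, n_runs = 50, t_max = 100, grid_dt = 20, seed = 42)
  b <- ensemble(m, n_runs = 50, t_max = 100, grid_dt = 20, seed = 42)
  expect_identical(a, b)

  small <- ensemble(m, n_runs = 250, t_max = 60, grid_dt = 30,
                    init_fraction = 0, seed = 9)
  big <- ensemble(m, n_runs = 1000, t_max = 60, grid_dt = 30,
                  init_fraction = 0, seed = 9)
  ratio <- mean(small$stderr[-1L]) / mean(big$stderr[-1L])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("mean-field solution reduces to the closed form and matches RK4", {
  r <- tensin_rates()
  m <- build_base(r)
  tt <- seq(0, 300, 10)
  expect_equal(mean_field_solution(m, tt, init_fraction = 0),
               analytic_trace(r, initial_state(0, 1), tt), tolerance = 1e-12)

  vloss <- build_vinculin_loss(talin_rates(), 0.0052)
  mf <- mean_field_solution(vloss, tt, init_fraction = 1)
  # independent fine-step integration of dn/dt = entry(1-n) - (exit+loss)n
  num <- oracle_rk4(entry = vloss$entry, exit = vloss$exit + vloss$partner_loss,
                    n0 = 1, times = tt)
  expect_lt(max(abs(mf - num)), 1e-8)
  expect_equal(mean_field_solution(vloss, 1e6), vloss$steady_state,
               tolerance = 1e-12)
})

test_that("ensemble means track the mean-field oracle within Monte Carlo error", {
  m <- build_three_protein(talin_rates(), 0.002, 0.003, n_tot = 500)
  ens <- ensemble(m, n_runs = 400, t_max = 300, grid_dt = 50,
                  init_fraction = 1, seed = 17)
  mf <- mean_field_solution(m, ens$times, init_fraction = 1)
  dev <- abs(ens$mean - mf)
  ok <- dev <= 3 * pmax(ens$stderr, 1e-12)
  expect_gte(mean(ok), 0.99)
})
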