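test_that("noiseless exponential data are recovered exactly across the rate range", {
  cases <- expand.grid(R0 = -c(0.005, 0.0113, 0.03, 0.09),
                       y0 = c(0.45, 0.56, 0.8))
  for (i in seq_len(nrow(cases))) {
    y0 <- cases$y0[i]; R0 <- cases$R0[i]; A <- -y0
    tr <- make_noiseless_trace(y0, A, R0)
    fit <- fit_exponential(tr)
    expect_lt(abs(fit$y0 - y0), 1e-6)
    expect_lt(abs(fit$A - A), 1e-6)
    expect_lt(abs(fit$R0 - R0), 1e-6)
    expect_lt(fit$residual_sse, 1e-12)
    expect_true(fit$converged)
  }
})

test_that("noisy fit agrees with a brute-force grid-search minimizer of the same SSE", {
  t <- seq(0, 300, 10)
  truth <- list(y0 = 0.56, A = -0.56, R0 = -0.0257)
  set.seed(42)
  y <- truth$y0 + truth$A * exp(truth$R0 * t) + rnorm(length(t), 0, 0.02)
  fit <- fit_exponential(intensity_trace(t, y, "FRAP"))
  brute <- oracle_grid_expfit(t, y)
  # the optimizer must match or beat the refined grid search
  expect_lte(fit$residual_sse, brute$sse * (1 + 1e-6))
  expect_lt(abs(fit$R0 - brute$R0) / abs(brute$R0), 1e-3)
  expect_lt(abs(fit$y0 - brute$y0), 1e-3)
  # and land within 3 standard errors of the generating rate
  expect_lt(abs(fit$R0 - truth$R0), 3 * fit$se[["R0"]])
})

test_that("constant traces are rejected as unidentifiable", {
  expect_error(
    fit_exponential(intensity_trace(c(0, 10, 20, 30), rep(0.5, 4), "FRAP")),
    "constant")
})

test_that("amplitude sign contradicting the modality is flagged, not fatal", {
  tr <- make_noiseless_trace(0.5, 0.4, -0.02, modality = "FRAP")  # loss shape
  expect_warning(fit <- fit_exponential(tr), "sign")
  expect_false(fit$sign_ok)
})

test_that("turnover rate is the magnitude of the exponential rate", {
  expect_equal(turnover_rate(make_fit_stub(-0.015)), 0.015)
  expect_equal(turnover_rate(make_fit_stub(-0.0113)), 0.0113)
  expect_error(turnover_rate(make_fit_stub(0)), "zero")
})

test_that("turnover estimate on seeded noisy data is within 10% of truth", {
  k_t <- 0.0257
  set.seed(7)
  t <- seq(0, 300, 10)
  y <- 0.6 - 0.6 * exp(-k_t * t) + rnorm(length(t), 0, 0.02)
  fit <- fit_exponential(intensity_trace(t, y, "FRAP"))
  expect_lt(abs(turnover_rate(fit) - k_t) / k_t, 0.10)
})

test_that("turnover is invariant under intensity rescaling", {
  tr <- make_noiseless_trace(0.56, -0.56, -0.0113)
  k1 <- turnover_rate(fit_exponential(tr))
  for (c in c(0.2, 3, 40)) {
    scaled <- intensity_trace(tr$times, tr$intensities * c, "FRAP")
    expect_equal(turnover_rate(fit_exponential(scaled)), k1, tolerance = 1e-8)
  }
})

test_that("stationary concentration reads the plateau per modality", {
  t <- seq(0, 90, 10)
  frap <- intensity_trace(t, c(seq(0, 0.52, length.out = 9), 0.562), "FRAP")
  expect_equal(stationary_concentration(frap), 0.562)

  flap <- intensity_trace(t, c(seq(1, 0.5, length.out = 9), 0.44), "FLAP")
  expect_equal(stationary_concentration(flap), 0.56)  # complement of 0.44

  m3 <- intensity_trace(seq(0, 50, 10), c(0, 0.3, 0.5, 0.70, 0.72, 0.71), "FRAP")
  expect_equal(stationary_concentration(m3, m = 3), 0.71)

  expect_error(stationary_concentration(frap, m = 0), "between")
  expect_error(stationary_concentration(frap, m = 99), "between")
  off <- intensity_trace(t, c(rep(1, 9), 1.5), "FRAP")
  expect_error(stationary_concentration(off), "tolerance")
})

test_that("IQR fences keep equal-rate samples and flag gross outliers", {
  equal <- lapply(rep(-0.01, 6), make_fit_stub)
  res <- remove_outliers(equal)
  expect_length(res$kept, 6L)
  expect_length(res$removed, 0L)
  expect_equal(res$bounds$iqr, 0)

  fits <- lapply(c(rep(-0.010, 8), -0.20), make_fit_stub)
  res2 <- remove_outliers(fits)
  expect_equal(res2$removed, 9L)
  expect_length(res2$kept, 8L)

  # spread sample: Tukey fences from type-7 quartiles keep all four
  spread <- lapply(c(-0.008, -0.009, -0.010, -0.011), make_fit_stub)
  res3 <- remove_outliers(spread)
  expect_length(res3$removed, 0L)
  expect_equal(res3$bounds$lcl, -0.0125)
  expect_equal(res3$bounds$ucl, -0.0065)

  expect_error(remove_outliers(lapply(c(-1, -2, -3), make_fit_stub)),
               "at least 4")
})

test_that("outlier removal is invariant to input ordering", {
  r0s <- c(-0.009, -0.011, -0.05, -0.010, -0.0095, -0.0102)
  res_a <- remove_outliers(lapply(r0s, make_fit_stub))
  res_b <- remove_outliers(lapply(rev(r0s), make_fit_stub))
  kept_a <- sort(vapply(res_a$kept, `[[`, numeric(1), "R0"))
  kept_b <- sort(vapply(res_b$kept, `[[`, numeric(1), "R0"))
  expect_equal(kept_a, kept_b)
  expect_equal(res_a$bounds$lcl, res_b$bounds$lcl)
})

test_that("average_trace is the pointwise mean on a shared grid", {
  t <- c(0, 10, 20, 30)
  a <- intensity_trace(t, c(0, 1, 0, 1), "FRAP")
  b <- intensity_trace(t, c(1, 0, 1, 0), "FRAP")
  avg <- average_trace(trace_set(list(a, b)))
  expect_equal(avg$intensities, rep(0.5, 4))
  expect_equal(average_trace(trace_set(list(a, a)))$intensities, a$intensities)

  # truncation to a common prefix is allowed, incompatible grids are not
  longer <- intensity_trace(c(0, 10, 20, 30, 40), c(0, 1, 0, 1, 1), "FRAP")
  avg2 <- average_trace(trace_set(list(a, longer)))
  expect_equal(avg2$times, t)
  shifted <- intensity_trace(c(0, 12, 20, 30), c(0, 1, 0, 1), "FRAP")
  expect_error(average_trace(trace_set(list(a, shifted))), "incompatible")
})
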