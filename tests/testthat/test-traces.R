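test_that("trace and set constructors enforce their invariants", {
  tr <- intensity_trace(seq(0, 30, 10), c(0, 0.2, 0.3, 0.35), "frap", "r1")
  expect_s3_class(tr, "intensity_trace")
  expect_equal(tr$modality, "FRAP")
  expect_length(tr, 4L)

  expect_error(intensity_trace(c(0, 10, 5, 20), 1:4), "increasing")
  expect_error(intensity_trace(0:2, c(0, 1, 2)), "4 points")
  expect_error(intensity_trace(0:3, c(0, NA, 1, 2)), "missing")

  tr2 <- intensity_trace(seq(0, 30, 10), c(1, 0.8, 0.7, 0.6), "FLAP")
  expect_error(trace_set(list(tr, tr2)), "modality")
  expect_error(trace_set(list()), "nonempty")
  ts <- trace_set(list(tr, tr), protein = "demo")
  expect_length(ts, 2L)
  expect_length(ts[1L], 1L)
})

test_that("read_traces parses delimited tables with and without headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,rep_a,rep_b",
               "0,0.00,0.01", "10,0.20,0.18", "20,0.31,0.30", "30,0.38,0.40"),
             path)
  ts <- read_traces(path, "FRAP")
  expect_length(ts, 2L)
  expect_equal(ts$traces[[1L]]$label, "rep_a")
  expect_equal(ts$traces[[2L]]$intensities, c(0.01, 0.18, 0.30, 0.40))

  # headerless, tab-separated
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t0.0", "10\t0.2", "20\t0.3", "30\t0.4"), path2)
  ts2 <- read_traces(path2, "FRAP")
  expect_length(ts2, 1L)
  expect_equal(ts2$traces[[1L]]$times, c(0, 10, 20, 30))

  # comma decimal mark with semicolon separator
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0;0,0", "10;0,2", "20;0,3", "30;0,4"), path3)
  ts3 <- read_traces(path3, "FRAP", dec = ",")
  expect_equal(ts3$traces[[1L]]$intensities, c(0, 0.2, 0.3, 0.4))
})

test_that("missing cells are dropped pairwise per replicate only", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,a,b",
               "0,0.00,0.01", "10,NaN,0.18", "20,0.31,0.30",
               "30,0.38,0.40", "40,0.41,0.42"),
             path)
  ts <- read_traces(path, "FRAP")
  expect_equal(ts$traces[[1L]]$times, c(0, 20, 30, 40))
  expect_equal(ts$traces[[2L]]$times, c(0, 10, 20, 30, 40))
})

test_that("read_traces rejects non-monotone time, short replicates, empty files", {
  bad <- withr::local_tempfile()
  writeLines(c("0,1", "10,2", "5,3", "20,4"), bad)
  expect_error(read_traces(bad, "FRAP"), "monotone|increasing")

  short <- withr::local_tempfile()
  writeLines(c("time,a", "0,1", "10,NA", "20,NA", "30,2"), short)
  expect_error(read_traces(short, "FRAP"), "fewer than 4")

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_error(read_traces(empty, "FRAP"), "empty")

  expect_error(read_traces("/no/such/file.csv", "FRAP"), "not found")
})

test_that("read -> write -> read round-trips times and intensities", {
  spec <- generator_spec(0.005, 0.007, "FRAP", n_traces = 3, seed = 11)
  ts <- generate_traces(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(ts, path)
  back <- read_traces(path, "FRAP")
  for (j in 1:3) {
    expect_equal(back$traces[[j]]$times, ts$traces[[j]]$times,
                 tolerance = 1e-9)
    expect_equal(back$traces[[j]]$intensities, ts$traces[[j]]$intensities,
                 tolerance = 1e-9)
  }
})

test_that("normalize_trace divides by the reference and is identity at 1", {
  tr <- intensity_trace(c(0, 10, 20, 30), c(2, 4, 6, 8), "FRAP")
  nt <- normalize_trace(tr, 4)
  expect_equal(nt$intensities, c(0.5, 1, 1.5, 2))
  expect_equal(nt$times, tr$times)
  expect_equal(nt$modality, tr$modality)
  expect_equal(normalize_trace(tr, 1)$intensities, tr$intensities)
  expect_error(normalize_trace(tr, 0), "positive")
  expect_error(normalize_trace(tr, -2), "positive")
  # pre-bleach points define the default reference
  pre <- intensity_trace(c(-20, -10, 0, 10, 20), c(4, 4, 0, 2, 3), "FRAP")
  expect_equal(normalize_trace(pre)$intensities, c(1, 1, 0, 0.5, 0.75))
})

test_that("rates tables round-trip through write/read at high precision", {
  r1 <- dynamic_rates(0.0112932457, 0.5621118, sigma_k_t = 3.2e-4,
                      sigma_n_in_bar = 0.013, protein = "tensin1")
  r2 <- dynamic_rates(0.083, 0.649, sigma_k_t = 6e-3,
                      sigma_n_in_bar = 0.024, protein = "FAK")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rates_table(list(r1, r2), path)

  tab <- read.table(path, sep = "\t", header = TRUE)
  expect_equal(ncol(tab), 9L)
  expect_equal(nrow(tab), 2L)

  back <- read_rates_table(path)
  for (fld in c("k_t", "k_in", "k_out", "n_in_bar", "sigma_k_t",
                "sigma_k_in", "sigma_k_out", "sigma_n_in_bar"))
    expect_equal(back[[1L]][[fld]], r1[[fld]], tolerance = 1e-12)
  expect_equal(back[[2L]]$protein, "FAK")

  expect_error(write_rates_table(list(), path), "nonempty")
})
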