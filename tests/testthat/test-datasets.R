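test_that("msle is symmetric when uncensored and applies the capped censoring penalty", {
  a <- c(1, 2, 5, 10, 20, 50, 100, 200, 500)
  b <- a * exp(0.1)
  expect_equal(msle(a, b), msle(b, a))
  expect_equal(msle(a, b), 0.01)
  # model-censored level against an observed one: capped penalty
  a_cens <- a
  a_cens[9] <- NA
  expect_equal(msle(a_cens, b, t_max = 1e6),
               (sum(0.01 * 8) + log(1e6 / b[9])^2) / 9)
  # levels missing in the observation are excluded
  b_miss <- b
  b_miss[1] <- NA
  expect_equal(msle(a, b_miss), 0.01)
  expect_error(msle(a, rep(NA_real_, 9)), "no comparable")
})

test_that("observed progress times invert a noise-free synthetic dataset", {
  cc <- conditions(5e-5, 1e14)
  cv <- simulate_decay(default_truth(), cc)
  keep <- cv$time_s > 0 & cv$fraction_remaining > 0.02
  ds <- decay_dataset("unit", cc, cv$time_s[keep], cv$fraction_remaining[keep])
  obs <- observed_progress_times(ds)
  truth <- km_progress(default_truth(), cc)
  expect_lt(msle(truth, obs), 1e-3)
})

test_that("decay datasets round-trip through CSV + JSON sidecar", {
  cc <- conditions(3e-5, 2e13)
  ds <- decay_dataset("rt01", cc, c(1, 10, 100, 1000),
                      c(0.9, 0.6, 0.3, 0.1), note = "round trip")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_decay_dataset(ds, path)
  back <- read_decay_dataset(path)
  expect_equal(back$dataset_id, "rt01")
  expect_equal(back$conditions, ds$conditions)
  expect_equal(back$observations$time_s, ds$observations$time_s)
  expect_equal(back$observations$fraction_remaining,
               ds$observations$fraction_remaining)
})
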