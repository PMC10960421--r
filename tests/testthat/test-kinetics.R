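test_that("simulated decay curves are normalized, monotone non-increasing, and deterministic", {
  cc <- conditions(5e-5, 1e14)
  cv <- simulate_decay(default_truth(), cc)
  expect_s3_class(cv, "decay_curve")
  expect_equal(cv$time_s[1], 0)
  expect_equal(cv$fraction_remaining[1], 1)
  expect_true(all(diff(cv$fraction_remaining) <= 1e-9))
  expect_true(all(cv$fraction_remaining >= 0 & cv$fraction_remaining <= 1))
  cv2 <- simulate_decay(default_truth(), cc)
  expect_identical(cv, cv2)
})

test_that("progress times interpolate the nine levels and censor unreached ones", {
  # synthetic exponential curve with known crossing times
  k <- 1e-3
  tt <- c(0, exp(seq(log(1e-2), log(1e6), length.out = 400)))
  cv <- tibble::tibble(time_s = tt, fraction_remaining = exp(-k * tt))
  pt <- progress_times(cv)
  expect_named(pt, paste0("t", format(progress_fractions())))
  expect_equal(unname(pt), -log(progress_fractions()) / k, tolerance = 1e-3)
  # truncate before the 0.1 level is reached -> censored tail
  short <- cv[cv$time_s <= 500, ]
  pt_s <- progress_times(short)
  expect_true(is.na(pt_s[["t0.1"]]))
  expect_false(is.na(pt_s[["t0.9"]]))
})

test_that("km_progress responds physically to conditions", {
  p <- default_truth()
  t_small <- km_progress(p, conditions(2e-5, 1e14))
  t_large <- km_progress(p, conditions(2e-4, 1e14))
  # larger particles expose relatively less surface: slower conversion
  expect_gt(t_large[["t0.5"]], t_small[["t0.5"]])
  t_lowo3 <- km_progress(p, conditions(5e-5, 1e13))
  t_higho3 <- km_progress(p, conditions(5e-5, 1e15))
  expect_gt(t_lowo3[["t0.5"]], t_higho3[["t0.5"]])
})

test_that("surface ozone never exceeds a monolayer and profiles have the right shape", {
  cc <- conditions(5e-5, 1e14)
  prof <- simulate_profiles(default_truth(), cc)
  cfg <- model_config()
  expect_equal(dim(prof$O3_bulk), c(length(prof$time_s), cfg$n_layers))
  # Langmuir coverage bound: sites per cm2 = 1 / sigma_O3
  expect_lt(max(prof$O3_surf), 1 / cfg$sigma_O3 * (1 + 1e-9))
  expect_true(all(prof$OL_bulk >= -1e-6 * cc[["OL_b0"]]))
})
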