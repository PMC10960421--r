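test_that("the trained surrogate meets the accuracy target on held-out points", {
  sm <- fx_surrogate()
  expect_s3_class(sm, "surrogate_model")
  expect_lt(sm$median_abs_log10_error, 0.1)
  expect_gt(min(sm$metrics$r2), 0.5)
  expect_gt(sm$val_msle, 0)
  g <- glance(sm)
  expect_true(all(c("median_abs_log10_error", "val_msle") %in% names(g)))
})

test_that("surrogate predictions are deterministic, positive, and monotone across levels", {
  sm <- fx_surrogate()
  P <- cbind(toy_params(50, seed = 81),
             r_p = 10^runif(50, log10(2.5e-6), log10(1e-3)),
             O3_g0 = 10^runif(50, 11, 15),
             OL_b0 = rep(1.9e21, 50))
  y1 <- sm_predict(sm, P)
  y2 <- sm_predict(sm, P)
  expect_identical(y1, y2)
  expect_true(all(y1 > 0))
  # progress times must not decrease from the 0.9 to the 0.1 level
  expect_true(all(apply(y1, 1, function(r) all(diff(r) >= 0))))
})

test_that("the surrogate evaluator's batch path matches its scalar path", {
  sm <- fx_surrogate()
  ev <- sm_evaluator(sm)
  cc <- conditions(5e-5, 1e14)
  P <- toy_params(5, seed = 82)
  batch <- attr(ev, "batch")(P, cc)
  single <- t(apply(P, 1, function(p) ev(p, cc)))
  expect_equal(unname(batch), unname(single), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("surrogates round-trip through JSON with identical predictions", {
  sm <- fx_surrogate()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_surrogate(sm, path)
  back <- read_surrogate(path)
  P <- cbind(toy_params(20, seed = 83),
             r_p = rep(5e-5, 20), O3_g0 = rep(1e14, 20),
             OL_b0 = rep(1.9e21, 20))
  expect_equal(sm_predict(back, P), sm_predict(sm, P), tolerance = 1e-12)
})

test_that("training-set generation excludes fully censored draws and records retention", {
  ts <- generate_training_data(n = 200, seed = 84)
  expect_s3_class(ts, "surrogate_training_set")
  expect_equal(nrow(ts$inputs), nrow(ts$targets))
  expect_true(all(is.finite(ts$targets)))
  expect_lte(nrow(ts$inputs), 200)
  expect_gt(ts$retention, 0)
  expect_lte(ts$retention, 1)
})
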