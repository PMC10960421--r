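test_that("benchmark generation is reproducible and noise-free data sit on the truth curve", {
  b1 <- generate_benchmark(benchmark_spec(seed = 5))
  b2 <- generate_benchmark(benchmark_spec(seed = 5))
  expect_equal(length(b1$datasets), 7)
  expect_identical(b1$datasets[[3]]$observations, b2$datasets[[3]]$observations)
  b3 <- generate_benchmark(benchmark_spec(seed = 6))
  expect_false(identical(b1$datasets[[3]]$observations,
                         b3$datasets[[3]]$observations))
  # with the noise switched off, observations equal the model curve exactly
  b0 <- generate_benchmark(benchmark_spec(noise_sigma = 0, seed = 5,
                                          conds = default_conditions()[2]))
  ds <- b0$datasets[[1]]
  cv <- simulate_decay(b0$truth, ds$conditions)
  f_model <- approx(cv$time_s, cv$fraction_remaining,
                    xout = ds$observations$time_s)$y
  expect_equal(ds$observations$fraction_remaining, f_model,
               tolerance = 1e-10)
})

test_that("benchmarks write a complete dataset directory with a truth manifest", {
  b <- generate_benchmark(benchmark_spec(seed = 7,
                                         conds = default_conditions()[1:2]))
  dir <- tempfile("bench")
  on.exit(unlink(dir, recursive = TRUE))
  write_benchmark(b, dir)
  expect_setequal(list.files(dir),
                  c("bench01.csv", "bench01.csv.json",
                    "bench02.csv", "bench02.csv.json", "truth.json"))
  manifest <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(manifest$truth$k_BR, unname(b$truth["k_BR"]))
  expect_equal(manifest$seed, 7)
  back <- read_decay_dataset(file.path(dir, "bench01.csv"))
  expect_equal(back$observations, b$datasets[[1]]$observations,
               tolerance = 1e-12)
})

test_that("threshold calibration respects the floor and adds the evaluator error", {
  bench <- fx_bench()
  th0 <- calibrate_theta(bench)
  expect_gte(as.numeric(th0), 0.0105)
  expect_gt(attr(th0, "noise_msle"), 0)
  th1 <- calibrate_theta(bench, evaluator_msle = 0.02)
  expect_equal(as.numeric(th1), as.numeric(th0) + 2 * 0.02,
               tolerance = 1e-12)
  # huge floor dominates
  th2 <- calibrate_theta(bench, floor = 10)
  expect_equal(as.numeric(th2), 10)
})
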