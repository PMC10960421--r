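test_that("default bounds cover the ten sampled parameters with finite positive ranges", {
  b <- default_bounds()
  expect_setequal(b$parameter, c(kinetic_parameter_names(),
                                 experimental_parameter_names()))
  expect_true(all(b$lower > 0))
  expect_true(all(b$lower < b$upper))
  expect_setequal(unique(b$kind), c("kinetic", "experimental"))
})

test_that("parameter constructors validate their inputs", {
  expect_error(conditions(-1e-5, 1e14))
  expect_error(kinetic_params(k_SLR = -1, k_BR = 1e-15, D_b_O3 = 1e-7,
                              D_b_OL = 1e-9, H_cp_O3 = 1e-4,
                              tau_d_O3 = 1e-6, alpha_s0_O3 = 1e-2))
  cc <- conditions(5e-5, 1e14)
  expect_named(cc, c("r_p", "O3_g0", "OL_b0"), ignore.order = TRUE)
})

test_that("sample_params draws log-uniformly inside the bounds and is seed-reproducible", {
  set.seed(9)
  s1 <- sample_params(500, kind = "all")
  set.seed(9)
  s2 <- sample_params(500, kind = "all")
  expect_identical(s1, s2)
  b <- default_bounds()
  for (p in b$parameter) {
    lo <- b$lower[b$parameter == p]
    hi <- b$upper[b$parameter == p]
    expect_true(all(s1[[p]] >= lo & s1[[p]] <= hi))
    # log-uniform: median of log10 near the log-midpoint
    expect_lt(abs(median(log10(s1[[p]])) - (log10(lo) + log10(hi)) / 2),
              0.25 * (log10(hi) - log10(lo)))
  }
})
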