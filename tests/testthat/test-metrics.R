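test_that("ensemble spread is zero for identical members and grows with scatter", {
  M <- toy_outputs(1, seed = 1)[rep(1, 6), ]
  expect_equal(ensemble_spread(make_toy_ens(M)), 0)
  small <- toy_outputs(12, seed = 2)
  big <- small * exp(matrix(rnorm(length(small), 0, 1), nrow(small)))
  big <- t(apply(big, 1, sort))
  expect_gt(ensemble_spread(make_toy_ens(big)),
            ensemble_spread(make_toy_ens(small)))
})

test_that("constraint potentials behave at threshold extremes", {
  n <- 8
  M <- toy_outputs(n, seed = 3)
  P <- toy_params(n, seed = 4)
  fe <- make_toy_fe(P)
  ens <- make_toy_ens(M)
  # infinite threshold: every subset is the full ensemble
  pcp_inf <- parameter_constraint_potential(ens, fe, "k_SLR", theta = 1e12)
  lam <- log10(P[, "k_SLR"])
  q <- quantile(lam, c(0.05, 0.95), names = FALSE)
  expect_equal(as.numeric(pcp_inf),
               n * ((q[1] - min(lam)) + (max(lam) - q[2])), tolerance = 1e-12)
  tcp_inf <- target_constraint_potential(ens, make_toy_ens(
    toy_outputs(n, seed = 5)), theta = 1e12)
  expect_equal(tcp_inf, 0, tolerance = 1e-12)
  # fully censored members are skipped as hypothetical outcomes
  M_c <- M
  M_c[2, ] <- NA
  pcp_c <- parameter_constraint_potential(make_toy_ens(M_c), fe, "k_SLR",
                                          theta = 1e12)
  expect_equal(attr(pcp_c, "n_used"), n - 1)
})

test_that("condition grids are row-major with cells ordered radius-major", {
  g <- condition_grid(3, 4)
  expect_equal(nrow(g), 12)
  expect_equal(g$cell, 1:12)
  expect_equal(g$r_p[1:4], rep(g$r_p[1], 4))       # first row: fixed radius
  expect_equal(length(unique(g$O3_g0[1:4])), 4)
  expect_true(all(diff(unique(g$r_p)) > 0))
})

test_that("constraint maps mask infeasible cells and tie-break the argmax to the first cell", {
  n <- 10
  P <- toy_params(n, seed = 6)
  fe <- make_toy_fe(P)
  g <- condition_grid(2, 2, r_range = c(2e-5, 1e-4), o3_range = c(1e13, 1e15))
  # constant-value metric with controlled durations per cell
  ev <- analytic_evaluator()
  m <- constraint_map(fe, g, metric = function(ens) 1, evaluator = ev,
                      theta = 0.05)
  expect_s3_class(m, "constraint_map")
  expect_equal(nrow(m), 4)
  feas <- which(m$feasible)
  expect_gt(length(feas), 0)
  # all values tie at 1 -> argmax is the first feasible cell in grid order
  expect_equal(attr(m, "argmax"), feas[1])
  sug <- suggest_experiment(m)
  expect_equal(attr(sug, "cell"), m$cell[feas[1]])
  expect_equal(sug[["r_p"]], m$r_p[feas[1]])
})

test_that("constraint maps round-trip through CSV + JSON sidecar", {
  n <- 10
  P <- toy_params(n, seed = 7)
  fe <- make_toy_fe(P)
  g <- condition_grid(2, 3, r_range = c(2e-5, 1e-4), o3_range = c(1e13, 1e15))
  m <- constraint_map(fe, g, metric = "es", evaluator = analytic_evaluator(),
                      theta = 0.05)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_constraint_map(m, path)
  d <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(d$value, m$value)
  expect_equal(d$feasible, m$feasible)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$metric, "es")
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})

test_that("cached solution grids reproduce per-cell ensemble solutions", {
  n <- 6
  P <- toy_params(n, seed = 8)
  fe <- make_toy_fe(P)
  g <- condition_grid(2, 2, r_range = c(2e-5, 1e-4), o3_range = c(1e13, 1e15))
  ev <- analytic_evaluator()
  sg <- solution_grid(fe, g, evaluator = ev, fit_ids = fe$fits$fit_id)
  for (ci in seq_len(nrow(g))) {
    direct <- ensemble_solution(fe, c(r_p = g$r_p[ci], O3_g0 = g$O3_g0[ci],
                                      OL_b0 = g$OL_b0[ci]),
                                evaluator = ev, fit_ids = fe$fits$fit_id)
    expect_equal(unname(sg$outputs[, , ci]), unname(direct$outputs),
                 tolerance = 1e-12)
  }
})
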