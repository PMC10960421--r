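# design-loop mechanics exercised with the fast analytic evaluator through
# precomputed solution grids, so no kinetic-model solves are needed

toy_study_setup <- function(n_fits = 12, n_r = 3, n_o3 = 3, seed = 61) {
  P <- toy_params(n_fits, seed)
  # confine k_BR to the band where every grid cell stays inside the
  # feasibility window for any subset of fits (see analytic_evaluator)
  P[, "k_BR"] <- 10^runif(n_fits, log10(2.5e-17), log10(1.2e-16))
  fe <- make_toy_fe(P, theta = 0.05)
  g <- condition_grid(n_r, n_o3, r_range = c(2e-5, 1e-4),
                      o3_range = c(1e13, 1e15))
  sg <- solution_grid(fe, g, evaluator = analytic_evaluator(),
                      fit_ids = fe$fits$fit_id)
  list(fe = fe, grid = g, sg = sg)
}

test_that("on a one-cell grid every selector chooses the same condition", {
  s <- toy_study_setup(n_fits = 8, n_r = 1, n_o3 = 1)
  res <- lapply(c("nc_es_km", "random"), function(sel) {
    cfg <- simulation_config(grid = s$grid, selector = sel, theta = 0.05,
                             n_iterations = 1, seed = 3)
    run_simulation_study(s$fe, cfg, solution_grids = list(km = s$sg))
  })
  expect_equal(res[[1]]$trajectories$cell, res[[2]]$trajectories$cell)
  expect_equal(unique(res[[1]]$trajectories$cell), 1)
})

test_that("trajectory bookkeeping is consistent and repeats are avoided", {
  s <- toy_study_setup()
  cfg <- simulation_config(grid = s$grid, selector = "nc_es_km",
                           theta = 0.05, n_iterations = 3, seed = 4)
  st <- run_simulation_study(s$fe, cfg, solution_grids = list(km = s$sg))
  tr <- st$trajectories
  n <- nrow(s$fe$fits)
  expect_true(all(tr$remaining == tr$n_accepted))
  expect_true(all(tr$n_accepted + tr$n_rejected <= n))
  expect_true(all(tr$remaining >= 1))          # the truth always survives
  # within one truth, no condition is measured twice while others remain
  by_truth <- split(tr$cell, tr$truth_id)
  expect_true(all(vapply(by_truth, function(x) !anyDuplicated(x), TRUE)))
  # fixed seed -> fully reproducible
  st2 <- run_simulation_study(s$fe, cfg, solution_grids = list(km = s$sg))
  expect_identical(tr, st2$trajectories)
  g <- glance(st)
  expect_equal(nrow(g), 3)
  expect_true(all(g$median_remaining >= 1))
})

test_that("a single compass iteration filters the ensemble and returns the chosen condition", {
  s <- toy_study_setup()
  cfg <- simulation_config(grid = s$grid, selector = "nc_es_km",
                           theta = 0.05, n_iterations = 1, seed = 5,
                           cfg = model_config())
  truth <- unlist(s$fe$fits[3, kinetic_parameter_names()])
  # run through the engine with the analytic grid (no model solves)
  out <- kincompass:::run_study_engine(
    s$fe, cfg, sg_filter = s$sg, sg_map = s$sg, truths = list(truth),
    n_iterations = 1, return_fe = TRUE, truth_rows = list(3L))
  expect_named(out$counts, c("accepted", "rejected", "revived"))
  expect_s3_class(out$fe, "fit_ensemble")
  expect_equal(sum(out$fe$fits$accepted), unname(out$counts["accepted"]))
  expect_true(out$fe$fits$accepted[3])         # the truth survives
  expect_true(out$cell %in% s$grid$cell)
})

test_that("sensitivity maps vanish for parameters the response ignores", {
  # analytic response depends only on k_BR: all other partials are zero,
  # so halving the step leaves the total unchanged (linear in log-log)
  g <- condition_grid(2, 2, r_range = c(2e-5, 1e-4),
                      o3_range = c(1e13, 1e15))
  p <- default_truth()
  m1 <- sensitivity_map(p, g, evaluator = analytic_evaluator(),
                        fd_step = 0.05)
  m2 <- sensitivity_map(p, g, evaluator = analytic_evaluator(),
                        fd_step = 0.1)
  expect_equal(m1$value, m2$value, tolerance = 1e-8)
  # d log10(t) / d log10(k_BR) = -1 and all other derivatives are zero
  expect_equal(m1$value, rep(1, 4), tolerance = 1e-8)
})

test_that("simulated truth experiments reproduce the truth's progress times", {
  ev <- analytic_evaluator()
  truth <- default_truth()
  cc <- conditions(5e-5, 1e14)
  ds <- simulate_truth_experiment(truth, cc, evaluator = ev)
  obs <- observed_progress_times(ds)
  expect_equal(unname(obs), unname(ev(truth, cc)), tolerance = 1e-6)
  # with noise, expected error matches the noise scale
  set.seed(8)
  ds_n <- simulate_truth_experiment(truth, cc, evaluator = ev,
                                    noise_sigma = 0.2)
  expect_gt(msle(ev(truth, cc), observed_progress_times(ds_n)), 0)
})
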