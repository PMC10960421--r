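# acquisition, filtering, and IO exercised with a fast analytic evaluator
# so no kinetic-model solves are needed

analytic_dataset <- function(truth, cc, id = "an01") {
  ev <- analytic_evaluator()
  pt <- ev(truth, cc)
  decay_dataset(id, cc, pt, progress_fractions())
}

test_that("rejection sampling accepts only fits within the threshold and is reproducible", {
  ev <- analytic_evaluator()
  truth <- default_truth()
  ds <- list(analytic_dataset(truth, conditions(5e-5, 1e14)))
  fe1 <- acquire_fit_ensemble(ds, theta = 0.5, n_target = 40,
                              max_draws = 1e5, evaluator = ev, seed = 21)
  fe2 <- acquire_fit_ensemble(ds, theta = 0.5, n_target = 40,
                              max_draws = 1e5, evaluator = ev, seed = 21)
  expect_identical(fe1$fits, fe2$fits)
  expect_true(all(fe1$fits$error < 0.5))
  expect_gte(sum(fe1$fits$accepted), 40)
  expect_lte(fe1$acceptance_rate, 1)
})

test_that("errors from the batched evaluator path match scalar re-scoring", {
  ev <- analytic_evaluator()
  ev_scalar <- function(p, cc) ev(p, cc)     # strip the batch attribute
  truth <- default_truth()
  ds <- list(analytic_dataset(truth, conditions(5e-5, 1e14)),
             analytic_dataset(truth, conditions(1e-4, 1e13), "an02"))
  fe_b <- acquire_fit_ensemble(ds, theta = 0.5, n_target = 15,
                               max_draws = 2e4, evaluator = ev, seed = 5)
  ds_c <- kincompass:::cache_progress(ds)
  errs <- vapply(seq_len(nrow(fe_b$fits)), function(i) {
    p <- unlist(fe_b$fits[i, kinetic_parameter_names()])
    kincompass:::total_error(p, ds_c, evaluator = ev_scalar)
  }, numeric(1))
  expect_equal(errs, fe_b$fits$error, tolerance = 1e-12)
})

test_that("filtering is idempotent and re-scores every stored fit (revival possible)", {
  ev <- analytic_evaluator()
  truth <- default_truth()
  cc1 <- conditions(5e-5, 1e14)
  cc2 <- conditions(1e-4, 1e15)
  ds1 <- list(analytic_dataset(truth, cc1, "a"))
  fe <- acquire_fit_ensemble(ds1, theta = 0.5, n_target = 30,
                             max_draws = 1e5, evaluator = ev, seed = 31)
  f1 <- filter_ensemble(fe, ds1, evaluator = ev)
  f2 <- filter_ensemble(f1, ds1, evaluator = ev)
  expect_equal(f1$fits$accepted, f2$fits$accepted)
  counts <- attr(f1, "counts")
  expect_named(counts, c("accepted", "rejected", "revived"),
               ignore.order = TRUE)
  # adding a second dataset changes the joint error; counts stay consistent
  ds12 <- list(analytic_dataset(truth, cc1, "a"),
               analytic_dataset(truth, cc2, "b"))
  f3 <- filter_ensemble(f1, ds12, evaluator = ev)
  expect_equal(sum(f3$fits$accepted), unname(attr(f3, "counts")["accepted"]))
  expect_equal(nrow(f3$fits), nrow(fe$fits))
})

test_that("ensemble solutions carry outputs for exactly the accepted fits", {
  ev <- analytic_evaluator()
  truth <- default_truth()
  ds <- list(analytic_dataset(truth, conditions(5e-5, 1e14)))
  fe <- acquire_fit_ensemble(ds, theta = 0.5, n_target = 10,
                             max_draws = 1e5, evaluator = ev, seed = 41)
  ens <- ensemble_solution(fe, conditions(2e-5, 1e13), evaluator = ev)
  expect_equal(nrow(ens$outputs), sum(fe$fits$accepted))
  expect_equal(ncol(ens$outputs), 9)
  expect_true(all(ens$outputs > 0))
})

test_that("fit ensembles round-trip through TSV + JSON sidecar", {
  ev <- analytic_evaluator()
  ds <- list(analytic_dataset(default_truth(), conditions(5e-5, 1e14)))
  fe <- acquire_fit_ensemble(ds, theta = 0.5, n_target = 10,
                             max_draws = 1e5, evaluator = ev, seed = 51)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_fit_ensemble(fe, path)
  back <- read_fit_ensemble(path)
  expect_equal(back$theta, fe$theta)
  for (p in kinetic_parameter_names()) {
    expect_equal(back$fits[[p]], fe$fits[[p]], tolerance = 1e-12)
  }
  expect_equal(back$fits$accepted, fe$fits$accepted)
})
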