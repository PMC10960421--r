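# Shared fixtures, memoised for the whole test session. The expensive
# objects (trained surrogate, acquired ensemble, cached solution grids)
# are built once on first use and reused across test files.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# surrogate trained at the full training size; takes a few minutes once
fx_surrogate <- function() fx_get("sm", function() {
  ts <- generate_training_data(n = 5e4, seed = 71)
  train_surrogate(ts, seed = 72)
})

fx_bench <- function() fx_get("bench", function() {
  generate_benchmark(benchmark_spec(seed = 101))
})

fx_theta <- function() fx_get("theta", function() {
  as.numeric(calibrate_theta(fx_bench(),
                             evaluator_msle = fx_surrogate()$val_msle))
})

fx_ensemble <- function() fx_get("fe", function() {
  acquire_fit_ensemble(fx_bench()$datasets, theta = fx_theta(),
                       n_target = 100, max_draws = 2e6,
                       evaluator = sm_evaluator(fx_surrogate()), seed = 11)
})

fx_grid6 <- function() condition_grid(6, 6)

fx_sg_km <- function() fx_get("sg_km", function() {
  fe <- fx_ensemble()
  solution_grid(fe, fx_grid6(), fit_ids = fe$fits$fit_id)
})

fx_sg_sm <- function() fx_get("sg_sm", function() {
  fe <- fx_ensemble()
  solution_grid(fe, fx_grid6(), evaluator = sm_evaluator(fx_surrogate()),
                fit_ids = fe$fits$fit_id)
})

# ---- small toy builders -------------------------------------------------

# random positive nine-point output matrices (rows = ensemble members)
toy_outputs <- function(n, seed, censor = 0) {
  set.seed(seed)
  base <- sort(exp(runif(9, 0, 8)))
  M <- t(vapply(seq_len(n), function(i) {
    sort(base * exp(rnorm(9, 0, 0.4)))
  }, numeric(9)))
  if (censor > 0) M[sample.int(length(M), censor)] <- NA
  colnames(M) <- paste0("t", format(progress_fractions()))
  M
}

make_toy_ens <- function(outputs, fit_ids = seq_len(nrow(outputs))) {
  colnames(outputs) <- paste0("t", format(progress_fractions()))
  structure(list(condition = conditions(5e-5, 1e14), outputs = outputs,
                 fit_ids = fit_ids),
            class = "ensemble_solution")
}

# minimal fit ensemble around a matrix of kinetic parameters (linear scale)
make_toy_fe <- function(P, theta = 0.05) {
  kin <- kinetic_parameter_names()
  colnames(P) <- kin
  fits <- tibble::as_tibble(as.data.frame(P))
  fits$fit_id <- seq_len(nrow(fits))
  fits$accepted <- TRUE
  fits$error <- 0
  structure(list(fits = fits, theta = theta, bounds = default_bounds(),
                 seed = 1L, dataset_ids = character(0), n_draws = nrow(P),
                 acceptance_rate = 1),
            class = "fit_ensemble")
}

# random kinetic parameter matrix inside the default bounds
toy_params <- function(n, seed) {
  set.seed(seed)
  b <- default_bounds()
  b <- b[b$kind == "kinetic", ]
  P <- sapply(seq_len(nrow(b)), function(j) {
    10^runif(n, log10(b$lower[j]), log10(b$upper[j]))
  })
  colnames(P) <- b$parameter
  P
}

# analytic nine-point evaluator: pseudo-first-order decay with rate
# k_BR * O3_g0 * r_p (a closed form the model code never uses); the
# constant scales typical toy rates so times land on measurable scales
analytic_evaluator <- function() {
  fr <- progress_fractions()
  scale <- 7e3
  f <- function(p, cc) {
    -log(fr) / (p[["k_BR"]] * cc[["O3_g0"]] * cc[["r_p"]] * scale)
  }
  attr(f, "batch") <- function(P, cc) {
    k <- P[, "k_BR"] * cc[["O3_g0"]] * cc[["r_p"]] * scale
    outer(1 / k, -log(fr))
  }
  f
}

# ---- independent oracles ------------------------------------------------

# spread via explicit curve interpolation and piecewise-exact integration
oracle_es <- function(outputs) {
  z <- log10(outputs)
  z <- z[stats::complete.cases(z), , drop = FALSE]
  x <- rev(progress_fractions())
  z <- z[, ncol(z):1, drop = FALSE]
  zbar <- colMeans(z)
  sig <- apply(z, 2, function(v) sqrt(mean((v - mean(v))^2)))
  upper <- stats::approxfun(x, zbar + sig)
  lower <- stats::approxfun(x, zbar - sig)
  mid <- stats::approxfun(x, zbar)
  seg <- function(f) {
    sum(vapply(seq_len(length(x) - 1), function(i) {
      a <- x[i]; b <- x[i + 1]
      (b - a) * (f(a) + 4 * f((a + b) / 2) + f(b)) / 6  # exact for linear
    }, numeric(1)))
  }
  (seg(upper) - seg(lower)) / seg(mid)
}

# exhaustive double-loop subset formation: which members lie within theta
# of member l when l plays the hypothetical experimental outcome
oracle_subsets <- function(outputs, theta, t_max) {
  n <- nrow(outputs)
  subs <- list()
  for (l in seq_len(n)) {
    obs <- outputs[l, ]
    if (all(is.na(obs))) next
    idx <- integer(0)
    for (m in seq_len(n)) {
      d <- 0; cnt <- 0
      for (j in seq_along(obs)) {
        if (is.na(obs[j])) next
        mm <- if (is.na(outputs[m, j])) t_max else outputs[m, j]
        d <- d + (log(mm) - log(obs[j]))^2
        cnt <- cnt + 1
      }
      if (d / cnt < theta) idx <- c(idx, m)
    }
    subs[[length(subs) + 1]] <- idx
  }
  subs
}

oracle_pcp <- function(outputs, lam, theta, t_max) {
  lo <- min(lam); hi <- max(lam)
  subs <- oracle_subsets(outputs, theta, t_max)
  sum(vapply(subs, function(idx) {
    q <- stats::quantile(lam[idx], c(0.05, 0.95), names = FALSE)
    (q[1] - lo) + (hi - q[2])
  }, numeric(1)))
}

oracle_tcp <- function(test_out, target_out, theta, t_max) {
  es_full <- oracle_es(target_out)
  subs <- oracle_subsets(test_out, theta, t_max)
  mean(vapply(subs, function(idx) {
    if (length(idx) == 1) return(es_full - 0)
    es_full - oracle_es(target_out[idx, , drop = FALSE])
  }, numeric(1)))
}
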