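#' Simulate a truth experiment
#'
#' Evaluates the model for a chosen "simulated truth" parameter set at one
#' condition and re-expresses the nine-point output as a decay dataset
#' (time, fraction) — the synthetic analogue of running the suggested
#' laboratory experiment. Optional multiplicative log-normal noise on the
#' times: `t -> t * exp(e)`, `e ~ N(0, sigma)` i.i.d. per progress level,
#' so the expected MSLE between the noisy dataset and the noise-free truth
#' output is `sigma^2`.
#'
#' @param truth named kinetic parameter vector
#' @param cond condition vector from [conditions()]
#' @param cfg model configuration
#' @param evaluator optional nine-point evaluator (default kinetic model)
#' @param noise_sigma log-normal noise scale (0 = noise off)
#' @param dataset_id id for the emitted dataset
#' @return A [decay_dataset()]. Censored progress levels are dropped from
#'   the observations.
#' @export
simulate_truth_experiment <- function(truth, cond, cfg = model_config(),
                                      evaluator = NULL, noise_sigma = 0,
                                      dataset_id = "simulated") {
  if (is.null(evaluator)) {
    evaluator <- function(p, cc) km_progress(p, cc, cfg)
  }
  pt <- evaluator(truth, cond)
  fr <- progress_fractions()
  keep <- !is.na(pt)
  if (!any(keep)) stop("simulated experiment reaches no progress level")
  tt <- pt[keep]
  if (noise_sigma > 0) tt <- tt * exp(rnorm(length(tt), 0, noise_sigma))
  o <- order(tt)
  decay_dataset(dataset_id, cond, tt[o], fr[keep][o],
                note = sprintf("simulated truth experiment, sigma = %g",
                               noise_sigma))
}

#' Simulation study configuration
#'
#' @param grid candidate-condition grid, see [condition_grid()] (default
#'   10 x 10)
#' @param n_iterations iterations of the suggest-measure-filter loop
#' @param selector one of `"nc_es_km"`, `"nc_es_hybrid"`, `"nc_es_sm"`,
#'   `"random"`, `"sensitivity"`
#' @param theta acceptance threshold for loop filtering
#' @param noise_sigma log-normal noise on simulated experiments (default 0,
#'   noise off)
#' @param seed base seed (random selector draws derive from it)
#' @param surrogate a [train_surrogate()] model; required by the hybrid,
#'   surrogate-only, and sensitivity selectors
#' @param constraints a [feasibility_constraints()]
#' @param fd_step central-difference step (log10 units) for the
#'   sensitivity selector
#' @param truth_ids restrict simulated truths to these fit ids (default:
#'   every accepted fit in turn)
#' @param cfg model configuration
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(grid = condition_grid(10, 10),
                              n_iterations = 3,
                              selector = c("nc_es_km", "nc_es_hybrid",
                                           "nc_es_sm", "random",
                                           "sensitivity"),
                              theta = 0.0105, noise_sigma = 0, seed = 1L,
                              surrogate = NULL,
                              constraints = feasibility_constraints(),
                              fd_step = 0.05, truth_ids = NULL,
                              cfg = model_config()) {
  selector <- match.arg(selector)
  stopifnot(n_iterations >= 1, theta > 0, noise_sigma >= 0)
  if (selector %in% c("nc_es_hybrid", "nc_es_sm", "sensitivity") &&
      is.null(surrogate)) {
    stop("selector '", selector, "' needs a surrogate model")
  }
  structure(list(grid = grid, n_iterations = as.integer(n_iterations),
                 selector = selector, theta = theta,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 surrogate = surrogate, constraints = constraints,
                 fd_step = fd_step, truth_ids = truth_ids, cfg = cfg),
            class = "simulation_config")
}

# feasibility + ES per cell from a cached outputs array restricted to rows
study_cell_stats <- function(O, rows, constraints, dq = 9) {
  n_cells <- dim(O)[3]
  es <- dur <- ons <- cens <- rep(NA_real_, n_cells)
  for (ci in seq_len(n_cells)) {
    M <- O[rows, , ci, drop = FALSE]
    dim(M) <- dim(M)[1:2]
    cens[ci] <- mean(!stats::complete.cases(M))
    dur[ci] <- median(M[, dq], na.rm = TRUE)
    ons[ci] <- median(M[, 1], na.rm = TRUE)
    es[ci] <- tryCatch(es_core(M, quiet = TRUE), error = function(e) NA_real_)
  }
  feasible <- !is.na(dur) & !is.na(ons) &
    ons >= constraints$duration_window[1] &
    dur <= constraints$duration_window[2] &
    cens <= constraints$max_censored_frac
  list(es = es, duration = dur, onset = ons, censored = cens,
       feasible = feasible)
}

# per-cell total sensitivity of the surrogate response at one parameter set
surrogate_sensitivity <- function(params, grid, sm, fd_step) {
  kin <- kinetic_parameter_names()
  lp <- log10(params[kin])
  # rows: center, then +/- step per parameter
  P <- matrix(rep(lp, 15), 15, 7, byrow = TRUE, dimnames = list(NULL, kin))
  for (j in 1:7) {
    P[2 * j, j] <- lp[j] + fd_step
    P[2 * j + 1, j] <- lp[j] - fd_step
  }
  P <- 10^P
  vapply(seq_len(nrow(grid)), function(ci) {
    cc <- c(r_p = grid$r_p[ci], O3_g0 = grid$O3_g0[ci],
            OL_b0 = grid$OL_b0[ci])
    Z <- log10(sm_predict(sm, P, cc))
    tot <- 0
    for (j in 1:7) {
      tot <- tot + mean(abs(Z[2 * j, ] - Z[2 * j + 1, ]) / (2 * fd_step))
    }
    tot
  }, numeric(1))
}

#' One iteration of the numerical-compass loop
#'
#' Builds the selector's map from the currently accepted fits, picks the
#' feasible arg-max condition, simulates the truth experiment there, and
#' re-filters the FULL stored ensemble against all accumulated datasets —
#' previously rejected fits can be revived.
#'
#' @param fe a `fit_ensemble` (all stored fits; flags mark acceptance)
#' @param study_cfg a [simulation_config()]
#' @param datasets_so_far list of datasets accumulated in earlier
#'   iterations (may be empty)
#' @param truth named kinetic parameter vector used as simulated truth
#' @return List: `condition`, `cell`, `fe` (re-filtered), `counts`
#'   (accepted/rejected/revived), `datasets` (input plus the new one).
#' @export
run_nc_iteration <- function(fe, study_cfg, datasets_so_far = list(),
                             truth) {
  sg <- solution_grid(fe, study_cfg$grid, study_cfg$cfg,
                      fit_ids = fe$fits$fit_id)
  st <- run_study_engine(fe, study_cfg, sg_filter = sg, sg_map = sg,
                         truths = list(truth), n_iterations = 1,
                         datasets0 = datasets_so_far, return_fe = TRUE)
  st
}

# Core engine shared by run_nc_iteration and run_simulation_study.
# All model outputs come from cached solution grids, so iterating costs
# matrix bookkeeping only.
run_study_engine <- function(fe, study_cfg, sg_filter, sg_map, truths,
                             n_iterations, datasets0 = list(),
                             return_fe = FALSE, truth_rows = NULL) {
  grid <- sg_filter$grid
  n_cells <- nrow(grid)
  Of <- sg_filter$outputs            # filtering outputs (n_fits x 9 x cells)
  Om <- sg_map$outputs               # map outputs
  theta <- study_cfg$theta
  t_max <- study_cfg$cfg$t_max
  constraints <- study_cfg$constraints
  n_fits <- length(sg_filter$fit_ids)
  sens_cache <- new.env(parent = emptyenv())

  # error contribution of every fit against truth row l at cell ci
  cell_errors <- function(l, ci, noise = NULL) {
    obs <- Of[l, , ci]
    if (!is.null(noise)) obs <- obs * noise
    M <- Of[, , ci, drop = FALSE]
    dim(M) <- dim(M)[1:2]
    msle_rows(M, obs, t_max = t_max)
  }

  rows <- list()
  fe_out <- NULL
  for (ti in seq_along(truths)) {
    truth <- truths[[ti]]
    l <- if (is.null(truth_rows)) NULL else truth_rows[[ti]]
    accepted <- rep(TRUE, n_fits)
    err_sum <- rep(0, n_fits)
    n_data <- length(datasets0)
    # pre-scored error against any pre-existing datasets
    if (n_data > 0) {
      datasets <- cache_progress(datasets0)
      for (ds in datasets) {
        ci <- which(abs(log(grid$r_p / ds$conditions[["r_p"]])) < 1e-9 &
                      abs(log(grid$O3_g0 / ds$conditions[["O3_g0"]])) < 1e-9)
        obs <- attr(ds, "progress_cache")
        if (length(ci) > 0) {
          M <- Of[, , ci[1], drop = FALSE]
          dim(M) <- dim(M)[1:2]
        } else {
          # dataset condition off-grid: evaluate the ensemble there
          M <- ensemble_solution(fe, ds$conditions, study_cfg$cfg,
                                 fit_ids = sg_filter$fit_ids)$outputs
        }
        err_sum <- err_sum + msle_rows(M, obs, t_max = t_max)
      }
      accepted <- err_sum / n_data < theta
    }
    datasets <- datasets0

    measured <- rep(FALSE, n_cells)
    for (it in seq_len(n_iterations)) {
      if (!any(accepted)) {
        warning("all fits rejected; stopping iterations for this truth")
        break
      }
      stats <- study_cell_stats(Om, which(accepted), constraints)
      if (!any(stats$feasible)) {
        warning("no feasible cell; stopping iterations for this truth")
        break
      }
      # never repeat an already-measured condition for the same truth
      # (a noiseless repeat carries no new information); if every feasible
      # cell has been measured, repeats are allowed again
      candidate <- stats$feasible & !measured
      if (!any(candidate)) candidate <- stats$feasible
      ci <- switch(study_cfg$selector,
        random = {
          set.seed(study_cfg$seed * 1000003L + ti * 1009L + it)
          sample(which(candidate), 1)
        },
        sensitivity = {
          # map at the current best (lowest-error) fit, cached by fit id
          best <- if (n_data == 0) which.min(fe$fits$error) else
            which.min(ifelse(accepted, err_sum, Inf))
          key <- as.character(best)
          sens <- if (!is.null(sens_cache[[key]])) sens_cache[[key]] else {
            p <- unlist(fe$fits[best, kinetic_parameter_names()])
            s <- surrogate_sensitivity(p, grid, study_cfg$surrogate,
                                       study_cfg$fd_step)
            sens_cache[[key]] <- s
            s
          }
          v <- ifelse(candidate, sens, -Inf)
          which(v == max(v))[1]
        },
        {
          v <- ifelse(candidate, stats$es, -Inf)
          which(v == max(v))[1]
        })
      measured[ci] <- TRUE

      # a simulated experiment where the truth reaches no progress level
      # within the horizon is uninformative: the iteration is spent but
      # the filter is unchanged (the error metric compares observed
      # levels only)
      informative <- TRUE
      if (is.null(l)) {
        # external truth: evaluate it directly at the chosen condition
        cc <- c(r_p = grid$r_p[ci], O3_g0 = grid$O3_g0[ci],
                OL_b0 = grid$OL_b0[ci])
        ds <- tryCatch(
          simulate_truth_experiment(truth, cc, study_cfg$cfg,
                                    noise_sigma = study_cfg$noise_sigma,
                                    dataset_id = paste0("sim", it)),
          error = function(e) NULL)
        if (is.null(ds)) {
          informative <- FALSE
        } else {
          datasets <- c(datasets, list(ds))
          obs <- observed_progress_times(ds)
          M <- Of[, , ci, drop = FALSE]
          dim(M) <- dim(M)[1:2]
          err_sum <- err_sum + msle_rows(M, obs, t_max = t_max)
        }
      } else if (all(is.na(Of[l, , ci]))) {
        informative <- FALSE
      } else {
        noise <- NULL
        if (study_cfg$noise_sigma > 0) {
          set.seed(study_cfg$seed * 2000003L + ti * 1013L + it)
          noise <- exp(rnorm(9, 0, study_cfg$noise_sigma))
        }
        err_sum <- err_sum + cell_errors(l, ci, noise)
      }
      if (informative) n_data <- n_data + 1
      now <- if (n_data == 0) accepted else err_sum / n_data < theta
      rows[[length(rows) + 1]] <- tibble::tibble(
        selector = study_cfg$selector, truth_id = ti, iteration = it,
        cell = grid$cell[ci], r_p = grid$r_p[ci], O3_g0 = grid$O3_g0[ci],
        n_accepted = sum(now), n_rejected = sum(accepted & !now),
        n_revived = sum(!accepted & now), remaining = sum(now))
      accepted <- now
    }
    if (return_fe) {
      fits <- fe$fits
      fits$error <- err_sum / max(n_data, 1)
      fits$accepted <- accepted
      fe_out <- fe
      fe_out$fits <- fits
      fe_out$theta <- theta
    }
  }
  traj <- dplyr::bind_rows(rows)
  if (return_fe) {
    last <- traj[nrow(traj), ]
    return(list(condition = c(r_p = last$r_p, O3_g0 = last$O3_g0,
                              OL_b0 = grid$OL_b0[match(last$cell,
                                                       grid$cell)]),
                cell = last$cell, fe = fe_out,
                counts = c(accepted = last$n_accepted,
                           rejected = last$n_rejected,
                           revived = last$n_revived),
                datasets = datasets))
  }
  traj
}

#' Run the full simulated-experiment study
#'
#' Every accepted fit takes a turn as the simulated truth; for each truth
#' the suggest-measure-filter loop runs `n_iterations` times with the
#' configured selector, and accepted / rejected / revived counts are
#' recorded per iteration. All ensemble solutions over the grid are
#' computed once and cached, so the loop itself is pure bookkeeping.
#'
#' Selectors: `nc_es_km` maps ensemble spread from kinetic-model solutions;
#' `nc_es_hybrid` maps spread from surrogate solutions while filtering with
#' kinetic-model solutions; `nc_es_sm` uses surrogate solutions for both;
#' `random` picks a uniformly random feasible cell; `sensitivity` picks the
#' feasible cell with the largest total finite-difference sensitivity at
#' the current best fit (surrogate derivatives).
#'
#' @param fe a `fit_ensemble`
#' @param study_cfg a [simulation_config()]
#' @param solution_grids optional named list with entries `km` and/or `sm`
#'   (precomputed [solution_grid()]s over `study_cfg$grid` for ALL stored
#'   fits) to reuse across selector runs
#' @return A `simulation_study`: list with `trajectories` tibble
#'   (selector, truth_id, iteration, cell, counts), `grids` (the cached
#'   solution grids, reusable), `config`.
#' @export
run_simulation_study <- function(fe, study_cfg, solution_grids = NULL) {
  all_ids <- fe$fits$fit_id
  need_sm <- study_cfg$selector %in% c("nc_es_hybrid", "nc_es_sm")
  sg_km <- solution_grids$km
  if (is.null(sg_km) && (study_cfg$selector != "nc_es_sm")) {
    sg_km <- solution_grid(fe, study_cfg$grid, study_cfg$cfg,
                           fit_ids = all_ids)
  }
  sg_sm <- solution_grids$sm
  if (is.null(sg_sm) && need_sm) {
    sg_sm <- solution_grid(fe, study_cfg$grid, study_cfg$cfg,
                           evaluator = sm_evaluator(study_cfg$surrogate),
                           fit_ids = all_ids)
  }
  sg_map <- switch(study_cfg$selector,
                   nc_es_hybrid = sg_sm, nc_es_sm = sg_sm, sg_km)
  sg_filter <- if (study_cfg$selector == "nc_es_sm") sg_sm else sg_km
  truth_rows <- study_cfg$truth_ids %||% all_ids[fe$fits$accepted]
  truth_rows <- match(truth_rows, sg_filter$fit_ids)
  kin <- kinetic_parameter_names()
  truths <- lapply(truth_rows, function(i) unlist(fe$fits[i, kin]))

  traj <- run_study_engine(fe, study_cfg, sg_filter, sg_map, truths,
                           study_cfg$n_iterations,
                           truth_rows = as.list(truth_rows))
  structure(list(trajectories = traj,
                 grids = list(km = sg_km, sm = sg_sm),
                 config = study_cfg),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  tr <- x$trajectories
  last <- tr[tr$iteration == max(tr$iteration), ]
  cat(sprintf(paste0("<simulation_study> selector %s: %d truths, %d ",
                     "iterations, median remaining %g\n"),
              x$config$selector, length(unique(tr$truth_id)),
              max(tr$iteration), median(last$remaining)))
  invisible(x)
}

#' @export
tidy.simulation_study <- function(x, ...) x$trajectories

#' @export
glance.simulation_study <- function(x, ...) {
  tr <- x$trajectories
  dplyr::summarise(dplyr::group_by(tr, .data$iteration),
                   median_accepted = median(.data$n_accepted),
                   median_rejected = median(.data$n_rejected),
                   median_revived = median(.data$n_revived),
                   median_remaining = median(.data$remaining),
                   .groups = "drop")
}

#' Sensitivity map of the model response at one parameter set
#'
#' Per grid cell, central finite differences of the nine log10 progress
#' times with respect to each log10 kinetic parameter; the per-parameter
#' sensitivity is the mean absolute derivative over the nine outputs and
#' the cell value is the sum over the seven parameters.
#'
#' @param params named kinetic parameter vector (typically the best fit)
#' @param grid tibble from [condition_grid()]
#' @param cfg model configuration
#' @param evaluator optional evaluator; pass [sm_evaluator()] for fast
#'   surrogate derivatives (recommended for large grids)
#' @param fd_step central-difference step in log10 units
#' @param constraints a [feasibility_constraints()]; feasibility uses this
#'   fit's own duration at each cell
#' @return A `constraint_map` with the total sensitivity as `value`.
#' @export
sensitivity_map <- function(params, grid, cfg = model_config(),
                            evaluator = NULL, fd_step = 0.05,
                            constraints = feasibility_constraints()) {
  if (is.null(evaluator)) {
    evaluator <- function(p, cc) km_progress(p, cc, cfg)
  }
  kin <- kinetic_parameter_names()
  lp <- log10(params[kin])
  P <- matrix(rep(lp, 15), 15, 7, byrow = TRUE, dimnames = list(NULL, kin))
  for (j in 1:7) {
    P[2 * j, j] <- lp[j] + fd_step
    P[2 * j + 1, j] <- lp[j] - fd_step
  }
  P <- 10^P
  batch_fn <- attr(evaluator, "batch")
  n_cells <- nrow(grid)
  value <- duration <- onset <- rep(NA_real_, n_cells)
  dq <- match(constraints$duration_quantile,
              paste0("t", format(progress_fractions())))
  for (ci in seq_len(n_cells)) {
    cc <- c(r_p = grid$r_p[ci], O3_g0 = grid$O3_g0[ci],
            OL_b0 = grid$OL_b0[ci])
    Z <- if (!is.null(batch_fn)) batch_fn(P, cc) else
      t(apply(P, 1, function(p) {
        tryCatch(evaluator(p, cc), error = function(e) rep(NA_real_, 9))
      }))
    Z <- log10(Z)
    tot <- 0
    for (j in 1:7) {
      tot <- tot + mean(abs(Z[2 * j, ] - Z[2 * j + 1, ]) / (2 * fd_step))
    }
    value[ci] <- tot
    duration[ci] <- Z[1, dq]
    onset[ci] <- Z[1, 1]
  }
  duration <- 10^duration
  onset <- 10^onset
  in_range <- rep(TRUE, n_cells)
  for (nm in intersect(names(constraints$ranges), names(grid))) {
    rng <- constraints$ranges[[nm]]
    in_range <- in_range & grid[[nm]] >= rng[1] & grid[[nm]] <= rng[2]
  }
  feasible <- in_range & !is.na(duration) & !is.na(onset) & !is.na(value) &
    onset >= constraints$duration_window[1] &
    duration <= constraints$duration_window[2]
  out <- dplyr::mutate(grid, value = value, feasible = feasible,
                       censored_frac = as.numeric(is.na(value)),
                       duration = duration, onset = onset)
  argmax <- NA_integer_
  if (any(feasible)) argmax <- which(feasible & value ==
                                       max(value[feasible]))[1]
  structure(out, class = c("constraint_map", class(out)),
            metric = "sensitivity", theta = NA_real_, argmax = argmax,
            constraints = constraints)
}

#' Brute-force constraint map
#'
#' The expensive ground truth the spread map approximates: for every cell,
#' every accepted fit in turn plays the simulated truth and the map value
#' is the median number of fits a single filtering step at that cell would
#' reject.
#'
#' @param fe a `fit_ensemble`
#' @param grid tibble from [condition_grid()] or a cached [solution_grid()]
#' @param theta acceptance threshold
#' @param cfg model configuration
#' @param evaluator optional evaluator
#' @param constraints a [feasibility_constraints()]
#' @return A `constraint_map` with the median rejected-fit count as
#'   `value`.
#' @export
brute_force_constraint_map <- function(fe, grid, theta = fe$theta,
                                       cfg = model_config(),
                                       evaluator = NULL,
                                       constraints =
                                         feasibility_constraints()) {
  f <- function(ens) {
    n <- nrow(ens$outputs)
    subs <- subset_indices(ens$outputs, theta, 1, cfg$t_max)
    median(vapply(subs, function(idx) n - length(idx), numeric(1)))
  }
  m <- constraint_map(fe, grid, metric = f, constraints = constraints,
                      cfg = cfg, evaluator = evaluator, theta = theta)
  attr(m, "metric") <- "brute_force_rejections"
  m
}
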