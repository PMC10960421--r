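trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# population (ddof = 0) column standard deviation
col_sd0 <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(m^2) - mu^2)
}

es_core <- function(outputs, quiet = FALSE) {
  z <- log10(outputs)
  ok <- stats::complete.cases(z)
  z <- z[ok, , drop = FALSE]
  if (nrow(z) == 0) stop("all ensemble rows censored; no spread defined")
  if (nrow(z) == 1) {
    if (!quiet) warning("single-member ensemble; spread is 0 by convention")
    return(0)
  }
  x <- rev(progress_fractions())           # ascending 0.1 ... 0.9
  z <- z[, ncol(z):1, drop = FALSE]        # align columns with ascending x
  zbar <- colMeans(z)
  sig <- col_sd0(z)
  (trapz(x, zbar + sig) - trapz(x, zbar - sig)) / trapz(x, zbar)
}

#' Ensemble spread of an ensemble solution
#'
#' The area enclosed by the ensemble mean +/- one standard deviation of the
#' interpolated nine-point output curves, normalized by the area under the
#' ensemble mean. Outputs are taken as log10 progress times over the
#' progress-fraction axis; curves are interpolated piecewise-linearly and
#' integrated by the trapezoid rule; the standard deviation is the
#' population one (the ensemble is treated as the full representation of
#' the solution space). Under these conventions the spread equals
#' `2 * integral(sd) / integral(mean)`.
#'
#' Rows with any censored entry are excluded (they have no complete curve).
#'
#' @param ens an [ensemble_solution()]
#' @return Non-negative scalar spread.
#' @export
ensemble_spread <- function(ens) {
  es_core(ens$outputs)
}

# pairwise model-model MSLE of row l against all rows (l as the observation)
delta_to_row <- function(logt, l, log_tmax) {
  obs <- logt[l, ]
  use <- !is.na(obs)
  d <- sweep(logt[, use, drop = FALSE], 2, obs[use], "-")
  d[is.na(d)] <- sweep(matrix(log_tmax, nrow(logt), sum(use)), 2,
                       obs[use], "-")[is.na(d)]
  rowMeans(d^2)
}

subset_indices <- function(outputs, theta, stride, t_max) {
  logt <- log(outputs)
  n <- nrow(logt)
  if (stride > n) stop("sample stride exceeds ensemble size")
  subs <- lapply(seq(1, n, by = stride), function(l) {
    # a fully censored outcome observes nothing and is uninformative:
    # the error metric compares observed levels only, so such
    # hypothetical experiments are skipped
    if (all(is.na(logt[l, ]))) return(NULL)
    which(delta_to_row(logt, l, log(t_max)) < theta)
  })
  subs[!vapply(subs, is.null, logical(1))]
}

#' Parameter constraint potential of an ensemble solution
#'
#' Quantifies how much a hypothetical experiment at this condition could
#' narrow one kinetic parameter's range. Each ensemble member in turn is
#' treated as the experiment's outcome; the members within the acceptance
#' threshold of it form the hypothetically constrained subensemble, and the
#' potential sums, over all hypothetical outcomes, the narrowing of the
#' parameter's 5-95 percentile range relative to its full-ensemble min/max:
#' `sum_l (Q5_l - min) + (max - Q95_l)` (log10-parameter units).
#'
#' The pairwise comparison is quadratic in ensemble size; `sample_stride`
#' evaluates every stride-th member only (a reduced sample density
#' approximation; the returned value is then the sum over evaluated members,
#' with the stride recorded as an attribute).
#'
#' @param ens an [ensemble_solution()]
#' @param fe the `fit_ensemble` the solution was computed from
#' @param param kinetic parameter name
#' @param theta acceptance threshold (defaults to the ensemble's)
#' @param sample_stride evaluate every stride-th member (default 1 = all)
#' @param t_max censoring horizon for the pairwise metric
#' @return Non-negative scalar with attributes `n_used` and `stride`.
#' @export
parameter_constraint_potential <- function(ens, fe, param,
                                           theta = fe$theta,
                                           sample_stride = 1,
                                           t_max = 1e6) {
  stopifnot(param %in% kinetic_parameter_names(), theta > 0)
  lam <- log10(fe$fits[[param]][match(ens$fit_ids, fe$fits$fit_id)])
  lo <- min(lam); hi <- max(lam)
  subs <- subset_indices(ens$outputs, theta, sample_stride, t_max)
  terms <- vapply(subs, function(idx) {
    q <- quantile(lam[idx], c(0.05, 0.95), names = FALSE)
    (q[1] - lo) + (hi - q[2])
  }, numeric(1))
  structure(sum(terms), n_used = length(subs), stride = sample_stride)
}

#' Target constraint potential
#'
#' Expected reduction of the ensemble spread at a fixed target condition
#' achieved by filtering on a candidate test condition: each member of the
#' test-condition solution is treated as the hypothetical experimental
#' outcome, the within-threshold subensemble is formed, and the spread of
#' the target-condition solution restricted to that subensemble is compared
#' with the full-target spread. The potential is the mean reduction over
#' hypothetical outcomes; larger is better.
#'
#' @param ens_test ensemble solution at the candidate test condition
#' @param ens_target ensemble solution at the target condition (same fits)
#' @param theta acceptance threshold
#' @param sample_stride evaluate every stride-th member
#' @param t_max censoring horizon
#' @return Scalar mean spread reduction (>= 0 up to sampling effects).
#' @export
target_constraint_potential <- function(ens_test, ens_target, theta,
                                        sample_stride = 1, t_max = 1e6) {
  stopifnot(identical(ens_test$fit_ids, ens_target$fit_ids))
  es_full <- es_core(ens_target$outputs, quiet = TRUE)
  subs <- subset_indices(ens_test$outputs, theta, sample_stride, t_max)
  red <- vapply(subs, function(idx) {
    # outcomes whose subensemble is fully censored at the target leave
    # the target spread undefined; they are skipped like fully censored
    # outcomes
    tryCatch(es_full - es_core(ens_target$outputs[idx, , drop = FALSE],
                               quiet = TRUE),
             error = function(e) NA_real_)
  }, numeric(1))
  mean(red, na.rm = TRUE)
}

#' Experimental feasibility constraints
#'
#' Accessible ranges for the varied experimental parameters plus a window on
#' the predicted observable timescales: the ensemble-median onset (time to
#' the first progress level, 90 % remaining) must lie at or above the
#' window's lower edge, and the ensemble-median duration (default: time to
#' 10 % remaining, near-complete conversion) at or below its upper edge.
#' The default window of 1 s to 1e5 s keeps the whole nine-point curve on
#' laboratory-measurable timescales; it also keeps the spread metric in its
#' valid domain (log10 times non-negative), where its normalization by the
#' mean curve is meaningful.
#'
#' @param ranges named list of `c(min, max)` accessible ranges; defaults to
#'   the experimental rows of [default_bounds()]
#' @param duration_window `c(min, max)` seconds on the duration statistic
#' @param duration_quantile progress column used as duration (default
#'   `"t0.1"`)
#' @param max_censored_frac cells whose solutions are censored in more than
#'   this fraction of members are infeasible
#' @return A list of class `feasibility_constraints`.
#' @export
feasibility_constraints <- function(ranges = NULL,
                                    duration_window = c(1, 1e5),
                                    duration_quantile = "t0.1",
                                    max_censored_frac = 0.5) {
  if (is.null(ranges)) {
    b <- default_bounds()
    b <- b[b$kind == "experimental", ]
    ranges <- setNames(Map(c, b$lower, b$upper), b$parameter)
  }
  stopifnot(duration_window[1] <= duration_window[2])
  structure(list(ranges = ranges, duration_window = duration_window,
                 duration_quantile = duration_quantile,
                 max_censored_frac = max_censored_frac),
            class = "feasibility_constraints")
}

#' Grid of candidate experimental conditions
#'
#' Log-spaced grid over particle radius and ozone concentration (the
#' decade-spanning experimental parameters) at fixed initial oleic acid
#' concentration. Cells are ordered row-major in the axis order given.
#'
#' @param n_r,n_o3 grid resolution per axis
#' @param r_range,o3_range axis ranges (cm; cm-3)
#' @param OL_b0 fixed initial oleic acid concentration (cm-3)
#' @return Tibble with `cell`, `r_p`, `O3_g0`, `OL_b0`.
#' @export
condition_grid <- function(n_r = 10, n_o3 = 10,
                           r_range = c(2.5e-6, 1e-3),
                           o3_range = c(1e11, 1e15), OL_b0 = 1.9e21) {
  g <- tidyr::expand_grid(
    r_p = 10^seq(log10(r_range[1]), log10(r_range[2]), length.out = n_r),
    O3_g0 = 10^seq(log10(o3_range[1]), log10(o3_range[2]),
                   length.out = n_o3))
  dplyr::mutate(g, OL_b0 = OL_b0,
                cell = dplyr::row_number(), .before = "r_p")
}

#' Ensemble solutions over a condition grid
#'
#' Evaluates the nine-point output of every accepted fit at every grid cell.
#' The result is the expensive, reusable object behind constraint-potential
#' maps and simulation studies: metrics over any accepted subset of fits can
#' be recomputed from it without further model evaluations.
#'
#' @param fe a `fit_ensemble`
#' @param grid tibble from [condition_grid()]
#' @param cfg model configuration
#' @param evaluator optional nine-point evaluator (default kinetic model)
#' @param fit_ids fits to evaluate (default all accepted)
#' @return A `solution_grid`: list with `grid`, `fit_ids`, `outputs`
#'   (array n_fits x 9 x n_cells).
#' @export
solution_grid <- function(fe, grid, cfg = model_config(), evaluator = NULL,
                          fit_ids = NULL) {
  if (is.null(fit_ids)) fit_ids <- fe$fits$fit_id[fe$fits$accepted]
  kin <- kinetic_parameter_names()
  if (is.null(evaluator)) {
    evaluator <- function(p, cc) km_progress(p, cc, cfg)
  }
  rows <- match(fit_ids, fe$fits$fit_id)
  pm <- as.matrix(fe$fits[rows, kin])
  out <- array(NA_real_, dim = c(length(fit_ids), 9, nrow(grid)))
  n_fail <- 0L
  batch_fn <- attr(evaluator, "batch")
  for (ci in seq_len(nrow(grid))) {
    cc <- c(r_p = grid$r_p[ci], O3_g0 = grid$O3_g0[ci],
            OL_b0 = grid$OL_b0[ci])
    if (!is.null(batch_fn)) {
      out[, , ci] <- unname(batch_fn(pm, cc))
      next
    }
    for (fi in seq_along(fit_ids)) {
      pt <- tryCatch(evaluator(pm[fi, ], cc), error = function(e) {
        n_fail <<- n_fail + 1L
        rep(NA_real_, 9)
      })
      out[fi, , ci] <- pt
    }
  }
  if (n_fail > 0) {
    warning(sprintf("%d of %d grid evaluations failed and are censored",
                    n_fail, length(fit_ids) * nrow(grid)))
    if (n_fail > 0.2 * length(fit_ids) * nrow(grid)) {
      stop("more than 20% of grid evaluations failed")
    }
  }
  structure(list(grid = grid, fit_ids = fit_ids, outputs = out),
            class = "solution_grid")
}

cell_solution <- function(sg, ci, fit_ids = NULL) {
  idx <- if (is.null(fit_ids)) seq_along(sg$fit_ids) else
    match(fit_ids, sg$fit_ids)
  outputs <- sg$outputs[idx, , ci, drop = FALSE]
  dim(outputs) <- dim(outputs)[1:2]
  colnames(outputs) <- paste0("t", format(progress_fractions()))
  structure(list(condition = c(r_p = sg$grid$r_p[ci],
                               O3_g0 = sg$grid$O3_g0[ci],
                               OL_b0 = sg$grid$OL_b0[ci]),
                 outputs = outputs,
                 fit_ids = sg$fit_ids[idx]),
            class = "ensemble_solution")
}

map_metric_fun <- function(metric, fe, theta, param, target_ens, stride,
                           t_max) {
  if (is.function(metric)) return(metric)
  switch(metric,
    es = function(ens) es_core(ens$outputs, quiet = TRUE),
    pcp = {
      stopifnot(!is.null(param))
      function(ens) as.numeric(
        parameter_constraint_potential(ens, fe, param, theta, stride, t_max))
    },
    tcp = {
      stopifnot(!is.null(target_ens))
      function(ens) target_constraint_potential(ens, target_ens, theta,
                                                stride, t_max)
    },
    stop("unknown metric: ", metric))
}

#' Constraint potential map over a condition grid
#'
#' Applies a constraint metric to the ensemble solution of every grid cell
#' and attaches the feasibility mask and the feasible arg-max — the
#' suggested next experiment. Ties at the maximum break to the first cell
#' in row-major grid order.
#'
#' @param fe a `fit_ensemble`
#' @param grid tibble from [condition_grid()], or a precomputed
#'   [solution_grid()] (which avoids any model evaluation here)
#' @param metric `"es"`, `"pcp"`, `"tcp"`, or a function
#'   `(ensemble_solution) -> scalar`
#' @param constraints a [feasibility_constraints()]
#' @param cfg model configuration
#' @param evaluator optional nine-point evaluator
#' @param param kinetic parameter name (for `"pcp"`)
#' @param target_cond target condition vector (for `"tcp"`); its ensemble
#'   solution is computed with the same evaluator
#' @param theta acceptance threshold for subset formation
#' @param sample_stride reduced sample density for pcp/tcp
#' @param fit_ids accepted-fit subset to use (default: all accepted)
#' @return A `constraint_map`: tibble (`cell`, `r_p`, `O3_g0`, `value`,
#'   `feasible`, `censored_frac`, `duration`, `onset`) with attributes `metric`,
#'   `theta`, `argmax` (feasible arg-max row) and `constraints`.
#' @export
constraint_map <- function(fe, grid, metric = "es",
                           constraints = feasibility_constraints(),
                           cfg = model_config(), evaluator = NULL,
                           param = NULL, target_cond = NULL, theta = fe$theta,
                           sample_stride = 1, fit_ids = NULL) {
  sg <- if (inherits(grid, "solution_grid")) grid else
    solution_grid(fe, grid, cfg, evaluator, fit_ids)
  if (inherits(grid, "solution_grid") && !is.null(fit_ids)) {
    # restrict a cached grid to the currently accepted fits
    sub <- match(fit_ids, sg$fit_ids)
    sg <- structure(list(grid = sg$grid, fit_ids = fit_ids,
                         outputs = sg$outputs[sub, , , drop = FALSE]),
                    class = "solution_grid")
  }
  target_ens <- NULL
  if (!is.null(target_cond)) {
    target_ens <- ensemble_solution(fe, target_cond, cfg, evaluator,
                                    fit_ids = sg$fit_ids)
  }
  f <- map_metric_fun(metric, fe, theta, param, target_ens, sample_stride,
                      cfg$t_max)

  dq <- match(constraints$duration_quantile,
              paste0("t", format(progress_fractions())))
  n_cells <- nrow(sg$grid)
  value <- duration <- onset <- cens <- numeric(n_cells)
  for (ci in seq_len(n_cells)) {
    ens <- cell_solution(sg, ci)
    cens[ci] <- mean(!stats::complete.cases(ens$outputs))
    value[ci] <- tryCatch(f(ens), error = function(e) NA_real_)
    duration[ci] <- median(ens$outputs[, dq], na.rm = TRUE)
    onset[ci] <- median(ens$outputs[, 1], na.rm = TRUE)
  }
  if (mean(is.na(value)) > 0.2) stop("more than 20% of map cells failed")

  in_range <- rep(TRUE, n_cells)
  for (nm in intersect(names(constraints$ranges), names(sg$grid))) {
    rng <- constraints$ranges[[nm]]
    in_range <- in_range & sg$grid[[nm]] >= rng[1] & sg$grid[[nm]] <= rng[2]
  }
  feasible <- in_range & !is.na(duration) & !is.na(onset) &
    onset >= constraints$duration_window[1] &
    duration <= constraints$duration_window[2] &
    cens <= constraints$max_censored_frac & !is.na(value)

  out <- dplyr::mutate(sg$grid, value = value, feasible = feasible,
                       censored_frac = cens, duration = duration,
                       onset = onset)
  argmax <- NA_integer_
  if (any(feasible)) {
    vmax <- max(value[feasible])
    argmax <- which(feasible & value == vmax)[1]
  }
  structure(out, class = c("constraint_map", class(out)),
            metric = if (is.function(metric)) "custom" else metric,
            theta = theta, argmax = argmax, constraints = constraints)
}

#' Suggested next experiment from a constraint map
#'
#' The feasible cell with the largest metric value; ties break to the first
#' cell in row-major grid order.
#'
#' @param map a [constraint_map()]
#' @return Condition vector `c(r_p, O3_g0, OL_b0)` with attribute `cell`.
#' @export
suggest_experiment <- function(map) {
  argmax <- attr(map, "argmax")
  if (is.na(argmax)) stop("no feasible cell in the constraint map")
  structure(c(r_p = map$r_p[argmax], O3_g0 = map$O3_g0[argmax],
              OL_b0 = map$OL_b0[argmax]),
            cell = map$cell[argmax])
}

#' Export a constraint map
#'
#' CSV of the cell table plus a JSON metadata sidecar (metric, threshold,
#' suggested experiment).
#'
#' @param map a [constraint_map()]
#' @param path CSV path
#' @return The path, invisibly.
#' @export
write_constraint_map <- function(map, path) {
  readr::write_csv(tibble::as_tibble(map), path)
  argmax <- attr(map, "argmax")
  meta <- list(metric = attr(map, "metric"), theta = attr(map, "theta"),
               argmax_cell = if (is.na(argmax)) NULL else map$cell[argmax],
               suggested = if (is.na(argmax)) NULL else
                 as.list(suggest_experiment(map)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Plot a constraint map
#'
#' Log-log raster of the metric with the feasible region outlined and the
#' suggested experiment marked.
#'
#' @param object a [constraint_map()]
#' @param ... unused
#' @return A ggplot object.
#' @export
autoplot.constraint_map <- function(object, ...) {
  argmax <- attr(object, "argmax")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$r_p, .data$O3_g0)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = function(d) d[d$feasible, ],
                        shape = ".", colour = "white") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "metric")) +
    ggplot2::labs(x = "particle radius (cm)",
                  y = "ozone concentration (cm-3)")
  if (!is.na(argmax)) {
    p <- p + ggplot2::annotate("point", x = object$r_p[argmax],
                               y = object$O3_g0[argmax], shape = 4,
                               size = 4, colour = "purple")
  }
  p
}
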