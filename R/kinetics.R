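#' Configuration of the multi-layer kinetic model
#'
#' Discretization and solver knobs for [simulate_decay()]. Defaults follow
#' common practice for layered reactive-diffusion particle models.
#'
#' @param n_layers number of bulk shells (>= 1)
#' @param first_layer thickness of the outermost shell (cm), or `NULL` for
#'   the default `max(surface_layer_thickness, 1e-4 * r_p)` capped at
#'   `r_p / n_layers`. Shell thickness then grows geometrically inward so
#'   the shells sum to the radius. Grading keeps the outermost shells thin
#'   enough to resolve the reacto-diffusive front that forms at the particle
#'   surface under fast bulk reaction; for small particles the grid reduces
#'   to equal-thickness shells.
#' @param t_max integration horizon (s); progress levels not reached by
#'   `t_max` are censored
#' @param t_min first positive output time (s)
#' @param n_times number of log-spaced output times between `t_min` and `t_max`
#' @param rel_tol,abs_tol solver tolerances; `abs_tol` is relative to the
#'   natural scale of each species
#' @param surface_layer_thickness molecular length scale of the surface
#'   layer (cm)
#' @param sigma_O3 effective molecular cross section of sorbed ozone (cm2),
#'   sets Langmuir surface coverage
#' @param gas_diffusion logical; apply the transition-regime gas-phase
#'   diffusion correction
#' @param gas_diffusivity gas-phase diffusivity of ozone (cm2 s-1)
#' @param temperature temperature (K), used for the thermal velocity and the
#'   Henry's law conversion
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_layers = 40, first_layer = NULL, t_max = 1e6,
                         t_min = 1e-4, n_times = 140, rel_tol = 1e-6,
                         abs_tol = 1e-8, surface_layer_thickness = 8e-8,
                         sigma_O3 = 1.5e-15, gas_diffusion = TRUE,
                         gas_diffusivity = 0.14, temperature = 296) {
  stopifnot(n_layers >= 1, t_max > t_min, t_min > 0,
            rel_tol > 0, abs_tol > 0, n_times >= 20)
  structure(list(n_layers = as.integer(n_layers),
                 first_layer = first_layer, t_max = t_max,
                 t_min = t_min, n_times = as.integer(n_times),
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 surface_layer_thickness = surface_layer_thickness,
                 sigma_O3 = sigma_O3, gas_diffusion = gas_diffusion,
                 gas_diffusivity = gas_diffusivity,
                 temperature = temperature),
            class = "model_config")
}

#' The nine reaction-progress fractions
#'
#' Model output is summarized as the times at which the remaining oleic acid
#' fraction first reaches 0.9, 0.8, ..., 0.1.
#' @return Numeric vector `c(0.9, ..., 0.1)`.
#' @export
progress_fractions <- function() seq(0.9, 0.1, by = -0.1)

#' Dimensionless Henry's law equilibrium
#'
#' Equilibrium dissolved ozone number concentration per the ideal gas law:
#' `[O3]_b,eq = H_cp * R * T * [O3]_g` with R = 82.0574 cm3 atm mol-1 K-1.
#'
#' @param params kinetic parameter set (uses `H_cp_O3`)
#' @param cond experimental conditions (uses `O3_g0`)
#' @param cfg model configuration (uses `temperature`)
#' @return Equilibrium bulk ozone concentration (cm-3).
#' @export
henry_equilibrium <- function(params, cond, cfg = model_config()) {
  params[["H_cp_O3"]] * 82.0574 * cfg$temperature * cond[["O3_g0"]]
}

first_layer_thickness <- function(r_p, cfg) {
  d1 <- cfg$first_layer
  if (is.null(d1)) d1 <- max(cfg$surface_layer_thickness, 1e-4 * r_p)
  min(d1, r_p / cfg$n_layers)
}

shell_geometry <- function(r_p, n, d1 = r_p / n) {
  if (d1 * n >= r_p * (1 - 1e-12)) {
    delta <- rep(r_p / n, n)
  } else {
    lo <- 1 + 1e-12; hi <- 3
    for (it in 1:100) {
      g <- (lo + hi) / 2
      if (d1 * (g^n - 1) / (g - 1) < r_p) lo <- g else hi <- g
    }
    delta <- d1 * ((lo + hi) / 2)^(seq_len(n) - 1)
  }
  r_out <- r_p - c(0, cumsum(delta))[seq_len(n)]
  r_in <- pmax(r_p - cumsum(delta), 0)
  r_in[n] <- 0
  list(delta = delta,
       volume = 4 * pi / 3 * (r_out^3 - r_in^3),
       area_surface = 4 * pi * r_p^2)
}

#' Simulate the normalized oleic acid decay
#'
#' Integrates the layered flux ODE system (gas-phase diffusion, reversible
#' surface accommodation with Langmuir coverage, surface reaction,
#' surface-bulk exchange consistent with Henry's law, layer-to-layer bulk
#' diffusion, bulk reaction) and returns the total oleic acid number,
#' normalized to its initial value, on a log-spaced time grid. The gas-phase
#' ozone reservoir is held constant (excess ozone).
#'
#' @param params named kinetic parameter vector, see [kinetic_params()]
#' @param cond named condition vector, see [conditions()]
#' @param cfg a [model_config()]
#' @return A tibble (`decay_curve`) with columns `time_s` and
#'   `fraction_remaining`, starting at `time_s = 0` with fraction 1.
#' @name simulate_decay
NULL

km_solve <- function(params, cond, cfg) {
  n <- cfg$n_layers
  p <- c(n, params[["k_SLR"]], params[["k_BR"]], params[["D_b_O3"]],
         params[["D_b_OL"]], params[["H_cp_O3"]], params[["tau_d_O3"]],
         params[["alpha_s0_O3"]], cond[["r_p"]], cond[["O3_g0"]],
         cond[["OL_b0"]], cfg$temperature, cfg$surface_layer_thickness,
         cfg$sigma_O3, cfg$gas_diffusivity, as.numeric(cfg$gas_diffusion),
         first_layer_thickness(cond[["r_p"]], cfg))
  if (any(!is.finite(p))) stop("non-finite model input")

  y0 <- c(0, cfg$surface_layer_thickness * cond[["OL_b0"]],
          rbind(rep(0, n), rep(cond[["OL_b0"]], n)))

  # per-species absolute tolerances on each state's natural scale
  o3_scale <- max(henry_equilibrium(params, cond, cfg), 1)
  atol <- cfg$abs_tol * c(max(1, params[["tau_d_O3"]] *
                                params[["alpha_s0_O3"]] * 1e4 *
                                cond[["O3_g0"]] / 4),
                          y0[2],
                          rbind(rep(o3_scale, n), rep(cond[["OL_b0"]], n)))

  times <- c(0, exp(seq(log(cfg$t_min), log(cfg$t_max),
                        length.out = cfg$n_times)))
  # retry ladder: stiff corners of the parameter space (unresolved reaction
  # fronts, extreme desorption rates) occasionally defeat one solver setting
  attempts <- list(list(method = "lsoda", rtol = cfg$rel_tol, mul = 1),
                   list(method = "lsoda", rtol = 1e-4, mul = 100),
                   list(method = "bdf", rtol = cfg$rel_tol, mul = 1),
                   list(method = "bdf", rtol = 1e-4, mul = 100))
  out <- NULL
  for (a in attempts) {
    res <- try(suppressWarnings(
      deSolve::ode(y = y0, times = times, func = "kmsub_derivs",
                   parms = p, dllname = "kincompass",
                   initfunc = "kmsub_init", method = a$method,
                   jactype = "bandint", bandup = 2, banddown = 2,
                   rtol = a$rtol, atol = a$mul * atol, maxsteps = 50000)),
      silent = TRUE)
    if (is.matrix(res) && nrow(res) >= length(times) &&
        all(is.finite(res[, -1]))) {
      out <- res
      break
    }
  }
  if (is.null(out)) {
    stop("ODE solver failed for parameter set: ",
         paste(sprintf("%s=%.3g", names(params), params), collapse = ", "))
  }
  state <- out[seq_along(times), -1, drop = FALSE]
  if (any(!is.finite(state))) {
    stop("non-finite model state for parameter set: ",
         paste(sprintf("%s=%.3g", names(params), params), collapse = ", "))
  }
  list(times = times, state = state, n = n)
}

#' @rdname simulate_decay
#' @export
simulate_decay <- function(params, cond, cfg = model_config()) {
  sol <- km_solve(params, cond, cfg)
  n <- sol$n
  geom <- shell_geometry(cond[["r_p"]], n,
                         first_layer_thickness(cond[["r_p"]], cfg))
  ol_surf <- sol$state[, 2] * geom$area_surface
  ol_bulk <- sol$state[, 2 + 2 * seq_len(n), drop = FALSE] %*% geom$volume
  n_ol <- ol_surf + as.vector(ol_bulk)
  frac <- n_ol / n_ol[1]
  tibble::new_tibble(list(time_s = sol$times,
                          fraction_remaining = pmin(pmax(frac, 0), 1)),
                     class = "decay_curve")
}

#' Reaction-progress times of a decay curve
#'
#' Times at which the remaining fraction first crosses each of the nine
#' progress levels 0.9 ... 0.1, by linear interpolation in (log time,
#' fraction) between bracketing output points. Levels not reached within
#' `t_max` are `NA` (censored).
#'
#' @param curve a decay curve tibble (`time_s`, `fraction_remaining`)
#' @param t_max censoring horizon (s); defaults to the last curve time
#' @return Named numeric vector of length 9 (`t0.9` ... `t0.1`), seconds.
#' @export
progress_times <- function(curve, t_max = NULL) {
  tt <- curve$time_s
  ff <- curve$fraction_remaining
  if (is.null(t_max)) t_max <- tt[length(tt)]
  keep <- tt > 0 & tt <= t_max
  tt <- tt[keep]
  ff <- ff[keep]
  lt <- log(tt)
  qs <- progress_fractions()
  res <- rep(NA_real_, 9)
  for (j in seq_along(qs)) {
    q <- qs[j]
    i <- which(ff <= q)[1]
    if (is.na(i)) next
    if (i == 1) {
      res[j] <- tt[1]
    } else {
      w <- (ff[i - 1] - q) / (ff[i - 1] - ff[i])
      res[j] <- exp(lt[i - 1] + w * (lt[i] - lt[i - 1]))
    }
  }
  names(res) <- paste0("t", format(qs))
  res
}

#' Kinetic model as a nine-point evaluator
#'
#' Convenience wrapper: simulate and reduce to progress times. This is the
#' `KM` evaluator used for fit-ensemble acquisition and ensemble solutions.
#'
#' @inheritParams simulate_decay
#' @return Named numeric vector of nine progress times (s), `NA` = censored.
#' @export
km_progress <- function(params, cond, cfg = model_config()) {
  progress_times(simulate_decay(params, cond, cfg), t_max = cfg$t_max)
}

#' Analytic well-mixed reference model
#'
#' Two-state limit used as an independent oracle in tests: ozone instantly
#' equilibrated at its Henry value, a single well-mixed oleic acid pool, no
#' surface reaction. The decay is then exponential with pseudo-first-order
#' rate `k_BR * [O3]_eq`.
#'
#' @inheritParams simulate_decay
#' @return A decay curve tibble on the same time grid as [simulate_decay()].
#' @export
wellmixed_oracle <- function(params, cond, cfg = model_config()) {
  o3_eq <- henry_equilibrium(params, cond, cfg)
  # the surface monolayer holds a fraction of the oleic acid reservoir that
  # is exchanged with, but does not react in, the bulk; fold it into the
  # effective rate
  r <- cond[["r_p"]]
  f_bulk <- 1 / (1 + 3 * cfg$surface_layer_thickness / r)
  k <- params[["k_BR"]] * o3_eq * f_bulk
  times <- c(0, exp(seq(log(cfg$t_min), log(cfg$t_max),
                        length.out = cfg$n_times)))
  tibble::new_tibble(list(time_s = times,
                          fraction_remaining = exp(-k * times)),
                     class = "decay_curve")
}

#' Full state profiles of the multi-layer model
#'
#' Returns the raw layered solution, mainly for diagnostics and for testing
#' partitioning equilibria.
#'
#' @inheritParams simulate_decay
#' @return A list with `time_s`, `O3_surf` (cm-2), `OL_surf` (cm-2), and
#'   matrices `O3_bulk`, `OL_bulk` (times x layers, cm-3).
#' @export
simulate_profiles <- function(params, cond, cfg = model_config()) {
  sol <- km_solve(params, cond, cfg)
  n <- sol$n
  list(time_s = sol$times, O3_surf = sol$state[, 1],
       OL_surf = sol$state[, 2],
       O3_bulk = sol$state[, 1 + 2 * seq_len(n), drop = FALSE],
       OL_bulk = sol$state[, 2 + 2 * seq_len(n), drop = FALSE])
}
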