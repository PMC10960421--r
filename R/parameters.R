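#' Kinetic and experimental parameter bounds
#'
#' Default sampling bounds for the seven kinetic parameters of the multi-layer
#' ozonolysis model and accessibility bounds for the three experimental
#' parameters. Kinetic parameters span many decades and are handled on the
#' log10 scale throughout the package.
#'
#' Parameters (units):
#' * `k_SLR` surface reaction rate coefficient of OL + O3 (cm3 s-1; note the
#'   bimolecular surface flux `k_SLR * [O3]_s * [OL]_ss` with both reactants
#'   as area concentrations follows the surface-layer convention of
#'   multi-layer aerosol models)
#' * `k_BR` bulk reaction rate coefficient (cm3 s-1)
#' * `D_b_O3`, `D_b_OL` bulk diffusion coefficients (cm2 s-1)
#' * `H_cp_O3` Henry's law solubility of ozone (mol cm-3 atm-1)
#' * `tau_d_O3` ozone desorption lifetime (s)
#' * `alpha_s0_O3` surface accommodation coefficient on an adsorbate-free
#'   surface (dimensionless, at most 1)
#' * `r_p` particle radius (cm)
#' * `O3_g0` initial gas-phase ozone number concentration (cm-3)
#' * `OL_b0` initial bulk oleic acid number concentration (cm-3)
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`, `kind`
#'   (`"kinetic"` or `"experimental"`), `unit`.
#' @export
#' @examples
#' default_bounds()
default_bounds <- function() {
  tibble::tribble(
    ~parameter,     ~lower,   ~upper,  ~kind,          ~unit,
    "k_SLR",        1e-15,    1e-8,    "kinetic",      "cm3 s-1",
    "k_BR",         1e-20,    1e-11,   "kinetic",      "cm3 s-1",
    "D_b_O3",       1e-11,    1e-5,    "kinetic",      "cm2 s-1",
    "D_b_OL",       1e-12,    1e-6,    "kinetic",      "cm2 s-1",
    "H_cp_O3",      5e-6,     5e-3,    "kinetic",      "mol cm-3 atm-1",
    "tau_d_O3",     1e-9,     1e-2,    "kinetic",      "s",
    "alpha_s0_O3",  1e-4,     1,       "kinetic",      "1",
    "r_p",          2.5e-6,   1e-3,    "experimental", "cm",
    "O3_g0",        1e11,     1e15,    "experimental", "cm-3",
    "OL_b0",        1e19,     2e21,    "experimental", "cm-3"
  )
}

#' @rdname default_bounds
#' @export
kinetic_parameter_names <- function() {
  c("k_SLR", "k_BR", "D_b_O3", "D_b_OL", "H_cp_O3", "tau_d_O3", "alpha_s0_O3")
}

#' @rdname default_bounds
#' @export
experimental_parameter_names <- function() c("r_p", "O3_g0", "OL_b0")

#' Construct a kinetic parameter set
#'
#' @param k_SLR,k_BR,D_b_O3,D_b_OL,H_cp_O3,tau_d_O3,alpha_s0_O3 parameter
#'   values on the natural (linear) scale; see [default_bounds()] for units.
#' @param check if `TRUE`, values must lie inside [default_bounds()]. Tests of
#'   limiting cases may switch the check off (e.g. zero rate coefficients).
#' @return A named numeric vector of the seven kinetic parameters.
#' @export
kinetic_params <- function(k_SLR, k_BR, D_b_O3, D_b_OL, H_cp_O3, tau_d_O3,
                           alpha_s0_O3, check = TRUE) {
  p <- c(k_SLR = k_SLR, k_BR = k_BR, D_b_O3 = D_b_O3, D_b_OL = D_b_OL,
         H_cp_O3 = H_cp_O3, tau_d_O3 = tau_d_O3, alpha_s0_O3 = alpha_s0_O3)
  if (check) {
    validate_params(p, kind = "kinetic")
  }
  p
}

#' Construct experimental conditions
#'
#' @param r_p particle radius (cm)
#' @param O3_g0 initial gas-phase ozone number concentration (cm-3)
#' @param OL_b0 initial bulk oleic acid number concentration (cm-3)
#' @param check validate against [default_bounds()]
#' @return Named numeric vector `c(r_p, O3_g0, OL_b0)`.
#' @export
conditions <- function(r_p, O3_g0, OL_b0 = 1.9e21, check = TRUE) {
  cond <- c(r_p = r_p, O3_g0 = O3_g0, OL_b0 = OL_b0)
  if (check) validate_params(cond, kind = "experimental")
  cond
}

validate_params <- function(p, kind = c("kinetic", "experimental")) {
  kind <- match.arg(kind)
  b <- default_bounds()
  b <- b[b$kind == kind, ]
  missing <- setdiff(b$parameter, names(p))
  if (length(missing) > 0) {
    stop("missing ", kind, " parameter(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop(kind, " parameters must be finite and strictly positive")
  }
  for (i in seq_len(nrow(b))) {
    v <- p[[b$parameter[i]]]
    if (v < b$lower[i] || v > b$upper[i]) {
      stop(sprintf("%s = %g outside bounds [%g, %g]",
                   b$parameter[i], v, b$lower[i], b$upper[i]))
    }
  }
  invisible(p)
}

#' Sample parameter sets log-uniformly within bounds
#'
#' Draws each parameter independently and uniformly in log10 space between its
#' lower and upper bound — the prior used for rejection-sampling acquisition
#' of fit ensembles.
#'
#' @param n number of draws
#' @param bounds bounds tibble as from [default_bounds()]; rows restrict which
#'   parameters are drawn
#' @param kind draw `"kinetic"` parameters (default), `"experimental"`, or
#'   `"all"` ten
#' @return A tibble with one row per draw, columns on the linear scale.
#' @export
sample_params <- function(n, bounds = default_bounds(),
                          kind = c("kinetic", "experimental", "all")) {
  kind <- match.arg(kind)
  b <- if (kind == "all") bounds else bounds[bounds$kind == kind, ]
  draws <- lapply(seq_len(nrow(b)), function(i) {
    10^stats::runif(n, log10(b$lower[i]), log10(b$upper[i]))
  })
  names(draws) <- b$parameter
  tibble::as_tibble(draws)
}
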