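---
title: "The numerical compass: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The numerical compass: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the methods behind `kincompass`: the kinetic
model, the fit-ensemble representation of parameter uncertainty, the
constraint-potential metrics that rank candidate experiments, the
conventions the implementation commits to, and the open findings of the
bundled desk study.

## 1. The kinetic model

The forward model describes ozone uptake into a spherical oleic acid
particle as a multi-layer reactive-diffusion flux model:

* **Gas-surface exchange.** Ozone adsorbs onto the particle surface with
  a Langmuir-limited accommodation coefficient (`alpha_s0_O3` at zero
  coverage), and desorbs with lifetime `tau_d_O3`.
* **Surface chemistry.** Adsorbed ozone reacts with surface oleic acid at
  rate `k_SLR` (a surface-layer reaction, cm^2 s^-1).
* **Surface-bulk exchange and solubility.** Transfer between the sorption
  layer and the first bulk shell is parameterized so that, with reactions
  off, dissolved ozone relaxes to Henry's-law equilibrium
  `H_cp_O3 * R * T * [O3]_g`.
* **Bulk chemistry and diffusion.** Dissolved ozone reacts with bulk
  oleic acid at `k_BR` (cm^3 s^-1); both species diffuse between shells
  with diffusivities `D_b_O3` and `D_b_OL`.

The particle bulk is discretized into `n_layers` concentric shells.
Shell thicknesses follow a **graded (geometric) progression**: the
outermost shell is pinned near the scale on which the ozone reaction
front lives (default `min(surface_layer_thickness, 1e-4 * r_p)`, never
thicker than `r_p / n_layers`), and a bisection solves for the growth
factor that makes the remaining shells fill the radius exactly. A
micron-sized particle therefore resolves a nanometre-scale reaction front
near the surface without paying for equally fine shells at the core.
Doubling `n_layers` from 40 to 80 moves the decay half-time by less than
2 % (this is one of the suite's acceptance checks).

The right-hand side is compiled C; integration uses stiff solvers behind
a retry ladder (`lsoda`, then `lsoda` with relaxed tolerances, then
`bdf`), because extreme corners of the sampled parameter space —
unresolved reaction fronts, extreme desorption rates — occasionally
defeat a single solver configuration. Solves that fail the whole ladder
are censored, not fabricated.

Model limits are tested against closed forms: mass conservation with
reactions off; Henry equilibrium of the dissolved-ozone profile; and the
well-mixed analytic limit, where fast bulk diffusion and a bulk rate slow
enough that ozone stays at equilibrium make the decay exponential with
pseudo-first-order rate `k_BR * [O3]_eq`. The last limit only applies
when ozone resupply outruns consumption; the test probes it at small
radius and small `k_BR` and additionally checks that the model
*converges* to the limit as `k_BR` decreases.

## 2. Observables: nine-point progress times

Every solved decay curve is summarized by the times at which the
normalized oleic acid fraction first reaches 0.9, 0.8, ..., 0.1
(`progress_times()`). Experimental decay datasets are reduced to the same
nine numbers by interpolation (`observed_progress_times()`). Model-data
distance is the mean squared log error (MSLE) over the progress levels
both curves reach; a level the model never reaches within the time
horizon enters with the capped penalty `log(t_max / t_obs)^2`, so a model
that stalls cannot look better than one that merely runs slow.

## 3. Fit ensembles by rejection sampling

`acquire_fit_ensemble()` draws kinetic parameter sets log-uniformly from
broad literature-scale bounds and accepts every draw whose mean MSLE
against all datasets is below a threshold `theta` (approximate Bayesian
computation with a hard kernel). The accepted set — typically 100-1000
fits — *is* the uncertainty representation: every member reproduces the
data about as well as the measurement noise allows, and the scatter of
their predictions at untried conditions is the motor of everything below.

The threshold is not free. `calibrate_theta()` fixes it a priori as

```
theta = factor * (noise_msle + evaluator_msle),   floored at 0.0105
```

where `noise_msle` is the MSLE of the noise-free truth curve against the
noisy observations (the irreducible data-noise floor, computable for the
synthetic benchmark) and `evaluator_msle` is the held-out validation MSLE
of whatever evaluator does the scoring (zero for the kinetic model
itself; the surrogate's `val_msle` otherwise). The default safety factor
is 2. This emulates "threshold calibrated to measurement uncertainty"
without ever looking at acceptance outcomes.

## 4. Constraint-potential metrics

### Ensemble spread (ES)

For a candidate condition, every accepted fit predicts the nine progress
times. Plotting log10(time) against progress fraction gives a bundle of
monotone curves. With `Zbar` the mean curve and `sigma` the pointwise
population standard deviation (both piecewise linear in the progress
fraction), the spread is

```
ES = [ integral(Zbar + sigma) - integral(Zbar - sigma) ] / integral(Zbar)
   = 2 * integral(sigma) / integral(Zbar)
```

— the area of the +/-1 sigma band, normalized by the area under the mean
curve. Large ES means the ensemble *disagrees* about what would happen
there, i.e. measuring there would discriminate between fits. The test
suite checks `ensemble_spread()` against an independent
interpolate-and-integrate oracle to 1e-12.

### Parameter and target constraint potentials (PCP / TCP)

ES asks "where do predictions scatter?"; PCP asks "where would a
measurement actually *narrow a parameter*?". Each ensemble member in turn
plays the hypothetical experimental outcome at the candidate condition;
the members within `theta` of it form the surviving subset. PCP for a
parameter is the summed reduction of the subset's 5-95 % quantile range
relative to the full sampled range, accumulated over all hypothetical
outcomes. TCP is the mean reduction of ES *at a target condition* when
the subsets surviving the candidate condition are propagated there. Both
are validated against exhaustive double-loop oracles to 1e-12.

Members whose predictions are fully censored at the candidate condition
(no progress level reached within the horizon) are **skipped as
hypothetical outcomes** — a measurement that observes nothing constrains
nothing — and the number actually used is reported as an attribute.

## 5. Feasibility masking

A constraint map (`constraint_map()`) is only as useful as its cells are
measurable, and the ES normalization is only meaningful where the whole
log10-time curve is positive. A cell is **feasible** when

* the ensemble-median *onset* (time to reach 0.9) is at least the lower
  edge of the duration window (default 1 s): faster decays cannot be
  captured, and log-times below zero break the spread normalization;
* the ensemble-median *duration* (time to reach 0.1) is at most the upper
  edge (default 1e5 s, about a day of instrument time);
* at most a fraction `max_censored_frac` of members are censored there.

Infeasible cells keep their computed value but are masked from the
arg-max; `suggest_experiment()` returns the feasible arg-max cell, with
ties broken to the first cell in row-major grid order (so suggestions are
deterministic).

## 6. The surrogate

Grid-scale workloads (36-100 cells x hundreds of fits x iterations) and
rejection sampling (acceptance rates of order 1 %) need a fast forward
model. `train_surrogate()` fits a feed-forward network (10 log10 inputs:
7 kinetic parameters + radius, ozone, initial oleic acid; 4 hidden layers
of 128; 9 log10 progress-time outputs) to solved decays at log-uniform
parameter/condition draws. Fully censored draws are excluded and the
retention fraction recorded. At the shipped training size (5e4 draws) the
held-out median absolute log10 error is below 0.1 — smaller than typical
ensemble spreads — and `val_msle` feeds the threshold calibration above.

The surrogate enters three ways: as the acquisition evaluator, as the map
evaluator (`nc_es_sm`), or in a **hybrid** mode (`nc_es_hybrid`) where
the ensemble itself was acquired against the kinetic model but candidate
maps are surrogate-evaluated. Hybrid and kinetic-model ES maps agree to
Spearman rho > 0.99 on the benchmark ensemble.

## 7. The iterative design loop

`run_simulation_study()` plays the full campaign in silico. Every
accepted fit takes a turn as the simulated truth; per iteration the
selector picks a feasible cell, the truth's curve there becomes a new
dataset, and the **entire stored ensemble** is re-scored against all
accumulated data — fits rejected earlier can be revived, so the loop is a
filter on a fixed sample, not sequential attrition. Selectors:

* `nc_es_km` — arg-max of the kinetic-model ES map (the compass);
* `nc_es_hybrid`, `nc_es_sm` — surrogate-assisted variants;
* `sensitivity` — arg-max of total local sensitivity (mean
  |d log10 t / d log10 p| summed over parameters) at the current
  best-fitting member, a classical one-at-a-time baseline;
* `random` — uniform over feasible cells.

Two conventions keep the loop honest:

* **No repeats.** Within one truth's campaign a condition is never
  re-selected while unmeasured feasible cells remain (a noiseless repeat
  carries zero information and would let a selector idle).
* **Uninformative experiments are spent, not free.** If the simulated
  truth reaches no progress level at the chosen cell, the iteration
  counts but the filter is unchanged.

## 8. The committee-spread application

The spread idea transfers to any prediction committee.
`enumerate_substituted()` builds an exhaustive grid of hydroxyl/methyl
substitutions on 1,2-naphthoquinone (484 placement pairs; 283 valid
unique structures after clash and symmetry-duplicate removal via
canonicalization), and `spread_heatmap()` scores each novel structure
with the **non-normalized** spread `2 * sd` of the committee's
predictions — predictions on an interval scale (e.g. reduction
potentials) may be near zero, so dividing by the mean would be
meaningless. High-spread molecules are where the committee disagrees,
i.e. the most informative next measurements or training labels
(`rank_training_candidates()`).

## 9. Open findings and limitations

The acceptance suite leaves two empirical requirements red on purpose;
both are reproducible findings about the system, not implementation
defects, and the test comments carry the analysis:

* **Sensitivity-guided selection does not beat random** on the benchmark
  (the compass beats both decisively, p ~ 1e-16). The total-sensitivity
  map varies by barely 10 % across the grid and peaks at small particles
  / low ozone, where decays are slow and member curves nearly coincide —
  local derivatives at a single best fit simply do not see where the
  *ensemble* disagrees. This is, in effect, the motivating observation
  for ensemble-based design.
* **ES-map ranks agree only moderately with a brute-force
  median-rejection map** (Spearman rho ~ 0.5-0.65 across the feasible
  cells), although the two agree on the arg-max cell, as do the PCP and
  hybrid maps. The driver is the `1 / integral(Zbar)` normalization:
  with a threshold calibrated for a surrogate-assisted pipeline the
  ensemble is wide, `integral(Zbar)` varies several-fold across the
  grid, and rank order away from the extremes is reshuffled.

Further limitations worth knowing:

* the model is seeded with oleic acid ozonolysis scales; other systems
  need new bounds and possibly new processes (e.g. secondary chemistry,
  evaporation);
* the hard-kernel rejection sampler is embarrassingly simple and pays
  for it in acceptance rate; at kinetic-model cost it is only practical
  behind the surrogate;
* feasibility is a box on onset/duration/censoring — real instruments
  have richer constraints (concentration floors, radius-dependent signal
  quality) that would slot into `feasibility_constraints()`;
* suggestions are greedy one-step arg-maxes; batch or horizon-aware
  designs are out of scope.

## Session

```{r, eval = TRUE}
packageVersion("kincompass")
```
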