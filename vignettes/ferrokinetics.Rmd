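---
title: "Whole-body ferrokinetics: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body ferrokinetics: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrokin)
```

## The model

Iron metabolism in the adult mouse can be treated, over a one-month
experiment, as a quasi-closed steady-state flux network. Bulk ("cold")
iron fluxes `v_ij` between organ pools `C_j` are invisible, but a trace
dose of radioiron injected into plasma distributes in proportion to
them. Writing fractional clearance coefficients `k_ij = v_ij / C_j`
(the fraction of the source pool cleared along an edge per day), the
tracer content `x_i` (% of injected dose) of every compartment follows
a linear constant-coefficient system

$$\frac{dx_i}{dt} = \sum_j k_{ij} x_j - \sum_j k_{ji} x_i - k_{oi} x_i,$$

with boundary condition `x_plasma(0) = 100`, all other compartments 0.

The topology (`build_topology()`) is mammillary with structure imposed
by erythropoietic physiology:

* 13 edges plasma → organ (transferrin-receptor uptake); the spleen has
  **no** direct plasma edge — it is fed through the erythron;
* 10 reflux edges organ → plasma (ferroportin export / RES recycling);
* 3 body-loss edges (stomach, intestine, integument → external sink),
  representing epithelial exfoliation and desquamation;
* the irreversible erythron chain bone marrow → erythrocytes →
  spleen/RES, plus a direct marrow → spleen edge (murine splenic
  erythropoiesis and ineffective erythropoiesis).

Compartments with physiologically double exits (reflux *and* loss) are
modelled with the single dominant route decided a priori: intestine and
integument lose, erythrocytes/liver/kidney reflux. The estimator never
frees both exits of one compartment simultaneously — the
identifiability scan (below) demonstrates why.

Units are fixed throughout: time in days, tracer in % of injected dose,
rates in 1/day, iron masses in µg per 25-g mouse. The plasma and
extravascular-fluid pools equilibrate within an hour and are merged
into one central compartment; no tracer data resolve them separately.

## Solving the system

`simulate_tracer()` evaluates the exact solution
`x(t) = e^{At} x(0)` on the requested grid. The system is stiff in the
mild sense that rates span 0.02–20/day, which makes explicit
integration wasteful but poses no difficulty for the matrix
exponential. An eigendecomposition fast path is used when the
reconstructed `V Λ V⁻¹` matches `A` to 1e-8 (the generic case);
otherwise the solver falls back to `Matrix::expm()` stepping interval
by interval. An explicit fixed-step RK4 integrator exists **only** in
the test suite, as an independent oracle; the two agree to better than
1e-4 % dose over 28 days.

The external sink is not a state of the rate matrix: cumulative loss is
computed by mass balance, `100 − Σ_i x_i(t)`, which also provides the
conservation invariant checked by the tests (tolerance 1e-6).

## Data processing

Raw organ concentrations (µg/g or % dose per g) are scaled to whole
organs with the exact product-rule SD
`sqrt(f²s² + w²h² + h²s²)` (`scale_to_body()`); intestinal subsections
are averaged unweighted into one intestine compartment, with variance
divided by K² (`combine_intestinal_segments()`) — the source protocol
gives no segment weights, so an unweighted mean is the only defensible
choice. Negative means produced by residual-blood over-correction
(iron-deficient spleen) are clipped to zero and recorded.

Because the injected dose varies slightly between animals, each
timepoint is rescaled by a common factor so the whole-body total equals
`100·exp(−λt)` with λ = 0.005/day (`normalize_to_decaying_total()`).
That λ encodes the slow physiological iron loss of the mouse — about
13% per month, a whole-body residence time of 200 days. A lower
literature estimate (0.004/day) exists, so λ is a parameter, not a
constant. Normalization is idempotent and requires full organ coverage
per timepoint.

## Estimation

`fit_rates()` minimizes the weighted criterion

$$\mathrm{fval} = \sum_m \frac{(\hat x_m - \bar x_m)^2}{\mathrm{SD}_m},$$

i.e. weights are the **inverse SD**, not the inverse variance — the
variance weighting (available as `weighting = "var"` for sensitivity
studies) overemphasizes low concentrations, uniform weighting high
ones. The reported `fit_quality` is `sqrt(fval / N)`. SDs below 1% of
an organ's maximum mean are floored to that value; without a floor,
noise-free cells would carry infinite weight. The source material does
not print the exact algebra behind its criterion values, so those
numbers are not reproduction targets; the definitions here are the
plain reading of the described procedure.

The total plasma clearance (20/day) is not identifiable from data whose
first observation is at 12 h — plasma is cleared within ~1 h — so it is
fixed: the 13 plasma-exit rates are parameterized as a softmax simplex
scaled to the set value, making the constraint exact at every iterate
(to 1e-9 in the tests). All other rates are optimized in log space.

The optimizer is multi-start L-BFGS-B followed by a Levenberg–Marquardt
polish of the weighted residuals (quadratic convergence near the
optimum of a near-zero-residual problem). One start is deterministic
and data-informed: plasma shares are read off the first-timepoint organ
contents (distribution is complete well before 12 h) and each organ's
exit rate from the steepest post-peak log-slope of its curve. The late
tail of every organ decays with the *system's* slowest eigenvalue, so a
tail-slope estimate would badly underestimate fast exits — a lesson
that is baked into the heuristic. On noise-free daily-grid data this
start recovers all 29 generating constants to numerical precision; on
30%-CV data it reliably reaches the global basin where purely random
starts often stall in local minima.

## Uncertainty and identifiability

`resample_fit()` draws per-cell Gaussian datasets preserving each
cell's mean and SD (negatives clipped at zero, mirroring the spleen
handling), refits each, and `parameter_bounds()` reports the 1/6 and
5/6 empirical quantiles (type-7, linear interpolation) of the replicate
estimates. For Gaussian scatter this sextile interval is
`(z_{5/6} − z_{1/6})σ ≈ 1.93σ`, i.e. approximately ±1 SD. Replicate
fits start from the point estimate — the replicates perturb the data,
not the basin — which keeps 200 replicates affordable; the test suite
scales the count down and says so.

`identifiability_scan()` is a deliberately simplified surrogate for
ACE-style exploration of the acceptable-fit domain: many seeded
single-start fits, retention of all fits within a factor (default 1.05)
of the best criterion, then per-parameter spread and pairwise
correlations across that set. A pair is flagged when |correlation| >
0.9 **and** both parameters have relative spread above 1% — the second
condition prevents flagging correlations of pure numerical noise when
every accepted fit is essentially identical. The tests exercise the
mechanism on tiny purpose-built topologies (a freed double exit; a free
total clearance with late-only data), where the ridges are provable,
rather than on the full 29-parameter model, which would not fit a test
budget.

## Derived physiology

From a fitted rate vector the package computes, per diet:

* residence times `Θ_i = 1/(Σ_j k_ji + k_oi)` — compartments without
  exit are reported as `Inf` and flagged;
* plasma turnover shares `k_{p→i} / Σ k_{p→j}`;
* absolute fluxes `v_i = k_{p→i} · C_plasma/ECF`, with the marrow
  outflux split `kbon_rbc : kbon_spl` between the erythrocyte and
  splenic routes;
* tracer-accessible pool sizes `C_i = influx_i · Θ_i`, with the
  erythron chain using its chain influx. The duodenum is excluded by
  construction: its unmeasured cold dietary influx breaks the tracer
  balance, so the calculation is refused rather than silently wrong.

The default plasma/ECF pools (1.13 / 1.50 / 2.02 µg for
deficient/adequate/loaded) are back-solved from the published absolute
marrow influxes (15; 19; 14 µg/day) and the corresponding plasma→marrow
clearances; they are documented as derived stand-ins for the direct
plasma-iron measurements and are overridable everywhere.

## The synthetic-data generator

`generate_dataset()` emulates the experimental design: sacrifice
timepoints {0.5, 1, 2, 3, 7, 14, 21, 28} days (the published design
gives the 12-h start and 28-day end; the interior grid is a declared
stand-in, configurable), 5 animals per point (allowed 3–7), and
multiplicative measurement noise with CV 0.30. The noise is lognormal
by default — only the CV is stated in the source material, and a
positive-support noise matches tracer-count data; a truncated-Gaussian
switch exists and reproduces the clip-at-zero behaviour. A 5%
per-timepoint dose jitter emulates the injection variability that
motivates the whole-body normalization.

What a green test establishes: the estimation machinery recovers known
parameters under the *stated* statistical structure (design, CV,
normalization). What it does not establish: robustness to residual-blood
correction errors, organ-weight uncertainty, inter-animal kinetic
heterogeneity, or model misspecification (sub-compartments of liver,
spleen and muscle are known simplifications) — none of which the
generator emulates.

## Numerical choices and limitations

* Matrix-exponential solve on the output grid; eigen fast path guarded
  by reconstruction error < 1e-8, `Matrix::expm` fallback.
* Tiny negative contents from rounding (> −1e-9) are snapped to zero.
* log-rate bounds [1e-5, 1e3]/day in the optimizer; softmax weights
  clamped to ±25 (±30 inside the LM polish) against overflow.
* Quantile convention: R type 7 (linear interpolation), stated because
  sextile bounds of small ensembles depend on it.
* Seeds: every stochastic routine takes an integer seed and derives
  per-replicate/per-start streams below 2³¹; identical inputs give
  identical results.
* The two anomalous loaded-diet upper limits shipped with the package
  (ktes_p 7.16, kp_tes 2.68, both ≫ best fit) are stored verbatim and
  flagged by `diet_parameters()`, not corrected.
* Out of scope by design: nonlinear/regulated kinetics (hepcidin,
  receptor saturation), sub-compartmentalization of mixed organs,
  residual-blood correction of raw counts (inputs are assumed
  pre-corrected), and Laplace-domain identifiability algebra.

## A minimal session

```{r example, eval = FALSE}
rates <- diet_parameters("adequate")$best_fit
g <- generate_dataset(rates, study_design(seed = 1))
fit <- fit_rates(g$dataset, n_starts = 2, seed = 1)
ens <- resample_fit(g$dataset, n_replicates = 50, seed = 1)
write_fit_csv(fit, "fit.csv", bounds = parameter_bounds(ens))
derived_report(fit$rates, plasma_pool("adequate"))
```
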