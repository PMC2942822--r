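# ferrokin

Whole-body ferrokinetic compartment modelling of iron metabolism in the
mouse.

## The problem

Iron homeostasis in the adult mouse is a steady-state flux network: a
tiny transferrin-bound plasma pool (1–2 µg per 25-g animal) turns over
about 20 times per day, feeding the erythropoietic bone marrow, the
parenchymal organs and the slow storage pools, while exfoliation of
intestinal epithelium and desquamation of skin drain a small fraction of
body iron per day. Injecting a trace dose of radioiron into plasma and
following its appearance in dissected organs over 28 days makes these
invisible fluxes measurable without disturbing the steady state.

`ferrokin` is for researchers who run (or re-analyse) such dietary
tracer studies. It implements:

* a **16-compartment linear clearance model** (plasma/EVF central pool,
  mammillary exchange with the periphery, an irreversible erythron chain
  bone marrow → erythrocytes → spleen/RES, and body-loss exits from
  stomach, intestine and integument), solved exactly by matrix
  exponentials: `dx/dt = A x`, where `A` is built from 29 fractional
  clearance constants `k` (1/day),
* **weighted least-squares estimation** of the 29 constants from organ
  time-courses, with weights `1/SD` and the total plasma clearance fixed
  at `Σ k_plasma→organ = 20/day` (enforced exactly via a simplex
  parameterization),
* **Monte-Carlo resampling** scatter intervals (1/6–5/6 sextile bounds
  of replicate estimates ≈ ±1 SD for Gaussian scatter),
* a **multi-start identifiability scan** flagging parameter pairs that
  only their sum or ratio identifies,
* **derived physiology**: residence times `Θ_i = 1/(Σ_j k_ji + k_oi)`,
  plasma turnover shares, absolute fluxes `v_i = k_i · C_plasma/ECF`,
  and tracer-accessible pool sizes `C_i = influx_i · Θ_i`,
* a **synthetic-data generator** emulating the experimental design
  (8 timepoints between 12 h and 28 days, 3–7 animals per point, ~30%
  coefficient of variation, whole-body normalization to
  `100·exp(−0.005 t)`),
* a **CLI** (`simulate`, `synth`, `fit`, `resample`, `derive`, `report`,
  `export-sbml`) writing CSV/JSON/SBML artifacts stamped with seed and
  config hash.

The best-fit clearance constants for iron-deficient, iron-adequate and
iron-loaded diets ship with the package
(`inst/extdata/table1_parameters.csv`).

## Worked example

```r
library(ferrokin)

topo  <- build_topology()
rates <- diet_parameters("adequate")$best_fit

# where does plasma iron go?
round(100 * plasma_shares(rates), 1)
#>  bone_marrow  kidney  intestine  liver  stomach  integument  fat
#>         63.3     2.2        4.5   13.1      0.6         5.7  0.2
#>  muscle  lungs  duodenum  brain  heart  testes
#>     7.4    1.6       0.2    0.1    0.7     0.3

# how long does an iron atom stay, once delivered?
round(residence_times(rates), 2)
#> plasma: 0.05   bone_marrow: 0.85   rbc: 16.67   spleen: 0.14
#> liver: 7.14    kidney: 5.00        intestine: 2.78
#> integument: 25.00  brain: 16.67  ... (days)

# absolute fluxes for the adequate diet (plasma pool 1.50 ug)
fl <- absolute_fluxes(rates, plasma_pool("adequate"))
round(fl$plasma_influx[["bone_marrow"]], 1)   # 19.0 ug/day into marrow
round(fl$erythron[["rbc_to_spleen"]], 1)      # 17.4 ug/day through RBC

# simulate and check conservation
tr <- simulate_tracer(topo, rates, times = c(0.5, 1, 2, 3, 7, 14, 21, 28))
max(abs(colSums(tr$content) + tr$external_loss - 100))  # 0 (by balance)
```

The numbers mean: an iron-adequate mouse routes 63% of its plasma iron
turnover (19 of 30 µg/day) into red cell production; iron passes the
marrow in under a day but sits in circulating erythrocytes for ~17 days;
intestinal epithelium clears its iron at 36%/day, consistent with
epithelial exfoliation every few days.

End-to-end on synthetic data:

```r
g   <- generate_dataset(rates, study_design(seed = 1))
fit <- fit_rates(g$dataset, n_starts = 2, seed = 1)
ens <- resample_fit(g$dataset, n_replicates = 50, seed = 1)
parameter_bounds(ens)
```

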