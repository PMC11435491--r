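# skinpod

Quantitative skin-sensitization potency prediction from GARDskin
Dose-Response assay readouts.

## The problem

Risk assessment of skin sensitizers needs a quantitative point of departure
(PoD): a dose per skin area (ug/cm2) below which induction of sensitization
is not expected. The reference sources are in vivo — the murine LLNA, whose
EC3 converts to a NESIL by `NESIL = EC3 x 250`, and human repeat-insult
patch-test NOELs. The GARDskin Dose-Response assay offers a non-animal
alternative: a genomic classifier scores a chemical at several
concentrations with a decision value (DV, where DV >= 0 calls a sensitizer),
and the lowest concentration reaching DV = 0 — the **cDV0** (ug/mL) — acts
as an in vitro dose-response PoD.

`skinpod` implements the full pipeline from decision values to NESIL
predictions, for toxicologists and method developers working on
new-approach-methodology (NAM) potency assessment:

- **cDV0 estimation** — per-concentration mean DVs, lowest
  negative-to-non-negative crossing, linear (or log-axis) interpolation;
  replicate runs merged by geometric mean.
- **Composite potency scale** — both in vivo references are treated as noisy
  observations of one latent potency. A Passing-Bablok errors-in-variables
  line is fitted between log10 human NOEL (x) and log10 LLNA NESIL (y), each
  chemical is projected orthogonally onto it, and its along-line position
  (rescaled by `1/sqrt(1+a^2)` to original log10 dose units, shifted so the
  scale agrees with the projections on average) is exponentiated into a
  composite potency value (cPV, ug/cm2 or umol/cm2).
- **Potency model** — Huber-robust (IRLS, `k = 1.345`, MAD scale) or OLS
  regression of log10 cPV on log10 cDV0. The slope sits near 1 and AIC
  prefers fixing it there, so the selected model is a single intercept:
  `predicted NESIL [ug/cm2] = cDV0 [ug/mL] x 304` (mass basis) or
  `predicted NESIL [umol/cm2] = cDV0 [uM] x 0.301` (molar basis).
- **Evaluation** — absolute geometric mean fold change
  `exp(mean |ln(pred/ref)|)`, repeated k-fold cross-validation, Wilcoxon
  paired error comparison, and 3-fold/5-fold categorisation.
- **Synthetic data** — generators for reference tables and dose-response
  curves with the latent structure the method assumes, used for
  parameter-recovery tests.

The package is tidyverse-native: functions take data frames, return tibbles,
fitted objects support `tidy()`/`glance()` and `autoplot()`. A 30-chemical
reference dataset (`chemical_dataset()`) is bundled.

## Worked example

```r
library(skinpod)

chem <- chemical_dataset()          # 30 chemicals, 25 with both references

# composite potency scale (mass basis)
scale <- build_composite_scale(chem)
scale
#> Composite potency scale (mass basis, ug/cm2)
#>   PB line: y = 0.9576 x + 0.1833  (n = 25 complete chemicals)
#>   shift: 0.9911
#>   composite values: 25 defined, range 9.8 - 2.14e+04 ug/cm2

# intercept-only robust potency model on the complete chemicals
train <- tidy(scale) |>
  dplyr::left_join(chem[, c("name", "cdv0")], by = "name") |>
  dplyr::filter(complete)
model <- fit_potency_model(train, cdv0, cpv, family = "huber", basis = "mass")
model
#> Potency model (Huber robust, intercept only, mass basis)
#>   intercept: 2.4823  [2.2953, 2.6692]
#>   slope:     1.0000 (fixed)
#>   n = 25, residual scale = 0.4263
#>   multiplier: predicted potency = cDV0 x 303.6

predict(model, cdv0 = 1.11)         # citral's merged cDV0, in ug/mL
#> [1] 336.9564   # predicted NESIL in ug/cm2

# how good are the predictions?
cv <- repeated_cv(chem, repeats = 50, folds = 10, seed = 1)
cv
#> Repeated cross-validation: 50 repeats x 10 folds (huber, intercept only, mass, n = 30)
#>   fold-change error vs LLNA NESIL: 2.761
#>   fold-change error vs human NOEL: 3.221
```

A cross-validated error of 2.76 fold changes means held-out NESIL
predictions differ from the LLNA-derived values by a factor of about 2.8 in
geometric mean — comparable to the 2.63-fold disagreement between the LLNA
and human references themselves, which is the natural floor on this dataset.

The methods vignette (`vignettes/potency-pipeline.Rmd`) documents the model,
its conventions (interpolation axis, Passing-Bablok median and tie handling,
Huber scale, CV rosters) and the synthetic-data generator.

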