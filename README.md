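# glycomediate

Causal mediation analysis of postprandial glucose from meal-centered
continuous glucose monitoring (CGM) windows.

In type 1 diabetes, meal carbohydrates `Z` (grams) raise glucose directly
and, at the same time, trigger a bolus insulin dose `M` (units) that lowers
it. Treating insulin as a confounder mixes these two channels; treating it
as a **mediator** separates them. For the excursion
`dG(t) = G(t) - G(0)` at horizons `t = 60, 90, ..., 210` minutes post-meal,
the package estimates, per meal type, dose contrast and outcome quantile:

- **ACME** — the average causal mediation effect through insulin,
  `E[Y(z1, M(z1)) - Y(z1, M(z0))]` (averaged over both treatment anchors),
- **ADE** — the average direct effect, `E[Y(z1, M(z0)) - Y(z0, M(z0))]`,
- **TE = ACME + ADE** — the total effect of shifting carbohydrates from the
  meal-type median `z0` to `z0 + {15, 30, 45}` g.

The pipeline: meal-centered windowing with imputation and exclusion rules →
a causally-constrained convolutional autoencoder that turns the two-hour
pre-meal multichannel trajectory into an 8-d pre-treatment embedding
(multi-head reconstruction plus balancing, linearizability,
conditional-independence and stability penalties) → PCA → entropy-balancing
weights for the continuous treatment (the convex analogue of npCBPS) → a
left-censored Tobit mediator model and mixed-effects / quantile-regression
outcome models → quasi-Bayesian Monte Carlo decomposition (1000 draws, 95%
percentile intervals). Because the real study data of this kind sits behind
data-use agreements, the package includes a synthetic cohort generator with
the same statistical structure and a brute-force potential-outcome oracle,
so every stage is testable against known ground truth.

Intended users: biostatisticians and quantitative diabetes researchers who
want a reproducible, fully seeded reference implementation of this
mediation workflow, or a harness for methods work on confounder
representation learning and continuous-treatment balancing.

## Worked example

```r
library(glycomediate)

cfg <- pipeline_config(
  generator = generator_config(n_subjects = 10, days_per_subject = 28, seed = 11),
  encoder   = clae_config(epochs = 40),
  strata    = "pooled", models = c("mixed", "q50"),
  n_sims    = 500, seed = 11)
res <- run_pipeline(cfg)
res
#> pipeline_result: 799/904 windows kept; n_eff 244.2; 108 mediation rows
res$weights
#> weight_set: n = 256, n_eff = 244.2 (95.4%)
#> mean |corr(Z, X)|: 0.0832 -> 0.0000 (100.0% reduction)
#> weights: median 0.995, IQR [0.90, 1.08], 0.4% > 2.0
report_summary(res$mediation, horizon = 120, dose = 30)
#>   stratum model tau       ade ade_p      acme acme_p    total total_p significant
#> 1  pooled mixed  NA 12.329926 0.002 -7.517987  0.002 4.811939   0.002        TRUE
#> 2  pooled   q50 0.5  8.730434 0.012 -3.136147  0.252 5.594287   0.002        TRUE
```

Reading the mixed-model row: at 120 minutes, an extra 30 g of carbohydrate
above the meal-type median raises glucose by ~12.3 mg/dL directly (ADE),
while the induced extra bolus pulls it down by ~7.5 mg/dL (ACME), leaving a
net excursion of ~4.8 mg/dL (TE). The generator's simulation oracle for
this cohort configuration is ACME -10.7, ADE 14.7, TE 4.0 mg/dL
(`oracle_effects(cfg$generator, dose = 30)`); the mild attenuation of the
two channels reflects the part of the latent confounding the pre-meal
window does not reveal — see the methods vignette
(`vignettes/methods.Rmd`) for that analysis.

Individual stages are exported if you want them separately:
`generate_cohort()`, `impute_gaps()`, `build_windows()`,
`split_and_standardize()`, `clae_train()`, `clae_encode()`, `fit_pca()`,
`estimate_weights()`, `fit_tobit()`, `fit_outcome_mixed()`,
`fit_outcome_quantile()`, `mediate_decompose()`, `run_stratified()`,
`plot_effects()`.

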