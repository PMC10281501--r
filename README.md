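# aeroscope

Thermal-physiology analysis for interpopulation fish experiments: from raw
intermittent-flow respirometry traces to Bayesian thermal-performance trait
models, thermal optima and environment–phenotype association screens.

## The scientific problem

Conservation of cold-water fishes such as Pacific salmon increasingly
depends on knowing **which populations are adapted to which conditions**. A
standard common-garden design rears juveniles from several populations at
multiple acclimation temperatures and measures a panel of physiological
traits — growth rate, critical thermal maximum (CT~max~), routine and
maximum metabolic rate (RMR, MMR) and aerobic scope (AS = MMR − RMR) — then
asks whether trait variation tracks characteristics of each population's
home habitat (stream temperatures, migration distance, latitude).

`aeroscope` implements that entire analysis chain as a tested R package:

1. **Respirometry processing.** Oxygen saturation traces are converted to
   concentration, `[O2] = %sat/100 · α(O2) · BP`, and each sealed
   measurement period is regressed over time; the slope *R*
   (mgO₂ L⁻¹ s⁻¹) becomes a mass-specific metabolic rate
   `MO2 = |R| · V · M⁻¹ · 60` (mgO₂ kg⁻¹ min⁻¹). RMR is the mean of the
   three lowest per-period rates (activity-flagged periods removed), MMR
   the steepest ≥ 5-min window during swimming, found by an exhaustive
   sliding-window scan. QC rules — 80% saturation floor, r² linearity
   threshold, mortality and activity exclusions — are applied
   programmatically with a full exclusion log.
2. **Bayesian trait models.** Each trait is a Gaussian mixed model on
   z-scored data with weakly regularizing priors: growth is linear in
   scaled time at treatment level, CT~max~ has mass and age covariates, RMR
   is exponential in test temperature (log response), MMR is linear in
   log₂ temperature and AS is a second-order polynomial of test
   temperature, all with the population × acclimation interaction. A
   collapsed Gibbs sampler (scale parameters slice-sampled against the
   analytically marginalized likelihood; coefficients drawn exactly)
   yields ≥ 2000 posterior draws with enforced split-Rhat < 1.01. Stepwise
   WAIC selection, posterior treatment means, pairwise contrasts and
   acclimation capacities (20 °C − 11 °C) follow, with the posterior-mass
   significance rule (strong ≥ 94.5%, weak ≥ 85%).
3. **Thermal optimum.** T~opt~ is the temperature maximizing AS: posterior
   draws of the AS curve are simulated over the tested range, a quadratic
   is refit to each and its vertex −b/(2a) collected; estimates outside
   8–26 °C are flagged as extrapolations.
4. **Environmental association screen.** 15 habitat predictors × 5 traits
   = 75 single-predictor mixed models (population as random intercept;
   predictor × test-temperature interactions for the metabolic traits)
   yield 495 classified association cells, with leave-one-population-out
   robustness for growth and a predictor correlation report.
5. **Synthetic data.** A generator with known ground truth emulates the
   full study design — 6 populations × 3 acclimation temperatures, biweekly
   growth sampling, 0.33 °C/min CT~max~ ramps, saturation traces built by
   inverting the respirometry equations — so every stage is testable
   without the raw field data.

## Worked example

```r
library(aeroscope)

truth <- synthetic_truth()          # ground truth emulating the study magnitudes
config <- cohort_config(resp_n = 36)

# 1. Simulate respirometry fish and fit the aerobic-scope model
metabolic <- generate_metabolic_data(truth, config, seed = 1)
d <- prepare_metabolic_data(metabolic)
fit <- fit_trait_model(d, default_trait_specs()$as, seed = 1)
glance(fit)
#> # A tibble: 1 × 9
#>   trait n_obs n_draws  waic  lppd p_waic sigma rhat_max converged
#>   <chr> <int>   <int> <dbl> <dbl>  <dbl> <dbl>    <dbl> <lgl>
#> 1 as      648    2000  364. -129.   53.2 0.307     1.00 TRUE

# 2. Thermal optimum per treatment from 500 posterior draws
topt <- estimate_topt(fit, n_draws = 500, seed = 2)
head(dplyr::select(topt, -draws), 3)
#> # A tibble: 3 × 7
#>   population acclim topt_C  sd_C extrapolated concave_frac n_draws_used
#>   <chr>      <chr>   <dbl> <dbl> <lgl>               <dbl>        <int>
#> 1 Coleman    11       17.9 0.230 FALSE                   1          500
#> 2 Coleman    16       20.8 0.640 FALSE                   1          500
#> 3 Coleman    20       23.5 1.25  FALSE                   1          500

# 3. Warm-minus-cold shift in the optimum for one population
delta_topt(topt, "Coleman")
#> # A tibble: 1 × 4
#>   population delta_topt_C  sd_C paired
#>   <chr>             <dbl> <dbl> <lgl>
#> 1 Coleman            5.63  1.26 TRUE
```

The fitted optimum rises with acclimation temperature (17.9 → 23.5 °C for
this population), and the warm-minus-cold shift of 5.6 ± 1.3 °C is the
population's acclimation response of its thermal optimum. `glance()` shows
the fit converged (split-Rhat ≈ 1.00) with 2000 retained posterior draws;
`n_draws_used` confirms all 500 simulated curves were concave, so the
vertex is a genuine optimum rather than an extrapolation.

`run_pipeline(pipeline_config(seed = 1))` chains the stages (simulation →
respirometry → trait fits → optima → optional environmental screen) and
`render_report()` assembles the treatment-mean, contrast, T~opt~ and
association-grid tables.

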