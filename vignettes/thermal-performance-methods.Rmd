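---
title: "Methods: from oxygen traces to thermal optima and environmental associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from oxygen traces to thermal optima and environmental associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeroscope)
```

`aeroscope` analyzes common-garden thermal-physiology experiments on fish
populations. This vignette documents the models, the numerical choices
behind them, and what the synthetic-data generator does and does not
emulate, so results can be interpreted with the right caveats.

## Respirometry

Intermittent-flow respirometry alternates sealed measurement periods with
flush periods. Within a sealed period, percent air saturation is converted
to concentration,

$$[O_2] = \frac{\%O_2sat}{100}\,\alpha(O_2)\,BP,$$

with $\alpha(O_2)$ the temperature-corrected solubility coefficient
(mgO₂ L⁻¹ mmHg⁻¹; `o2_solubility()` provides a Benson–Krause freshwater
fit) and $BP$ barometric pressure (mmHg). The least-squares slope $R$ of
concentration on time (mgO₂ L⁻¹ s⁻¹) gives the mass-specific rate

$$\dot{M}O_2 = |R| \cdot V \cdot M^{-1} \cdot 60 \quad
  (\mathrm{mgO_2\,kg^{-1}\,min^{-1}}),$$

with $V$ the respirometer volume (L) and $M$ fish mass (kg). Slopes are
stored **signed** so anomalous oxygen-gain periods remain visible to QC;
only the conversion to a rate takes the magnitude. No allometric mass
exponent is applied because the design holds fish size nearly constant
within trials.

Decisions a user can tune:

* **Linearity filter** (`r2_threshold`, default 0.90). Trace inspection is
  replaced by a programmatic r² threshold; sealed periods below it are
  dropped before any rate is selected. Clean traces regress with r² well
  above 0.97, so 0.90 is permissive yet protective. A zero-variance trace
  reports r² = 0, never `NaN`, so it fails the filter deterministically.
* **RMR** is the mean of the three lowest per-period rates after removing
  activity-flagged periods; ties are broken by earliest period start so
  selection is deterministic. Fish with fewer than three usable periods
  are excluded with a reason code. All retained sealed routine periods are
  eligible, irrespective of clock time — the overnight protocol makes a
  time-of-day restriction redundant.
* **MMR** is the maximum over *every* contiguous sub-window of at least
  `min_window_s` (default 300 s) within sealed swim periods, with the
  slope refit by least squares per window at a one-sample scan step.
  Prefix-sum identities make the exhaustive scan O(n²) with O(1) work per
  window, and a brute-force oracle in the test suite confirms exactness.
* **Saturation floor** (default 80%). A fish whose used periods let
  saturation fall below the floor is excluded; the boundary is closed
  (exactly 80% passes).
* Aerobic scope is always `mmr - rmr`; a negative value is returned with a
  warning rather than clipped, because silent clipping would hide a
  protocol failure.

On units: the conversion above yields per-minute rates, and the package
standardizes on mgO₂ kg⁻¹ min⁻¹ throughout. Published tables in this
literature occasionally label equally sized numbers as per-hour; treat
magnitudes, not unit strings, as the comparable quantity.

## Trait models

Each trait is a Gaussian linear mixed model fitted to z-scored responses
with z-scored covariates (mass, condition factor, test temperature) and
0–1 scaled time and age. The families, chosen to match each trait's
thermal shape, are encoded in `default_trait_specs()`:

| trait   | response            | temperature form            | report |
|---------|---------------------|-----------------------------|--------|
| growth  | mass (g)            | linear in scaled time       | g/day at treatment level |
| ctmax   | LOE temperature (°C)| —                           | cell mean |
| rmr     | log RMR             | linear (exponential curve)  | cell mean, back-transformed |
| mmr     | MMR                 | log₂(test temperature)      | cell mean |
| as      | aerobic scope       | quadratic                   | cell mean |

Every spec carries the population × acclimation interaction. Priors are
weakly regularizing and configurable (`prior_settings()`): standard normal
on coefficients of the standardized design, half-normal(0, 1) on the
residual and random-intercept scales — the natural scale-free choice once
everything is z-scored.

**Sampler.** The posterior is explored by a collapsed Gibbs sampler
(`gibbs.R`): the scale parameters are slice-sampled on the log scale
against the *marginal* posterior with all coefficients integrated out
analytically (the Gaussian linear-model evidence), and the coefficient
vector is then drawn exactly from its multivariate-normal full
conditional. Marginalization matters: a centered sampler funnels when a
variance component approaches zero — precisely the regime of a
population random intercept over six populations — whereas the collapsed
chain mixes freely there. Each marginal evaluation costs one Cholesky of
the (p+q)-dimensional posterior precision built from precomputed
cross-products, so chain cost does not grow with the number of
observations. Defaults retain 2000 draws (2 chains × 1000 after 500
warmup); split-Rhat is computed for every scalar parameter and a fit
failing the 1.01 threshold errors — or, inside the screen, is flagged and
its cells reported as unavailable. One test cross-checks the sampler
against JAGS on an identical model, and another against the conjugate
normal closed form.

**WAIC and selection.** `compute_waic()` uses the pointwise formula with
log-sum-exp stabilization; pointwise log-likelihoods are stored on the
z-scale, whose Jacobian is constant across candidate models for the same
response, so comparisons are valid. `stepwise_select()` does greedy
forward addition then a single backward pass over the spec's candidate
terms, recording every tried model in an auditable ledger. Simulation puts
the long-run rejection rate of a pure-noise candidate near 80%, which is
the expected behaviour of WAIC-style criteria rather than a defect.

**Means, contrasts, capacities.** `treatment_means()` evaluates the fixed
linear predictor per draw on a reference grid — z-scored covariates at
zero (their training mean), time/age at the cell-specific mean, random
intercepts at zero — and back-transforms to the natural scale
(exponentiating for log responses). Growth is reported as a treatment-level
daily rate derived from the time slope, never per fish, because fish are
not individually marked under repeated cross-sectional sampling. Contrasts
difference cells draw-by-draw; the significance rule is the posterior-mass
classification with **closed** thresholds: strong when ≥ 94.5% of the
difference's mass lies on one side of zero, weak when ≥ 85%.

## Thermal optimum

`estimate_topt()` takes the aerobic-scope fit, samples 500 posterior draws
(without replacement; configurable), predicts the AS curve on a fixed
0.5 °C grid over 8–26 °C, refits a quadratic to each simulated curve and
records the vertex $-b/2a$. Refitting on a grid rather than reading
coefficients mirrors how simulated-dataset optima are computed in this
literature; for an exactly quadratic model the two agree exactly, which
the single-draw reduction test verifies. Non-concave draws are dropped and
counted; more than 50% non-concave draws is an estimation failure, never a
silent `NaN`. A mean vertex outside the tested range is flagged
`extrapolated` — such optima (monotone curves within range) should be
quoted with that caveat. `delta_topt()` differences the warm and cold
acclimation groups, pairing draws by index when both cells come from the
same posterior subsample and otherwise combining SDs independently; both
modes exist because pairing is a modelling choice, not an identity.

## Environmental associations

`build_env_spec()` constructs one model per trait × predictor: the
standardized predictor (`env_z`, z-scored across populations) replaces any
geography term, source population enters as a random intercept, the
predictor interacts with acclimation temperature for every trait and
additionally with the linear test-temperature term for the metabolic
traits. The reported estimand per cell is the posterior of the +1 SD
predictor effect on the standardized response — for growth, the effect on
the *growth rate* (a difference-in-differences across the time axis); for
metabolic traits, evaluated at test temperatures 11/16/20 °C. This is the
marginal-slope reading of "effect at a test temperature", stated here
because the estimand is otherwise underdetermined.

With six populations, a population-level predictor and a population
random intercept are weakly identified. Three consequences are built in:
priors and convergence thresholds are surfaced in configuration; the
screen refuses to classify cells from non-converged fits (class
`unavailable`); and growth associations are only trusted when direction
and class survive leaving out the outlying slow-growing population
(`trinity_robustness()`), otherwise they are demoted to "none". Null
calibration by simulation (uniform truth, randomized predictor tables)
shows the strong-class rate at or below the nominal two-sided 11% tail
mass; the default random intercept is what keeps that rate honest. By
default the screen uses only the population intercept as a random term;
assay-structure terms (CT~max~ chamber, swim tunnel) can be appended via
`extra_random` where the design warrants them.

## The synthetic-data generator

`synthetic_truth()` + the `generate_*()` functions emulate the full study
design: 6 populations × 3 acclimation temperatures (18 treatments, two
tanks each), 30 growth measurements per treatment per biweekly date,
~20 CT~max~ fish and ~36 respirometry fish per treatment spread over test
temperatures 8–26 °C, a 30-min hold then a 0.33 °C/min CT~max~ ramp logged
every 5 min, and saturation traces produced by inverting the respirometry
equations so a zero-noise trace round-trips exactly. Default trait
magnitudes are seeded from published treatment-level summaries
(`published_table()`), so simulated figures are visually comparable to the
study's; they are an emulation, not data. Two generator defaults deserve
justification:

* **AS curvature** (−0.025 mgO₂ kg⁻¹ min⁻¹ °C⁻²). Chosen so the
  aerobic-scope quadratic stays well above zero at the cold end of the
  tested range for every treatment, matching the shape of published
  thermal performance curves; steeper curvature would clip against the
  positivity floor and distort the quadratic family the models assume.
* **Sensor noise** (0.05% saturation). Set so per-period regression r²
  lands in the high 0.98–0.99 range reported for well-behaved systems.

Noise is Gaussian on saturation, Gaussian on log mass (so growth data are
mildly heteroscedastic relative to the Gaussian trait model — a deliberate,
realistic misspecification) and Gaussian on loss-of-equilibrium
temperature. The bundled environmental table carries the real latitude,
migration distance and migration slope per population (migration slope is
hatchery elevation divided by migration distance, m/km); the twelve
stream-temperature metrics are synthetic emulations constrained to
plausible magnitudes and internal consistency (ranges equal max − min),
because per-kilometre stream-temperature summaries are not published at
that granularity. Files and documentation label them synthetic.

What passing tests do **not** show about real data: the generator has no
probe drift, no tank effects unless requested, no hatchery-practice
confounds, no non-quadratic performance curves and no missingness
mechanism beyond the modelled exclusions. Recovery and calibration results
certify the *procedure*, not any field conclusion.

On T~opt~ recovery specifically: at study-scale noise the posterior SD of a
cell's optimum is roughly 0.3–1.2 °C (edge-of-range cells higher), and
round-trip errors are consistent with those SDs — the estimator is
calibrated, not super-efficient. The round-trip test therefore checks that
the *cell-averaged* recovery error stays within 0.5 °C and that per-cell
errors are within posterior uncertainty, rather than demanding each noisy
cell land within half a degree.

## Problem sizes in the test suite

The suite runs every stage at reduced but structurally faithful sizes
chosen to keep the full run in the minutes range on a single core: model
fits use 2 chains × 1000 retained draws; recovery experiments use three
populations with 8–12 fish per treatment and 50 replicates per model
family; screen calibration uses 20 null replicates (60 cells) and 5
injected replicates. Statistical assertions are placed two Monte-Carlo
standard errors from their simulated long-run rates so they test
properties, not individual draws.

## Known limitations

* Gaussian responses only — the five families above; no Sharpe–Schoolfield
  or other mechanistic TPC shapes.
* Random effects are intercepts only; random slopes would need a different
  coefficient prior structure.
* The screen's per-cell classifications are not multiplicity-adjusted, by
  design — the posterior-mass rule is reported as-is.
* Stream-temperature modelling, GIS extraction of migration routes and
  historical-vs-current habitat regression are out of scope; environmental
  predictors are treated as given inputs.
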