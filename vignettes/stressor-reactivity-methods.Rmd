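---
title: "Quantifying stress resilience as residualized stressor reactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress resilience as residualized stressor reactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resil)
```

## The model

Resilience is not low symptom load: a person may be symptom-free simply
because little has happened to them. `resil` therefore operationalizes
resilience as *residualized stressor reactivity* (SR). Let $E_{it}$ be an
aggregate stressor-exposure score and $P_{it}$ an internalizing-symptom sum
score for participant $i$ at monitoring $t$. The sample's *normative* E–P
relation is a regression line

$$P = \beta_0 + \beta_1 E + \varepsilon,$$

and a participant's SR score over an outcome interval is the residual of
their interval-average symptom score from that line at their
interval-average exposure:

$$\mathrm{SR}_i = \bar P_i - (\hat\beta_0 + \hat\beta_1 \bar E_i).$$

Negative SR means fewer symptoms than exposure-peers (more resilient),
positive SR more. Because the line is estimated once on a fixed baseline
window and then applied to any interval, SR scores from different intervals
are on the same symptom-unit scale and comparable across exposure levels.

Two dialects of both the exposure score and the normative line are
implemented, corresponding to the two study designs the package emulates:

* **Observational monitoring dialect** (`freshmo_exposure()`,
  `fit_normative_ols()`): $E$ is the mean of the z-scored life-event count
  and daily-hassle day-sum; severity ratings are collected but deliberately
  excluded, so that $E$ measures exposure rather than burden appraisal. The
  line is ordinary least squares on per-participant averages of the first
  three post-baseline monitorings, frozen thereafter.
* **Trial dialect** (`respond_exposure()`, `fit_normative_lmm()`): $E$ is a
  dichotomized life-event sum (3 items, occurred/not) plus a hassle
  frequency sum (15 items rated 0–3), bounded by $3 + 45 = 48$. The line is
  a linear mixed model of $P$ on $E$ over all participants and time points
  with a participant-level random intercept and slope.

### Why SR uses the fixed-effects line in the mixed-model dialect

Per-row SR in the trial dialect is defined as the residual to the
*population* (fixed-effects) line, not to subject-specific conditional
predictions. Conditional residuals would absorb exactly the stable
between-person deviation that SR is meant to quantify — a persistently
over-reactive participant would have their reactivity soaked up by their
random intercept and appear average. If the random-slope variance is
estimated as singular (as it is when no slope heterogeneity exists), the
model falls back to a random intercept only and says so.

### Linearity and variance explained

`quadratic_check()` compares the linear model against the same model plus
$E^2$ with a 1-df likelihood-ratio test. Maximum likelihood (never REML) is
used for both fits, because likelihood ratios on fixed effects are only
valid under ML. `variance_explained()` reports the mixed-model
decomposition: marginal $R^2 = \sigma^2_f / (\sigma^2_f + \sigma^2_r +
\sigma^2_e)$ (fixed effects only) and conditional $R^2$ additionally
crediting the random effects; the random-slope contribution uses the mean
row-wise $z_i^\top \Sigma z_i$, so it is exact for models with correlated
intercepts and slopes.

## Prediction models

`select_covariates()` implements the screening rule used throughout: age
and gender always enter; any other baseline candidate is kept iff its
univariate regression on the longest-interval SR score has $p < 0.2$.
`fit_sr_regression()` then fits OLS on complete cases with all continuous
variables z-scored, so coefficients are standardized betas; binary 0/1
covariates are left unscaled so their coefficient is a group contrast in
standardized-outcome units. `high_exposure_subset()` selects the top two
terciles of mean exposure, with ties at the cut included — "top two
terciles" is read as a floor, and inclusion is the conservative choice for
a resilience subsample. No multiple-comparison adjustment is applied across
the predictor-by-interval grid, matching the descriptive use of these
models.

## Mediation

Two inferential routes are provided, matching their use cases:

1. **Bootstrap product of coefficients** (`bootstrap_indirect()`) for
   observational chains: $a$ from $M \sim X$, $b$ and $c'$ from
   $Y \sim X + M$, indirect effect $ab$, inferred by nonparametric
   case-resampling (rows, not residuals) with percentile intervals. The
   reported point estimate is the mean over resamples. 5000 resamples by
   default. The OLS identity $c = c' + ab$ holds exactly for identical
   covariate sets and is asserted in the tests at $10^{-10}$.
2. **Counterfactual natural effects** (`counterfactual_effects()`,
   `pool_and_ci()`) for the trial: mediator model $M \sim A + C$ and
   outcome model $Y \sim A + M\,(+A{\times}M) + C$; the four
   potential-outcome means $E[Y(a, M(a^*))]$ are produced by counterfactual
   imputation — predict $M(0)$ and $M(1)$ per subject, plug into the outcome
   model, average — and the contrasts give the total effect
   $te = E[Y(1,M(1))]-E[Y(0,M(0))]$, the *pure* natural indirect effect
   $nie = E[Y(0,M(1))]-E[Y(0,M(0))]$ and the *total* natural direct effect
   $nde = E[Y(1,M(1))]-E[Y(0,M(1))]$, with $pm = nie/te$. The pure-indirect
   / total-direct pairing is the default (the direct effect absorbs any
   exposure–mediator interaction); the other pairing is available, and both
   telescope to $te = nde + nie$ exactly, which the tests assert at
   $10^{-8}$ per completed dataset.

Counterfactual mediator values are by default simulated from the fitted
mediator model with normal errors (`mediator_draws` shared across the four
contrast cells, so the decomposition remains exact); `mediator_draws = 0`
switches to the deterministic model-mean plug-in, which is equivalent in
expectation for outcome models linear in $M$ and is what the linear
analyses use. The outcome is min–max scaled to 0–100 before estimation
(constants frozen from the analysis sample) so effects read as
points-of-range differences.

Missing mediator, outcome or covariate values are handled by
`impute_missing()`: chained-equation stochastic regression imputation with
normal linear models, 5 completed datasets by default (a configuration
knob, since published analyses of this design have used both 5 and 10).
Effects are estimated per completed dataset and pooled by averaging;
bootstrap intervals re-impute inside every resample, so imputation
uncertainty propagates into the CIs.

### Monte-Carlo power

`monte_carlo_power()` follows the Monte-Carlo confidence-interval method
for indirect effects: simulate a trivariate sample from the standardized
path model, estimate $(\hat a, \hat b)$ and their standard errors, draw a
large number of $(a^*, b^*)$ pairs from the estimated sampling
distributions, and check whether the percentile interval of $a^* b^*$
excludes zero; power is the significant fraction over repetitions (defaults
1000 repetitions, 20000 draws). The sample-size search walks a grid in
steps of 10 and reports the first size meeting the target, which keeps the
answer reproducible at the granularity such power tables are printed.

### A note on null calibration

The percentile bootstrap of $ab$ attains its nominal ~5% type-I rate at the
*half-null* (one path zero, the other not); this is verified by a property
test. At the *joint* null ($a = b = 0$) the product statistic is extremely
conservative — rejection rates near zero, a well-documented property of
product-of-coefficients tests — and the suite measures exactly that
behavior. Claims that the interval "excludes zero in about 5% of null
runs" are therefore only true, and only tested as true, for the half-null
regime.

## The synthetic cohorts

`generate_observational()` and `generate_rct()` are first-class, tested
generators whose defaults *are* the study conditions the analyses assume;
they are not tuning knobs.

**Observational cohort** (defaults): 1000 participants — the scale of the
replication cohort, large enough that planted standardized effects carry
small standard errors — monitored at 13 three-monthly time points T0..T12
(T0 is the acquaintance monitoring and excluded from analysis), with
battery waves B0/B1/B2 at T0/T6/T12 spanning ~3 years. A standardized
latent chain

$$S \rightarrow \mathrm{PAS} \rightarrow \{\mathrm{recovery},\; r_i\}$$

plants: social support→PAS $a_1 = 0.5$; PAS→recovery $a_2 = 0.5$; direct
PAS→reactivity $g_1 = -0.2$ and recovery→reactivity $g_2 = -0.2$, so the
total standardized PAS→reactivity path is $g_1 + g_2 a_2 = -0.3$ — the
magnitude of the published standardized PAS coefficient for the longest
interval. The person reactivity offset $r_i$ (SD 4 symptom units) enters
$P$ additively, i.e. random-intercept-style; slope heterogeneity is off by
default (the mixed model's singular-slope fallback is exercised
deliberately) and can be switched on for stress tests. Stressor items are
27 life-event Poisson counts (rates decaying from 0.5 per window, the
printed top-item frequency) and 58 daily-hassle binomial day-counts over 7
days (day probabilities from 0.64 ≈ 4.5/7 downwards, matching the printed
top hassles); a person-level log-rate shift (SD 0.4) creates the
between-person exposure differences the normative regression needs.
Severity ratings are generated and summarized but never enter $E$. The
symptom line uses $P = 17 + 4E + r_i + \varepsilon$, $\varepsilon \sim
N(0, 6^2)$ — a GHQ-scale baseline near the printed cohort means. 10% of
monitorings are skipped at random, which the interval minimum-monitoring
filters (4 for B0–B2, 3 for B0–B1/B1–B2, 2 for 9-month windows) absorb.

**Trial cohort** (defaults): 232 participants, exact 1:1 allocation, four
assessments. PAS (12–48 scale, baseline mean 33, SD 6) is flat in control
and gains 1 point per step under intervention; SR at time $t$ is driven by
PAS at $t-1$ with $b = -0.5$ SR units per PAS point plus a direct
intervention effect of $-0.5$ per step, so the planted T3 decomposition is
$nie = -1.0$, $nde = -1.5$, $pm = 0.4$ — inside the 0.32–0.47 band of the
published proportions mediated. $P = 8 + 0.9E + \mathrm{SR}$ ties the
symptom score to a dichotomized-sum exposure with mean ≈ 13.5 of 48, and
20% of post-baseline values are MCAR-missing, leaving roughly the
complete-case fraction the published trial analysis had.

**What the generators do not emulate:** item-level measurement error in the
battery scores (scores are linear transforms of the latents, so planted
standardized paths are exact at the score scale; a `wave_reliability` knob
adds occasion noise when test-retest behavior itself is under study),
informative missingness, time-varying reactivity, floor/ceiling effects in
the symptom scales, and pandemic-style exposure waves. Passing recovery
tests on these cohorts therefore shows the estimators are correct under
the assumed data-generating model — not that real data meet those
assumptions.

## Numerical choices and degenerate inputs

* z-scores use sample (n−1) SDs; a zero-SD component standardizes to 0
  with a warning rather than NaN.
* Standardization constants for exposure and the 0–100 outcome scaling are
  frozen from their estimation windows and reusable via explicit arguments.
* The tercile cut uses the default sample-quantile definition; ties at the
  cut are included.
* Bootstrap resamples with a degenerate design (constant predictor or
  mediator, or a single trial arm) are redrawn.
* Reported mixed models use REML; ML is used only inside likelihood-ratio
  tests. Wald intervals are reported for mixed-model fixed effects,
  Satterthwaite p-values via `lmerTest`.
* Two-occasion reliability uses the consistency ICC from the two-way ANOVA
  decomposition, chosen because it satisfies $ICC = (F-1)/(F+1)$, the
  relation the published reliability pairs obey. Identical occasions give
  ICC 1; zero between-subject variance gives ICC 0 with a warning.
* Any missing item makes an instrument score missing — no proration — and
  reverse-key sets default to empty, since none of the scored instruments
  document reverse keys; both are configurable per `instrument_spec()`.
* All stochastic operations are pure functions of (data, parameters,
  seed); the pipeline writes outputs atomically with a checksummed
  manifest.

## Problem sizes used by the test suite

The suite validates calibration claims at sizes chosen to keep Monte-Carlo
error well inside the asserted bands: 200–300 replications for bootstrap
type-I behavior, 1000 repetitions for the power bounds, 200 trial
replications for the mediated-proportion recovery, and single cohorts at
the default scales for parameter recovery (each within 3 estimated
standard errors). These are the package's own verification sizes; larger
runs sharpen the same estimates without changing any conclusion.

## Known limitations

Only regression-based natural-effect estimation is implemented
(weight-based estimation is a sensitivity variant left out of scope);
controlled direct effects, multilevel 1-1-1 mediation, multiple mediators,
and sensitivity analysis for unmeasured confounding are not provided.
McDonald's ω is not computed (it needs a factor model; α and the ICC cover
the reliability surface here). The chained-equation imputer assumes
approximately linear-Gaussian conditionals and imputes numeric columns
only. Nonlinear or spline normative curves and time-varying reactivity are
out of scope by design.
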