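---
title: "Methods: normative analysis and listener simulation for the SR2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative analysis and listener simulation for the SR2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sr2norm)
```

## The measurement and its scoring

The SR2 is a rapid headphone test of spatial release from masking (SRM).
Three simultaneous sentences from a closed-set corpus ("Ready, CALLSIGN, go
to COLOR, NUMBER, now") are presented in two spatial configurations:
*colocated* (target and both maskers at 0°) and *separated* (maskers at
±45°). A run is a fixed progressive track of 20 trials, two at each
target-to-masker ratio (TMR) from +10 dB down to −8 dB in 2-dB steps. A
trial is correct only when both the reported color and number match the
target. The threshold estimate is simply

$$\widehat{\theta} = 10 - \#\text{correct},$$

an integer in [−10, +10] dB TMR that depends only on the count of correct
responses. SRM is the colocated threshold minus the separated threshold;
positive SRM means spatial separation helps. The estimator cannot report
below −10 dB, so very good listeners pile up at the floor, and prior
psychometric analysis of the procedure puts its accurate range at roughly
±6 dB with underestimation beyond it. We score, but never "correct", this
floor.

## Normative regression

For each condition (colocated, separated, SRM) and run label (run 1, run 2,
average of both), performance is regressed on age (years) and bilateral
standard pure-tone average (PTA; mean of 0.5/1/2/4 kHz across both ears, dB
HL):

$$\text{predicted} = \beta_0 + \beta_{\text{age}}\,\text{age} +
\beta_{\text{PTA}}\,\text{PTA}.$$

Fitting starts from age + PTA + age×PTA. The interaction is tested first
and removed when non-significant (it never survives in practice); main
effects are then removed one at a time, largest *p* first, refitting after
each removal, until every surviving term has *p* < α (default .05). The
exact elimination sequence is not dictated by the published analysis; we
use this conventional backward pass because it reproduces the published
inclusion pattern (colocated: age only; separated: age and PTA; SRM: PTA
only) and is deterministic. A non-finite *p* (zero-residual fits) counts as
non-significant. If nothing survives, an intercept-only model is returned
with a warning.

The **model error** is the average magnitude of observed-minus-predicted
values on the final fit. The published description ("the difference between
the predicted and the observed value ... the average value") is ambiguous
between RMSE and MAE; because the Z-transform treats it as a standard
deviation, the default is RMSE, with MAE available via `error_method`.
Individual performance is then normed as

$$Z = \frac{\text{observed} - \text{predicted}}{\text{model error}},$$

with |Z| ≥ 2 (two-sided, boundary inclusive) flagging performance abnormal
for that age and hearing level — two-sided because both remarkably good and
remarkably poor performance are of interest. Predictions outside age 18–80
or PTA 0–45 dB HL are computed but labelled extrapolations.

The correlation screen (`correlation_table()`) reports Pearson correlations
of the run-averaged outcomes with age, bilateral SRT, standard PTA and
high-frequency PTA, plus each hearing measure against age — 15 correlations
with the full predictor set — and applies a Bonferroni criterion of
.05/15 = .0033. The rounded criterion is sometimes quoted as corresponding
to |r| ≥ .333 at n = 82; the exact t-based critical value is ≈ .32, so the
table carries the exact `critical_r` attribute rather than hard-coding the
rounded figure. Retest-delay correlations with run-difference scores are
reported when a delay column is present but never enter the models (the
published effect sizes are ≤ 0.03 dB/week).

`sr2_norms()` ships the published coefficient set (n = 82, ages 18–80, PTA
0–45 dB HL) so single patients can be normed without refitting anything.

## The listener simulator

`simulate_cohort()` generates cohorts on which the entire pipeline can be
validated by parameter recovery. Its defaults are the study conditions:

* **Demographics.** Age and PTA are drawn through a Gaussian copula.
  Marginals are truncated normals on [18, 80] years and [0, 45] dB HL whose
  underlying parameters are moment-matched numerically so the *truncated*
  distributions hit the cohort summary statistics (age mean 46.74, SD
  18.66; PTA mean 12.48, SD 8.89); the latent copula correlation is solved
  by quadrature so the realized Pearson r(age, PTA) ≈ .51. One feasibility
  note: no truncated normal on [18, 80] can exceed the uniform-limit SD of
  ≈17.9 years, so the age SD lands there rather than at the published 18.66
  — the published SD is an empirical summary, not exactly realizable by
  this family. `age_dist = "uniform"` is available for design-style
  recovery studies.
* **Audiograms.** A flat-plus-sloping bilateral profile (flat through
  1 kHz, 60% of the PTA per octave above) is scaled so the standard PTA
  equals the sampled value; only the PTA feeds the models, so the spectral
  shape is cosmetic but satisfies all audiogram invariants. Per-ear SRTs
  track the PTA with 2 dB of jitter; gender, hearing-aid use and
  retest-delay categories are sampled with the study frequencies (delay has
  no generative effect).
* **Latent thresholds.** Each listener's baseline in each condition is the
  generative normative prediction (defaults: the published average-run
  functions) plus a persistent deviation u ~ N(0, σ), with σ defaulting to
  that function's model error (1.045 dB colocated, 1.864 dB separated).
  Run-specific thresholds are prediction + ρ·u + √(1−ρ²)·e_run with fresh
  e_run ~ N(0, σ) and ρ = 0.8 by default (the published work establishes
  good test–retest reliability but prints no coefficient; ρ is a config
  parameter, not a claim). Run 2 adds the published practice improvements:
  −0.7 dB colocated, −1.4 dB separated, applied to the latent listener, not
  to the scoring rule.
* **Trials.** Responses are Bernoulli draws from a logistic psychometric
  function with guessing floor 1/32 (4 colors × 8 numbers, lapse-free) and
  slope 2 dB — a plausible, explicitly unvalidated default chosen to give
  realistic between-run variability.

### Why the psychometric midpoint is calibrated

The track's expected score is $E[\widehat\theta] = 10 - 2\sum_t p(t)$ over
the ten schedule levels. If the logistic *midpoint* is placed at the latent
threshold θ, this expectation sits about 1.0–1.6 dB below θ across the
valid range: the schedule is centered at +1 dB, the sigmoid half-credits
its midpoint level, and guessing adds −10·chance. The normative functions,
however, live on the *score* scale — they were fit to progressive-track
scores — and the procedure is documented as mean-accurate within ±6 dB. So
by default (`calibrate = TRUE`) the simulator places each listener's
psychometric midpoint by a deterministic root solve (vectorized bisection)
so that the expected track score equals the latent threshold exactly;
thresholds beyond the attainable expectation range pin to the walls, which
reproduces the −10 dB floor. `calibrate = FALSE` gives the literal
midpoint-at-θ listener (useful for step-function reasoning: a noiseless
listener with θ = 1 scores 0).

### What the simulator does and does not emulate

Recovered coefficients from *direct* normative draws
(`draw_normative_outcome()`: prediction + Normal noise) are unbiased, and
that is the generative process used for parameter-recovery validation. The
*full* pipeline additionally censors scores at −10 dB, which visibly
flattens refit separated and SRM slopes at default settings — exactly the
floor the original procedure has, but doubled up here because the
generative coefficients already come from floor-affected data. Whole-
pipeline checks therefore assert the inclusion/sign pattern rather than
coefficient equality. The simulator also does not model talker confusions,
informational-masking structure, asymmetric-hearing effects on SRM, lapses,
or any acoustic rendering; passing tests say the *analysis* recovers what
the *generator* put in, not that the generator is a complete model of real
listeners.

## Numerical choices and degenerate inputs

* OLS is delegated to `stats::lm` behind `ols_fit()`; tests hold it to an
  explicit normal-equation solve at 1e−8. p-values use t with n − p − 1 df;
  adjusted R² is 1 − (1−R²)(n−1)/(n−p−1). Rank-deficient designs error.
* Model JSON is written with 17 significant digits so coefficients
  round-trip bit-identically; cohort CSVs round-trip exactly via shortest-
  representation floats. Missing optional fields are empty cells, surfaced
  as `NA`, never zero.
* Stored PTA/asymmetry columns are always recomputed from the audiogram; a
  stored PTA disagreeing by > 0.05 dB warns (stored values may be rounded;
  derived values must be reproducible).
* Validation is total: every malformed row yields a localized diagnostic
  (row, column, message) and nothing is silently dropped. Single-condition
  thresholds must be integers in [−10, 10]; SRM, being a difference of two
  scores, is bounded at [−20, 20].
* Printed tables round to 2–3 decimals, half away from zero in spirit of
  the published formatting; all underlying artifacts keep full precision.

## Problem sizes used in validation

The packaged checks use: the full 21-case enumeration of the scoring rule;
n = 2000 cohorts for coefficient recovery (three generative truths, each
accepted within 3 Monte-Carlo SEs); 200 replicate cohorts at n = 82 for
unbiasedness and 95%-CI coverage; n = 10 000 draws for demographic moment
recovery; and 6000 simulated tracks per latent threshold on the ±6 dB grid
for mean-calibration of the track estimator (±0.2 dB). These sizes give
Monte-Carlo standard errors several times smaller than the tolerances they
are tested against.

## Known limitations

The norms are linear and were fit on 0–45 dB HL PTAs with few participants
above 20 dB HL; predictions beyond age 18–80 or PTA 0–45 are extrapolations
and tagged as such. Nonlinear or hierarchical norms, quantile regression,
and age-binned lookup tables are out of scope. The psychometric slope and
between-run persistence defaults are plausible but unvalidated; both are
exposed in `sim_config()`.
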