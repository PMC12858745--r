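---
title: "Methods: ear-piece dosimetry, outcome models and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ear-piece dosimetry, outcome models and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earnoise)
```

This vignette is the package's own account of its science: the exposure
model and its assumptions, the outcome models, the simulator, the
synthetic-cohort generator, and the numerical and design choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The exposure model

### Calibration curve

A volume-control setting (percent of maximum) is mapped to an output
level (dBA) through a `calibration_curve`: a set of strictly increasing
anchors interpolated with a monotone Fritsch–Carlson piecewise-cubic
Hermite spline. Monotone shape preservation matters for two reasons: the
device relation between volume and level is mildly nonlinear, and the
curve must be invertible (the energy-weighted average volume setting is
defined through the inverse map). Inversion uses a grid-initialised,
safeguarded Newton iteration on the spline, converged to a residual
below 1e-10 dB, so a level→volume→level round trip is accurate to well
under 1e-6 dB; tests also cross-check the inverse against plain
bisection.

The shipped default anchors — 0%→58, 25%→76, 50%→85, 75%→93,
100%→100 dBA — are **fixture values**: the top anchor reflects the
~100 dBA maximum output reported for TETRA ear-pieces, and the rest give
a realistic, mildly compressive curve. The measured fleet-average curve
for a specific device population should replace them via
`read_calibration()`; everything downstream is curve-agnostic.

### Energy accumulation

Wearing time is converted to noise-exposure time with a duty cycle of
0.2, reflecting the fraction of time a police radio channel actually
carries speech (reported channel-activity estimates range roughly
15–30%; 0.2 is a deliberately conservative single value). Each
sub-exposure of `h` hours at level `L` contributes
`h · 10^((L−85)/10) / 1880` exposure units, where one unit is one
working year (47 weeks × 40 h) of constant 85 dBA exposure — 85 dBA
being the UK Upper Exposure Action Value. Energy is additive, so the
engine is validated against a brute-force oracle that chops every
exposure into ≤1 h chunks and sums them directly (agreement to 1e-9
relative over 1,000 random careers), plus the two structural identities:
+10·log₁₀(2) ≈ 3.0103 dB at fixed duration doubles the energy, and
doubling duration at fixed level doubles the energy.

Weekly-averaged level and the energy-weighted volume average are pure
functions of the accumulated energy:

* `device_weekly_level(E, W) = 85 + 10·log₁₀(E·1880/(40·W))`, with
  `W = Σ years × 47` unless reported weeks are supplied. It depends only
  on total energy and weeks, not on how hours were distributed — a
  property tested explicitly.
* `device_volume_average` converts the within-exposure average level
  back to a volume setting. Because the average is energy-weighted it is
  never below the duration-weighted mean setting.

Zero-exposure careers have energy 0 and *missing* (never −Inf) level
metrics. All levels are carried at full float precision; rounding is a
display concern only.

## 2. Derived outcome variables

* **Shift estimate.** Careers report hours/week, not shifts; shifts are
  estimated as `years × 47 × min(hours_per_week / 8, 5)` (8-h shifts,
  at most 5 per week — a standard full-time policing pattern; both
  configurable), rounded half away from zero after summing segments.
* **TTS instances.** The five-option TTS-frequency response is mapped to
  a proportion of shifts — Never 0, Sometimes 0.25, About half the time
  0.5, Most of the time 0.75, Every time 1 — interior values being
  midpoints of their plain-language intervals (endpoints are forced by
  the wording). Only the group boundaries (0 / 1–100 / >100) enter the
  registered models, so sensitivity to the interior multipliers is
  limited; they are overridable.
* **Side imputation.** Nonusers receive an exposed-ear side only for the
  between-ear speech analysis: a seeded permutation assigns exactly
  `round(0.57·n)` of them "right" (the proportion observed in unilateral
  users), the rest "left". Users' reported sides are never altered.
* **Ear-wise reshape.** For the laterality analysis each eligible
  participant (unilateral user, asymmetric tinnitus) becomes two rows —
  one ear each — with exactly one exposed and exactly one
  tinnitus-present row per pair.
* **DIN quality control.** Per-condition means and SDs are computed once
  over all complete three-threshold records; a participant is dropped if
  any threshold lies strictly outside mean ± 3 SD. The rule is
  single-pass (one reported exclusion count, no iteration) and
  participant-level: one aberrant ear removes all three thresholds.
  Whether a pooled or per-condition rule was used in the original
  platform is not documented; per-condition was chosen as the more
  conservative reading.

## 3. The registered analyses

RQ1/RQ2 are descriptive. RQ2's response-option table carries
**Sison–Glaz simultaneous confidence intervals**, implemented from the
truncated-Poisson/Edgeworth construction (no installed R package
provides them); the implementation is pinned against an independent
reference implementation in the test suite, and its simultaneous
coverage is verified by simulation (k = 5 equally likely categories,
n = 500, 10,000 draws — coverage must be ≥94% at nominal 95%).

RQ3 is a proportional-odds model of TTS frequency on the volume average
(single slope; the proportional-odds assumption is adopted without a
formal test, matching the single-slope reporting convention). Empty
response levels are dropped; sparse levels warn; suspected separation is
flagged and profile-likelihood CIs replace Wald CIs.

RQ4/RQ5 are logistic models for prolonged spontaneous tinnitus (use;
TTS group as two dummies against "none"), reported as odds ratios with
Wald CIs. RQ7 is a linear model of the between-ear DIN difference
(exposed minus control; positive = worse exposed ear) on use and side,
with t-based intervals.

**Covariate screening.** The registered "include if indicated" rule is
made explicit and symmetric: a candidate (age for RQ3–RQ5; test order
for RQ7) is included iff it associates with *both* the exposure and the
outcome at p < .05 on the analysis sample (correlation, one-way ANOVA
or chi-square, chosen by variable type). The decision and both p-values
are logged in every fit result, and unadjusted estimates are always
retained alongside adjusted ones.

**RQ6 inference.** The registered formula is a plain logistic regression
of ear-wise tinnitus presence on exposure status and ear. With exactly
one tinnitus ear per pair the two rows of a participant are perfectly
anticorrelated, so model-based SEs are roughly √2 too small. The
primary fit therefore keeps the registered mean model but uses
participant-clustered robust (HC1) covariance with a t reference on
(clusters − 1) degrees of freedom — the standard finite-cluster
treatment. Null simulations confirm calibration (the type-I criterion
below); without the correction the nominal 5% test rejects at ~17%. A
conditional-logistic variant (`method = "clogit"`) is available; note
its exposure coefficient targets the *conditional* estimand
`logit(concordance)`, half the marginal fixed-effects log-odds
`2·logit(concordance)` — both are stored in the generator truth record.

## 4. The digits-in-noise simulator

The online test is abstracted to a psychometric listener: per-digit
recognition probability `lapse/2 + (1−lapse)·logistic(k·(SNR − T))`,
with the lapse applied symmetrically so `T` remains the 50% point and
`k` scaled so the slope at threshold equals the `slope` parameter
(probability/dB). A triplet trial is correct when ≥2 of 3 independent
digits are correct: `p³ + 3p²(1−p)`. The antiphasic condition is
modelled as a scalar unmasking advantage subtracted from the better
ear's threshold — crude, but sufficient for pipeline validation; no
audio, digit corpora or filtering are modelled.

The adaptive track starts at +2 dB SNR and follows a two-down one-up
rule: 6-dB steps until the second reversal, 2-dB steps thereafter; the
run ends at the sixth reversal and the threshold is the mean SNR of the
final four reversals. A reversal is logged at each direction change,
and a step-size change takes effect from the next SNR update onward;
all reversals after the second count toward the final four (whether a
double-reversal at the switch should count is unspecified in public
descriptions of such platforms — this reading is flagged here). Plumbing
bounds absent from any public description: 100-trial budget, SNR clamped
to [−30, +20] dB; exceeding the budget yields a non-converged signal,
and >10 consecutive pinned updates at a bound yields a degenerate-listener
signal. Tracks are replayable: the stored (SNR, correct) pairs
deterministically regenerate every reversal flag and the threshold, and
the replay API verifies the stored SNR sequence en route.

A battery mirrors the test structure: an unscored antiphasic practice
track, the two monaural blocks in randomised order, then the scored
antiphasic block (its position is not randomised; only the monaural
order is). The two-down one-up rule converges on the 70.7%-correct SNR;
the acceptance suite verifies that 1,000 seeded runs under the default
listener land within ±0.5 dB of the root of `trial_correct_prob = √0.5`
found by root-finding.

## 5. The synthetic-cohort generator

The generator's defaults are the study conditions: 4,498 participants;
48/41/11% nonuser/unilateral/nonunilateral; 57/43 right/left side; age
55.6 (SD 8.6) with users 2.0 years younger; 66% male; loud/normal
volume settings averaging 81%/51% used 48%/52% of wearing time; TTS
marginals matching the reported response proportions (54.8% "Never",
…, 0.8% "Every time"); tinnitus at 13.1% baseline with odds ratios
2.8 / 3.0 for 1–100 / >100 TTS instances and 1.025 per year of age; 60%
central tinnitus with 0.8 exposed-side concordance otherwise; DIN
completion 3752/4498 with a null exposure effect and ~3% aberrant
(equipment-failure) records that exercise the QC rule.

Where the study reports no value, defaults were chosen once as
realistic: careers of 1–3 periods totalling a log-normal ~10 years
(capped at 25, the survey-consistency bound), hours/week log-normal
with median 25.5 — chosen so the median weekly *exposure* duration is
5.1 h after the 0.2 duty cycle — truncated to (0, 80]; volume SDs 12
and 18; DIN person thresholds N(−9, 1.3) dB SNR with 0.9 dB measurement
noise and a 6 (SD 1.5) dB antiphasic advantage.

Two structural choices deserve emphasis:

* **The use–tinnitus association is emergent.** The default structural
  use effect is OR 1.0; users' excess tinnitus arises entirely through
  the TTS-affected subset, so the marginal age-adjusted use OR lands
  near the ~1.7–1.9 range while users *without* TTS match nonusers —
  the mediation structure the study describes. Because the use OR and
  the TTS ORs are estimands of *different* models, they cannot both be
  structural in one generating process; the recovery study therefore
  pairs two configurations per replicate (use OR 1.7 with null TTS
  effects for the RQ4 check; default TTS/laterality/null-DIN effects
  for RQ5/RQ6/RQ7).
* **TTS responses are generated from the same proportional-odds family
  RQ3 fits** (slope 0.06 log-odds per % volume; cutpoints anchored at
  the cohort-mean volume average, 72.3%, so the marginals reproduce the
  reported response proportions). This self-consistency is by design:
  RQ3's recovery check is then meaningful.

`generate_null_cohort()` zeroes every effect parameter (unit ORs, zero
volume slope, concordance 0.5, zero DIN exposure effect) while keeping
the demographic structure — including the age confounding, so the
covariate-screening rule is exercised under the null.

What the generator does **not** emulate: nonresponse and self-selection
bias, recall error, correlated reporting (shared method variance),
device heterogeneity, and bilateral environmental noise exposure.
Passing recovery tests therefore show the pipeline is correct and
well-calibrated *for data of this structure*, not that the original
self-report data are unbiased.

## 6. Validation design and problem sizes

The acceptance suite runs five studies, sized to be decisive yet quick
on a single CPU (the whole test suite runs in about five minutes):

1. Dosimetry vs the brute-force oracle on 1,000 random careers (1e-9
   relative), plus the unit identity and doubling laws.
2. Staircase convergence: 1,000 seeded runs, mean threshold within
   ±0.5 dB of the theoretical 70.7% point; exact track replay.
3. Parameter recovery at n = 4,500, 200 replicates: 95% CIs must cover
   the generating use OR (1.7), TTS ORs (2.8, 3.0), laterality exposure
   OR (`exp(2·logit(0.8)) = 16`) and the null DIN effect in ≥90% of
   replicates each.
4. Type-I error at n = 4,500 (the study's own scale, where the
   asymptotic inference of every model is trustworthy), 1,000 null
   replicates: each focal term must reject in 3.5–6.5% of replicates.
5. Sison–Glaz simultaneous coverage ≥94% (k = 5, n = 500, 10,000
   draws), and agreement of the k = 2 interval with the binomial
   large-sample interval within 0.3 percentage points at n = 2,334.

## 7. Known limitations

* The default calibration anchors are placeholders; absolute RQ1 levels
  (median weekly level, fraction above 85 dBA) shift with the curve and
  should be interpreted only after substituting measured device output
  levels. All validation properties are curve-independent.
* The antiphasic listener model is a scalar shift, not a binaural
  processing model; antiphasic thresholds are pipeline plumbing, not
  auditory predictions.
* The duty cycle, shift pattern and TTS multipliers are single
  configurable values standing in for heterogeneous real-world
  behaviour.
* Missing data are handled by listwise deletion within each analysis,
  mirroring per-analysis sample reporting; no outcome imputation is
  offered.
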