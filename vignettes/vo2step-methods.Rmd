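---
title: "Estimating VO2max from a submaximal step test: models, conventions, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating VO2max from a submaximal step test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vo2step)
```

## The problem

Maximal oxygen consumption (VO2max, mL·kg⁻¹·min⁻¹) is the reference measure
of cardiorespiratory fitness, but measuring it requires a maximal graded
exercise test with gas analysis. Submaximal step tests offer a practical
surrogate: heart rate (HR) rises less during stepping, and recovers faster
afterwards, in fitter people. This package implements two estimators built
on a step test with three 1-minute exercise stages and two 1-minute
recovery stages, plus a rule that combines them, and the method-comparison
statistics used to judge them.

## The heart-rate index and the regression estimator

The step test is summarized by the heart-rate index

$$\mathrm{HRindex} = (HR_{ex3} - HR_{ex1}) + (HR_{rec1} - HR_{rec2}),$$

which adds the exercise-stage HR rise to the recovery HR drop (lower =
fitter; the recovery term may exceed the exercise term, so negative values
are legal). The regression estimator (MRM) is a fixed, published equation —
it is never re-fitted here:

$$\widehat{VO}_{2max} = 64.22 - 0.23\,\mathrm{age} + 5.74\,I(\mathrm{male})
  - 0.57\,\mathrm{BMI} + 0.19\,\mathrm{PA} - 0.18\,\mathrm{HRindex}$$

with age in years, BMI in kg·m⁻², PA the 0–44 physical-activity
questionnaire score, and the sex indicator 0 for women, 1 for men. File
encodings of sex (F/M, 0/1, female/male) are normalized once at the
boundary (`normalize_sex()`); the 0/1 indicator is reconstructed only
inside the estimator. Scoring of the questionnaire items is out of scope —
the PA score is an input.

## The extrapolation estimator

Each stage is assigned a predetermined constant VO2 (mL·kg⁻¹·min⁻¹):
(4, 13, 19, 22, 17, 8) for females and (4, 14, 20, 23, 18, 8) for males at
rest, exercise stages 1–3, and recovery stages 1–2. The per-subject
least-squares line of HR (y) on constant VO2 (x) is extrapolated to the
age-predicted maximal heart rate, and the corresponding VO2 is the
estimate:

$$\widehat{VO}_{2max} = \frac{HR_{max,pred} - b}{m}.$$

Deliberate choices:

* **Regression direction.** HR is regressed on VO2 and the line inverted
  algebraically, matching the extrapolation's axes. Regressing VO2 on HR
  gives a different line whenever the points are not collinear.
* **Maximal-HR formulas.** The extrapolation anchor uses the tanaka formula
  208 − 0.7·age; the stage-3 skip rule and maximal-effort verification use
  the classical fox formula 220 − age. This split mirrors common protocol
  practice and each use-site takes a `formula` argument. The formulas cross
  at age 40 (180 bpm).
* **Slope guard.** Slopes at or below `slope_min` (default 0.1 bpm per
  mL·kg⁻¹·min⁻¹) refuse to extrapolate — a near-flat line sends the
  extrapolated VO2 to absurd values; the result is then missing with a
  reason code. Non-positive extrapolations are likewise refused. No other
  truncation or winsorization is applied: estimates are reported raw.
* **Stage-3 skip.** The protocol lets a participant skip exercise stage 3
  when, at the end of stage 2, HR is at or above 80% of the fox prediction
  *and* the Borg RPE is at or above 17 (both read inclusively, as stated
  targets). After a skip the heart-rate index — and hence the regression
  estimator — is undefined (missing with a reason); the extrapolation
  simply drops the stage-3 point and fits the remaining five. The
  five-point path is an extension beyond the validated protocol and is
  flagged by `n_points` in the fit.

## The combined rule

The regression estimator compresses the upper range (it underestimates fit
individuals — a proportional bias), while the extrapolation estimator is
noisier overall but unbiased at the top. The combined rule computes the
regression estimate and, when it reaches the cut-off (default 45.0
mL·kg⁻¹·min⁻¹), recomputes by extrapolation. Two readings of the cut-off
comparison circulate ("at or above" vs "exceeds"); the inclusive `>=` is
the default and strict `>` is available (`cutoff_strict`). The boundary
case is measure-zero in practice but must be deterministic. The combined
output is always bit-identical to exactly one leg; if the extrapolation leg
fails after switching, the result is missing with a reason rather than
silently falling back.

## Maximal-effort verification

A measured treadmill VO2 peak counts as VO2max when at least three of four
criteria hold: RER > 1.10; observed maximal HR within 10 bpm of the fox
prediction; final RPE > 17 (strict, "exceeded", unlike the skip rule's
inclusive 17 — the asymmetry is intentional and documented); and a VO2
plateau. The plateau is accepted as a reported boolean (unknown = unmet)
because plateau operationalizations vary; `vo2_plateau()` offers a
two-value helper with a configurable increment threshold (default 2.0
mL·kg⁻¹·min⁻¹) but is never auto-invoked.

## Agreement statistics and sign conventions

For measured $Y$ and estimated $\hat Y$:

* $CE = \mathrm{mean}(Y - \hat Y)$, with the sample SD of the differences
  and a two-tailed one-sample t-test;
* $SEE = SD_Y\sqrt{1 - r^2}$, with the sample (n − 1) SD and $r$ the
  Pearson correlation — invariant to positive affine recalibration of the
  estimates;
* $TE = \sqrt{\sum (Y - \hat Y)^2 / n}$ — the RMSE form, so TE is in
  mL·kg⁻¹·min⁻¹ and directly comparable to SEE;
* Bland–Altman difference $d = \hat Y - Y$: fixed bias = mean(d), 95%
  limits of agreement = bias ± 1.96·SD(d) (the conventional normal
  multiplier, not a t quantile), and proportional bias as the Pearson
  correlation of $d$ with the pair mean $(Y + \hat Y)/2$ — the standard
  Bland–Altman abscissa; its p-value equals the regression slope's t-test
  in simple regression.

The two sign conventions coexist on purpose: `fixed_bias == -ce` exactly,
and a *negative* proportional-bias r means underestimation grows with
fitness. Two identities the suite verifies: $TE^2 = CE^2 +
\frac{n-1}{n}SD_d^2$, and $TE^2 \ge \frac{n-1}{n}SEE^2$. The second
carries a degrees-of-freedom factor because the SEE is a sample-SD
quantity while TE divides by n; without that factor the inequality is
false for small cohorts whose estimates are affinely close to the
measurements. Missing estimates are excluded pairwise per method and the
dropped count is reported; nothing is imputed.

## The synthetic cohort generator

No raw participant data are distributed, so `generate_cohort()` simulates
cohorts with the structure the estimators assume. Defaults emulate a
working-adult reference population, sex-stratified (68/128 male): age
48.3 ± 7.0 (f) / 48.3 ± 6.9 (m) years; BMI 21.6 ± 3.2 / 24.6 ± 2.9 kg·m⁻²;
PA score 8.6 ± 7.5 / 11.9 ± 7.9 points on \[0, 44\]; VO2max 34.4 ± 5.0 /
41.2 ± 6.3 mL·kg⁻¹·min⁻¹. Structural knobs: resting HR 70 ± 8 bpm;
per-stage HR noise 3 bpm; true maximal HR scattered 10 bpm (SD) around the
tanaka prediction — encoding the documented unreliability of age-predicted
maxima; treadmill measurement = true fitness + b0 + b1·(centred fitness) +
noise with SD 4.2 mL·kg⁻¹·min⁻¹ (b0 = b1 = 0 by default).

Choices worth knowing:

* **Bounded scores are moment-matched.** Simulating the PA score by
  truncating a normal *at* the target moments would inflate the mean by
  ≈ 1.7 points (the lower bound sits at z ≈ −1.15). `match_truncnorm()`
  instead solves for parent parameters whose truncated distribution has
  exactly the target mean/SD; sampling is by rejection (capped), which
  respects the bounds exactly.
* **The generator embodies the extrapolation premise.** Stage HRs sit on
  one line per participant from (4, resting HR) to (true fitness, true
  maximal HR), plus independent noise, so with all noise at zero the
  extrapolation estimator recovers true fitness exactly — a calibration the
  tests exploit. Recovery-stage HR elevation is absorbed by the elevated
  recovery constants; no extra term is added.
* **Predictors are independent.** Only marginal moments of the reference
  population are known, so age, BMI, PA and fitness are drawn
  independently (a hook for a joint structure would be a stress-test
  extension, not a default). Draws producing a non-positive HR slope or
  stage HRs outside \[30, 230\] bpm are resampled up to a cap (1000), then
  the generator errors.
* **Determinism.** A config + seed pair reproduces a cohort bit-for-bit;
  all randomness flows from that one seed.

### What the generator does and does not show

Two consequences of the independence assumption matter when reading test
results. First, the generator's linear-HR premise with a ~70 bpm resting
anchor yields heart-rate indices around 55–67 bpm — higher than the
reference population's observed 46.9/35.4 — because real stage HRs are not
perfectly collinear with the tanaka-predicted maximum. Second, since the
regression estimator's other predictors carry no fitness signal under
independence, on these synthetic cohorts the *regression* estimator is the
noisier one and its estimates essentially never reach the 45 cut-off, so
the combined rule rarely switches — the opposite of the field situation
the rule was designed for, where demographic predictors do correlate with
fitness. Passing tests therefore validate the arithmetic, the guards, the
statistics, and the generator's own calibration; they do not certify
field accuracy of the estimators, and simulation-based claims are claims
about the generator, not about any real cohort.

## Numerical choices

* Least squares is computed from centred sums (numerically stable for six
  points); tests compare it against an independent normal-equations oracle
  at 1e−9 relative tolerance.
* t-tests on numerically constant differences (SD ≤ 1e−12 × scale) are
  reported as `NA` rather than fitting floating-point dust; the
  proportional bias is then flagged undefined with a reason.
* Heart rates are validated against a generous \[30, 230\] bpm envelope —
  wide enough for athletes, tight enough to catch unit mistakes (e.g. RR
  intervals). Ages outside the validated 30–60 band are flagged on the
  participant object, not refused, since the equations remain evaluable.
* Problem sizes in the test suite (cohorts of 128–2000; 100–500
  replicates) were chosen to keep Monte-Carlo error well below the asserted
  margins while running in well under a minute.

## Known limitations

* The regression coefficients and stage constants are fixed inputs from
  the validation literature; re-fitting them is explicitly out of scope.
* The questionnaire's item-level scoring is not implemented; the PA score
  arrives as a number.
* The 45 mL·kg⁻¹·min⁻¹ cut-off was derived on one population; it is a
  configurable parameter, not a universal constant.
* Bland–Altman limits of agreement are reported without confidence
  intervals, and no plotting layer is provided.
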