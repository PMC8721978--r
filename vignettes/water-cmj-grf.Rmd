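---
title: "Estimating water-based jump loading from a neck-worn accelerometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating water-based jump loading from a neck-worn accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquagrf)
```

## The problem

Countermovement jumps (CMJ) performed in chest-deep water deliver much
less impact than on land, which makes them useful for training
populations with fragile joints or low bone density.  Dosing that
exercise, however, requires knowing the landing force actually applied,
and waterproof force plates are lab equipment.  The workflow implemented
here replaces the force plate with a triaxial accelerometer worn at the
seventh cervical vertebra (C7): the landing-peak resultant acceleration,
together with covariates that capture immersion (PWDH, the water depth
as a percentage of body height), age and body weight, predicts the
landing-peak vertical ground reaction force normalised to body weight on
land:

$$\widehat{GRF}_{BW} = -1.712 + 0.658\,C7ACC + 0.016\,PWDH +
  0.008\,age + 0.003\,weight.$$

Normalising water forces by the *land* body weight matters: buoyancy
reduces the standing weight in water, so normalising by the in-water
weight would conflate immersion level with loading.  PWDH enters in
percent (0–100).  With the coefficient 0.016 that term contributes about
1 BW at typical immersion; on a 0–1 fraction scale it would contribute
about 0.01 BW and the prediction would be nonsense, which is why
`predict_grf()` warns when every supplied PWDH is ≤ 1.

The package covers four stages — synthetic data generation, signal
processing, intensity protocol, and model development/validation — each
usable on its own.

## The synthetic session generator

No public recordings of this protocol exist, so the generator is the
package's test bed: it emulates the *measurement process* with known
ground truth rather than the biomechanics.

**Force template.**  Each jump period (60/cadence seconds) is a
continuous piecewise-smooth curve: quiet stance at the apparent weight,
a cosine countermovement dip to 75% of the apparent weight, a push-off
rise to a modest peak falling to zero at takeoff, a flight phase at
exactly zero force, and a half-sine landing impulse whose maximum is the
jump's drawn peak GRF.  After a landing, the next stance begins with a
40 ms reweighting ramp so the force trace has no jump discontinuities —
steps in the trace would ring under zero-phase filtering and contaminate
extracted peaks.  Real CMJ force profiles are of course richer; the
template only guarantees the phase structure that segmentation and
peak extraction rely on.

**Study conditions.**  Per-intensity landing peaks are drawn from
N(0.64, 0.088²), N(0.67, 0.075²) and N(0.73, 0.099²) BW at 50/65/80%
heart-rate reserve, and phase jump counts from N(34.0, 2.88²),
N(45.3, 3.74²) and N(52.7, 3.23²), so a 12-subject cohort produces
roughly 1580 jump records.  Subjects are drawn as healthy young women
(23.6 ± 1.83 y, 158.2 ± 5.33 cm, 53.1 ± 7.50 kg) in 1 m of water, with
physiologic clamps applied by redrawing.

**Apparent weight.**  Quiet standing in water is modelled as
$(1-b)\cdot BW$ with buoyancy fraction $b = 0.55$ by default (apparent
weight 0.45 BW).  The value is chosen so that the drawn landing peaks
almost always exceed quiet stance: landing draws are truncated at the
apparent weight + 0.04 BW (a landing below stance could not be the
contact's peak), and at 0.45 BW that truncation trims under 5% of the
lowest-intensity distribution and shifts phase means by less than
0.01 BW, keeping the generated marginals on their anchors.  A larger
apparent weight would bite visibly into the 0.64 ± 0.088 BW
distribution.

**Acceleration link.**  Peak resultant acceleration at each wear
position follows $a = \alpha_0 + \alpha_1 g + \varepsilon$,
$\varepsilon \sim N(0, \sigma_a^2)$, with slopes solved from the
per-intensity marginal means (C7: $\alpha_1 = (1.61-1.51)/(0.73-0.64)
\approx 1.11$ g/BW, $\alpha_0 \approx 0.80$ g) and $\sigma_a$ set so the
implied marginal SD matches the 50%-intensity value (0.02 g for C7,
0.048 g for L5, 0.124 g for TA).  This makes the simulator's marginals
realistic *and* gives regression tests a known truth.  The resultant is
spread over three axes with a fixed dominant-vertical direction (15%
off-axis) plus 0.01 g per-axis white noise, a typical MEMS noise floor.
Whether such peaks are landing peaks or phase averages is a semantic
choice; the generator and the extractor both use landing-peak semantics,
consistent with treating impact loading as the construct of interest.

**Heart rate.**  Within a phase, heart rate approaches an asymptote
8 bpm above the phase's Karvonen target, with the time constant solved
per phase so the target is crossed mid-way through a 2 s "cue gap"
between the cadence ramp and the five terminal jumps.  That construction
keeps the kinetics first-order and bounded while making the labelling
rule exact by construction: the first 1 Hz sample at or above the target
always precedes the terminal five.  The 1 Hz samples are noise-free by
default — chest-strap output at 1 Hz is already smoothed — and recovery
between phases decays exponentially (τ = 45 s).  Only the labelling rule
matters downstream.

## Signal processing

* **Filtering** is sixth-order low-pass Butterworth at 50 Hz, applied
  forward and backward (`lowpass_filter`).  Zero-phase application
  avoids lagging the landing peaks; the price is that the effective
  magnitude response is the squared sixth-order response,
  $1/(1+(f/f_c)^{12})$, which is documented rather than hidden.  The
  implementation pads by odd reflection before filtering because bare
  forward–backward filtering leaks start-up transients of order 1e-6
  into the interior, violating the DC-gain contract.
* **Order of operations**: each axis is filtered first, then the
  resultant $\sqrt{a_x^2+a_y^2+a_z^2}$ is taken.  The norm is nonlinear,
  so the reverse order gives different output (a regression test pins
  the difference); fixing one order keeps results comparable.
* **Segmentation** thresholds the filtered force at 10% of the water
  body weight (the quiet-standing mean).  Sub-threshold dips shorter
  than 80 ms are merged (threshold chatter), contacts shorter than 50 ms
  are dropped (this also discards a clipped partial contact at a
  recording's end), and only contacts preceded by a flight of at least
  80 ms count as jump landings — which excludes the initial stance.
  The debounce durations are conventional choices; anything between
  roughly 30 and 150 ms works for these signals.
* **Per-jump scalar** is the *maximum* within the landing contact, for
  both normalised force and each position's resultant acceleration,
  because impact loading is the quantity of interest; contact means
  would be systematically lower and cadence-dependent.
* Sample intervals are 1-based and inclusive throughout, following R
  convention.

## Intensity protocol

Targets use the female age-predicted maximum $206.9 - 0.67\,age$,
immersion-adjusted by the resting-rate shift
($MHR_{water} = MHR_{pred} - (RHR_{land} - RHR_{water})$; the shift may
take either sign), and the Karvonen formula
$(MHR_{water}-RHR_{water})f + RHR_{water}$ at $f = 0.50, 0.65, 0.80$.
"Reaching" a target is interpreted as the first 1 Hz sample at or above
it, with no smoothing.  All jumps of a phase carry that phase's
intensity label in the record table — the per-intensity jump counts
(34/45/53) only make sense if every jump is analysed — while
`label_intensity()` flags the strict terminal five after the heart-rate
crossing.

## Model development

Records are split at the *jump* level: a uniform permutation under the
given seed, with the first $\lfloor 2n/3 \rfloor$ records forming the
development set.  Jumps within a subject are correlated, so a
subject-stratified split is available via `stratify_by = "subject_id"`;
the default follows the original per-record design.  Backward
elimination refits by ordinary least squares and removes the
highest-p-value term while it exceeds `alpha_remove = 0.10` — a common
statistical-package default for removal testing; exact p ties (which
arise only in constructed data) drop the later column.  A zero-residual
fit yields NaN p-values from `summary.lm`, which the elimination treats
as maximally significant, so exactly linear data are recovered to
machine precision.  The intercept is never a removal candidate.

## Validation battery

* **Lin's CCC** uses divide-by-*n* moment estimators, as in the original
  estimator; with n−1 estimators the value differs noticeably at small
  n.  Its magnitude never exceeds the Pearson correlation's.
* **Bland–Altman** limits default to bias ± 1.96·SD (sample SD).  The
  "±2 SD" convention appears in some reports; `k` is an argument, and
  the outside count uses strict inequality.
* **Bias percentage** has no single convention; here it is defined as
  mean(measured − predicted)/mean(measured) × 100 and documented as
  such.
* **Repeated-measures ANOVA** uses the classical three-way
  sum-of-squares decomposition with no sphericity correction, and
  pairwise post-hoc paired t-tests apply Bonferroni adjustment by
  default.

## What passing tests do and do not show

The test suite verifies, on simulated data: exact landing detection
across seeds and noise levels, noiseless peak fidelity to 1e-3 BW,
recovery of the reference equation's coefficients (exactly on noiseless
data; within 3 SE at 0.07 BW noise), the ~90% null-predictor removal
rate, Bland–Altman coverage, and the analytic filter contracts.  Problem
sizes are kept modest — single-phase six-jump sessions for segmentation
sweeps, 12-subject record-level cohorts for regression studies —
because they already exercise every code path at full sampling rate.

What this does *not* show: that a real neck-worn accelerometer in a real
pool reproduces the agreement statistics.  The simulator's
acceleration–force link is linear by construction, its waveform template
is an idealisation, hydrodynamic drag and marker motion artifacts are
absent, and within-subject correlation is present only through shared
covariates.  Agreement magnitudes obtained on simulated cohorts (CCC
around 0.7 at 0.07 BW noise) are plausible but are properties of the
simulator's settings, not evidence about hardware.  Likewise the
package's OLS machinery ignores the repeated-measures structure of
jumps within subjects; a mixed-effects extension is deliberately out of
scope.

```{r example}
rec <- simulate_records(12, seed = 1, grf_from = "reference",
                        sigma_ref = 0.07)
sp <- split_dd_vd(rec, 2 / 3, seed = 2)
fit <- fit_grf_model(sp$dd)
summary(fit)
agreement_report(sp$vd$grf_v_l_bw, predict(fit, sp$vd))
```
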