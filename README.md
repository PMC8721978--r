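# aquagrf

Estimating the vertical ground reaction force (GRF) of countermovement
jumps (CMJ) performed in water from a body-worn accelerometer.

Aquatic jumping exercise is attractive for populations that cannot
tolerate full-impact loading — buoyancy reduces the landing force — but
quantifying the skeletal loading actually delivered requires a
waterproof force plate, which confines measurement to the lab.  A small
accelerometer worn at the neck (the seventh cervical vertebra, C7) is a
practical field substitute if its landing-peak resultant acceleration
can be mapped to the force-plate measurement.  `aquagrf` implements that
mapping end to end for exercise scientists and biomechanists:

* **Synthetic sessions with known ground truth.**  1000 Hz force-plate
  and triaxial accelerometer traces (C7, fifth lumbar vertebra L5, and
  tibia TA wear positions) plus a 1 Hz heart-rate trace for continuous
  CMJ bouts in water, so every downstream stage is testable without
  human data.
* **Signal processing.**  Zero-phase sixth-order Butterworth low-pass
  filtering at 50 Hz, three-axis resultant acceleration, and
  landing-contact segmentation at 10% of the water body weight.
* **Intensity protocol.**  Karvonen heart-rate-reserve (HRR) targets
  with the maximal heart rate adjusted for immersion
  (`MHR_water = (206.9 − 0.67·age) − (RHR_land − RHR_water)`), a cadence
  ramp of +5 beats/min every 20 s from 80 beats/min, and the
  five-terminal-jump labelling rule.
* **Model development.**  Random two-thirds / one-third split into
  development (DD) and validation (VD) records, ordinary least squares,
  and backward elimination over the candidate predictors.
* **Validation.**  Paired t, Pearson r, Lin's concordance correlation
  coefficient (CCC), Bland–Altman limits of agreement and bias
  percentage.

At its core is the reference prediction equation over the landing-peak
C7 resultant acceleration (g), the percentage of water depth to body
height (PWDH, %), age (y) and body weight (kg):

```
GRF_BW = −1.712 + 0.658·C7ACC + 0.016·PWDH + 0.008·age + 0.003·weight
```

returning the landing-peak vertical GRF in units of body weight measured
on land (BW).

## Worked example

Evaluating the reference equation at the validation-group mean inputs —
C7ACC 1.568 g, 1 m water depth on a 158.2 cm subject
(PWDH = 63.2%), age 23.6 y, weight 53.1 kg:

```r
library(aquagrf)
predict_grf(1.568, pwdh(100, 158.2), 23.6, 53.1)
#> [1] 0.679222
```

i.e. a mean landing peak of 0.68 BW — about a third of the typical
land value, which is the point of exercising in water.  The full
develop-and-validate loop on a simulated 12-subject cohort whose jump
records follow the reference equation plus 0.07 BW of noise:

```r
rec <- simulate_records(12, seed = 1, grf_from = "reference", sigma_ref = 0.07)
sp  <- split_dd_vd(rec, 2/3, seed = 2)
m   <- fit_grf_model(sp$dd)          # backward elimination from the full model
m
#> GRF prediction model (fitted)
#>   GRF_BW = -1.746 +0.643*c7acc +0.017*pwdh +0.008*age +0.003*weight
#>   n = 1066, adjusted R^2 = 0.570

agreement_report(sp$vd$grf_v_l_bw, predict(m, sp$vd))
#> Agreement over 534 pairs
#>   paired t: t = 0.431, df = 533, p = 0.667
#>   Pearson r = 0.7547, Lin's CCC = 0.7171
#>   Bland-Altman bias -0.0014 BW, LoA [-0.1467, 0.1439], 5.06% outside
#>   bias percentage -0.206%
```

The elimination recovers all four terms with coefficients close to the
generating equation, and the held-out agreement shows no systematic
bias.  The waveform-level route — `generate_session()` →
`process_session()` — produces the same per-jump records from raw
traces, and `run_pipeline()` drives the whole chain
(simulate → process → develop → validate) writing `jumps.csv`,
`model.json` and `report.json`.

Per-subject heart-rate targets:

```r
s <- generate_subject(seed = 1)
intensity_targets(s)
#> MHR predicted 191.9 bpm, immersion shift 4.0, MHR water 187.8
#> targets: 50% HRR -> 131.7 bpm, 65% HRR -> 148.5 bpm, 80% HRR -> 165.4 bpm
```

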