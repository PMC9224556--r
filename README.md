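# ivcpulse

Semi-automated inferior vena cava (IVC) edge tracking and non-invasive
right atrial pressure (RAP) estimation from B-mode ultrasound.

Right atrial pressure — the filling pressure of the right heart — is
measured exactly only by right heart catheterization.  Sonographers
estimate it instead from the size and collapsibility of the IVC, but the
standard guidelines rule is coarse and operator dependent.  `ivcpulse`
implements, end to end, a quantitative alternative for researchers in
echocardiographic hemodynamics:

- **Edge tracking**: median-filter denoising, normalized-cross-correlation
  tracking of two reference points for motion compensation, gradient-based
  delineation of both vessel borders at 30 stations per frame with
  sub-pixel refinement, and 5 midline-orthogonal diameters covering the
  central 15 mm of the analyzed portion.
- **Pulsatility**: beat segmentation of the diameter signal and the
  cardiac caval index, the beat-wise fractional collapse
  CCI = (Dmax − Dmin)/Dmax averaged over stations and beats, plus the mean
  diameter.
- **Three RAP estimators**: the guidelines rule (< 2.1 cm and > 50%
  collapse → 0–5 mmHg; > 2.1 cm and < 50% → 10–20 mmHg; otherwise
  5–10 mmHg); a normalized linear model whose published form is

  RAP = 0.26 + 11.59·PAWP/33.7 + 3.89·TAPSE/35 − 8.28·(E/E′)/30
        − 2.3·TRd/4 + 3.693/(CCI + 0.3) + 2.82·D/34   [mmHg]

  with classes cut at 5 and 10 mmHg; and a one-vs-all RBF support vector
  machine on z-scored features.
- **Selection and validation**: backward feature elimination driven by
  stratified 10-fold cross-validated accuracy, leave-one-out evaluation,
  one-vs-all sensitivity/specificity/precision/accuracy/F-score, Fisher
  ratios, Bland–Altman agreement and mean absolute error.
- **Synthetic ground truth**: rendered speckle videos of a pulsating
  vessel with known diameter waveform, and patient cohorts with known
  generating model and realistic feature moments and missingness.

## Worked example

Measure a synthetic vessel video whose true pulsatility is 0.42 and feed
the result to the estimators:

```r
library(ivcpulse)

sim   <- simulate_vessel_video(vessel_sim_config(pulsatility = 0.42, seed = 1))
feats <- measure_ivc(sim$sequence, sim$init)
feats
#> <ivc_features: CCI 0.420 (42.0%), mean diameter 15.23 mm, 2 beat(s)>

guidelines_classify(feats$mean_diameter_mm / 10, feats$cci)
#>   class rap_low rap_high
#> 1     2       5       10
```

The tracked CCI (0.420) matches the generating pulsatility to three
decimals and the mean diameter is within 0.01 mm of the rendered truth
(15.22 mm); a 1.5 cm IVC collapsing 42% lands in the intermediate
guidelines class (5–10 mmHg).

Simulate a 170-patient cohort and evaluate the linear model by
leave-one-out cross-validation:

```r
cohort <- simulate_cohort(n = 170, seed = 20220607)
feats  <- published_lm_spec()$terms$feature
preds  <- loocv_predictions("lm", cohort$table, feats)

mean_absolute_error(cohort$table$RAP, preds$rap)
#> [1] 2.476765
mean(preds$class == preds$truth)
#> [1] 0.5647059
confusion(preds$truth, preds$class)
#>     predicted
#> true 1  2  3
#>    1 6 12  2
#>    2 6 43 28
#>    3 0 26 47
```

With the generator's default RAP noise (sd 3.2 mmHg) the out-of-sample
mean absolute error is 2.48 mmHg — so a 24 mmHg pressure range resolves
`rap_resolution_levels(24, 2.48)` ≈ 10 distinguishable levels — and
three-class accuracy is 56%, limited mostly by confusion between
neighbouring classes.

A command-line wrapper covering the same stages (simulate-video,
simulate-cohort, track, features, estimate, train, select, evaluate)
ships as `inst/cli/ivcpulse`.

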