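---
title: "Estimating right atrial pressure from IVC edge tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating right atrial pressure from IVC edge tracking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivcpulse)
```

## The problem

Right atrial pressure (RAP) is the filling pressure of the right heart.
It is measured exactly only by right heart catheterization, an invasive
procedure, so clinicians routinely estimate it from subcostal B-mode
ultrasound of the inferior vena cava (IVC): a large, compliant vein whose
diameter and respirophasic collapse reflect central venous pressure.  The
standard guidelines rule is coarse (three classes from two thresholds) and
operator dependent.  This package implements a complete alternative
pipeline:

1. **Edge tracking** — semi-automated delineation of the two IVC borders
   in every frame of a short (1–3 s) cine loop, with motion compensation
   from two user-chosen reference points;
2. **Pulsatility** — beat-wise cardiac caval index (CCI) and mean diameter
   from five midline-orthogonal diameters;
3. **RAP estimation** — the guidelines rule, a normalized linear model,
   and a one-vs-all radial-basis SVM over standard echocardiographic
   features;
4. **Feature selection and validation** — backward elimination driven by
   stratified k-fold cross-validated accuracy, leave-one-out evaluation,
   and the associated metrics (one-vs-all indexes, Fisher ratios,
   Bland–Altman agreement, mean absolute error).

Because the underlying clinical cohort is not publicly deposited, the
package also ships calibrated synthetic generators — rendered speckle
videos with a known diameter waveform, and patient cohorts with known
generating model — that provide exact ground truth for every stage.

## Edge tracking

Each frame is smoothed with a 2D median filter (default 5×5, edge
replication; implemented in C++ and verified against a brute-force
sliding-window oracle).  Two reference points indicated on the first frame
are followed through the clip by normalized cross-correlation of fixed
21×21 first-frame templates inside a ±15 px search window; the average of
the two displacements is the rigid motion estimate used to shift the
region of interest.  A correlation floor (0.5) guards against template
loss: below it the point keeps its previous position and the frame is
flagged.

Border detection casts, at 30 stations equally spaced along the vessel
axis, a scan line orthogonal to the axis and samples the image by bilinear
interpolation at a quarter-pixel step.  The two borders are the strongest
bright→dark and dark→bright intensity transitions bracketing the dark
lumen — found as the pair of gradient extrema *i < j* maximizing the drop
plus rise, a linear-time prefix-minimum scan — refined to sub-pixel
precision by a parabolic fit around each gradient extremum.  Stations
whose scan line shows no usable contrast (intensity range below the noise
floor, default 0.08 on unit-scaled intensities) are interpolated from
their neighbours and flagged with confidence zero.  For temporal
coherence, frames after the first search only a ±2 mm band around the
previous border positions.

All geometry is computed in physical millimetre coordinates so that
anisotropic pixels are handled correctly.  The vessel axis is re-estimated
every frame from the fitted midline; the first frame starts from the
user's axis hint and, when the fitted midline reveals the hint was off by
more than ~1 degree, the frame is re-delineated once with the corrected
axis.  This matters: scanning 30° off-axis inflates the apparent width by
1/cos 30° ≈ 15%, and the pixel staircase of oblique edges adds jitter.
Diameters are measured at 5 stations equally spaced over the **central
15 mm** of the analyzed portion (extremities avoided), orthogonal to the
local midline tangent: the separation measured along the scan normal is
multiplied by `1/sqrt(1 + m'^2)` with `m'` the local midline slope, and
borders and slope are estimated by local linear fits across stations
(window ±3 mm), which suppresses the staircase jitter.  A tilted vessel
therefore yields its true perpendicular width (the suite checks 15 mm
within 0.3 mm at 30° tilt), and a rigid shift of the whole clip leaves
the diameter series unchanged within half a pixel.

## Pulsatility

The five-station mean diameter is smoothed by two moving-average passes
(≈ a triangular low-pass, default 0.2 s window, reflection padding) and
successive local maxima — peak distension between cardiac collapses —
delimit the beats.  Candidate peaks must be compatible with an admissible
heart-rate range (default 40–180 bpm) and comparable in height to peak
distension (within 35% of the signal amplitude of the tallest peak), which
rejects noise bumps near the cycle minimum and clip boundaries that merely
cut the signal mid-slope; a genuine maximum lying exactly on the clip
boundary does count.  Per diameter *d* and beat *b* the cardiac caval
index is the fractional collapse

$$\mathrm{CCI}(d,b) = \frac{\max D - \min D}{\max D}$$

within the beat, and the reported CCI averages over all stations and
beats; the mean diameter averages all stations over all frames.  The CCI
convention normalizing by the within-beat maximum matches the caval-index
definition ("percentage decrease" from peak distension) applied per
heartbeat; because the source convention is not fully recoverable, the
alternative mean-normalized variant is available via
`compute_cci(..., denominator = "mean")`.  CCI is kept as a fraction
internally and shown as percent only at presentation.

## RAP estimators

**Guidelines rule.**  Diameter < 2.1 cm *and* collapse > 50% → low RAP
(0–5 mmHg); diameter > 2.1 cm *and* collapse < 50% → high RAP
(10–20 mmHg); everything else — including the exact boundaries, since
both defining inequalities are strict — intermediate (5–10 mmHg).

**Linear model.**  `published_lm_spec()` stores the selected model

$$\widehat{\mathrm{RAP}} = 0.26 + 11.59\,\frac{\mathrm{PAWP}}{33.7}
 + 3.89\,\frac{\mathrm{TAPSE}}{35} - 8.28\,\frac{E/E'}{30}
 - 2.3\,\frac{\mathrm{TRd}}{4} + \frac{3.693}{\mathrm{CCI} + 0.3}
 + 2.82\,\frac{D}{34}$$

with PAWP in mmHg, TAPSE in mm, TRd as 0–4 grade, CCI as fraction, D in
mm.  Each ordinary term is divided by the maximum value of its feature so
the weights are comparable across units.  The CCI term uses the
inverse-shifted transform `1/(CCI + 0.3)`, the form maximally correlated
with RAP: pressure rises as the vein stiffens and stops pulsating.  Two
typographic parses of the printed CCI term are possible; the default reads
3.693 as the full weight with unit denominator (consistent with how every
other fraction flattens, and with the weight's magnitude relative to the
others), the alternative is `published_lm_spec("max")`.  CCI enters as a
fraction: with percent units the term would be numerically negligible.
`lm_fit()` refits the same normalized form by ordinary least squares
(denominators either supplied or taken as data maxima) and diagnoses rank
deficiency by naming the collinear columns.  Continuous estimates are
classified by the 5/10 mmHg thresholds (low ≤ 5 < intermediate ≤ 10 <
high).

**SVM.**  Three binary radial-basis machines (one class against the other
two) on z-scored features — a radial kernel on raw mixed-unit clinical
features would be dominated by the largest-scaled column.  Prediction is
the argmax of the three decision values, ties toward the lower class.
Hyperparameters default to cost 1 and gamma 1/n_features on the
standardized scale; both are arguments.

**Screening and imputation.**  Only features observed in more than 95% of
subjects enter modelling (`screen_features()`); missing values receive the
column medians (`impute_missing()`), the categorical rhythm its mode.  Two
imputation modes exist: whole-table (the behaviour implied by a
retrospective single-pass analysis) and the leakage-safe default used
inside cross-validation, where medians come from the training fold only
and are applied to the held-out rows.

## Selection and validation

`kfold_accuracy()` partitions rows into k = 10 folds **stratified by RAP
class** — with three classes and 170 patients, unstratified folds can lose
a class entirely — using a fixed, logged seed (default 20220607).
`backward_select()` removes, at each iteration, the feature whose removal
maximizes the cross-validated accuracy (the least informative one), down
to a single feature; the full removal order ranks the candidates by
importance and the best subset is the accuracy maximizer (smallest subset
on ties).  Accuracy ties between candidate removals are broken by
removing the feature occurring later in the canonical table order, which
keeps clinically primary features longer; the rule is deterministic and
documented.  Rank-deficient subsets (duplicated columns) score NA and the
elimination continues.  Fold assignment is fixed for a whole selection
run rather than re-randomized per iteration, so subset comparisons share
the same partitions.  `loocv_predictions()` provides the final
leave-one-out evaluation feeding the confusion-matrix metrics.

One-vs-all indexes (sensitivity, specificity, precision, accuracy,
F-score) are computed per class and macro-averaged unweighted; an index
undefined for a class (zero denominator) is excluded from the macro mean
with a warning rather than zero-filled.  The per-class-then-average order
is the convention consistent with the reported summary figures (applying
the F-score formula to averaged precision and sensitivity gives a
different number).  Overall multi-class accuracy (trace/n) is reported
separately from macro one-vs-all accuracy, since the two genuinely
differ.  `bland_altman()` uses differences `x − y` with `x` the operator
measure; limits are bias ± 1.96 sample SD.

## Synthetic data: what it emulates, what it does not

`simulate_vessel_video()` renders a long-axis vein as a dark band of
instantaneous width

$$D(t) = D_0\left(1 - p\,\frac{1 - \cos 2\pi f t}{2}\right)$$

between bright walls, so the ground-truth CCI is exactly *p*.  Defaults
are the population means of the modelled cohort: D₀ = 19 mm, p = 0.42,
72 bpm, 30 fps, 0.2 mm/px, 2 s clips (the clinical clips span 1–3 s).
The walls carry a static, median-filtered texture that translates with a
slow sinusoidal respiratory drift — giving the reference tracker real
structure to lock onto — plus independent per-frame Gaussian noise
(default sd 0.05) for electronic speckle decorrelation; intensities are
quantized to 16 bits so frames are bit-reproducible from the seed and
survive TIFF round trips exactly.  The wall/lumen transition is a 0.15 mm
ramp, placing the gradient extremum exactly on the geometric border.  The
generator does **not** model Rayleigh/K-distributed speckle statistics,
out-of-plane motion, non-circular cross-sections or sniff maneuvers, so
passing tests demonstrate correctness of the measurement chain, not
robustness to every clinical artifact.

`simulate_cohort()` draws the Table-of-features variables independently
from truncated normal distributions at the population mean ± SD
(truncation at physiological bounds, e.g. CCI in [0, 0.95], LVEF in
[10, 80]), log-normals matched to the reported median and IQR for the two
skewed biomarkers, and a 0.65/0.28/0.07 sinus/afib/pacing rhythm mixture.
RAP is the published linear model's prediction plus Gaussian noise
(default sd 3.2 mmHg ≈ 2.56·√(π/2), reproducing the reported mean
absolute error), and **patients whose RAP falls outside the observed
0–24 mmHg range are redrawn rather than clipped**: rejection preserves the
exact linearity of the noiseless feature→RAP map, so an OLS refit
recovers the generating coefficients to machine precision for every seed,
while hard clipping would bias the tail and break that identity.
Missingness is punched in per column at the registry rates (e.g. 3/170
for TAPSE, 4/170 for troponin).  True inter-feature correlations are
unknowable from published moments, so features are independent by
default — a stated limitation: real collinearity (e.g. PAWP with E/E')
makes selection harder than these fixtures suggest.

At 2.5 mmHg RAP noise the weak model terms are genuinely unrecoverable at
n = 170: the IVCd and TRd terms contribute only ≈0.4–0.5 mmHg SD, so
their importance rank is near-random, while PAWP (≈2.4), E/E' (≈2.2) and
the transformed CCI (≈1.4 mmHg SD) are reliably kept.  The selection
tests assert exactly that recoverable property, and the sharper
3-informative-versus-3-noise construction at n = 200.

## Numerical choices and problem sizes

Scan-line sampling at min(spacing)/4 with parabolic sub-sample
refinement; borders never cross (offsets are sorted if a pathological
pair inverts); degenerate inputs error early with named causes (missing
calibration fields, missing features, absent classes, zero-variance
Fisher groups, sub-1 s clips without `force`).  Determinism is a
contract: every stochastic routine takes a seed, restores the caller's
RNG state, and identical configuration yields byte-identical outputs.

The validation suite runs at desk scale chosen to finish in minutes while
leaving no contract untested: three rendered 2 s videos for the
pulsatility sweep (p = 0.1/0.3/0.5, recovered within ±0.02), cohorts of
n = 170 matching the modelled registry, 20-seed Monte-Carlo for the
selection property, 10⁵ draws for generator-moment convergence, and 100
random confusion matrices against brute-force counting.

## Known limitations

Long-axis tracking only (no short-axis cross-sections); no respirophasic
or sniff-based indexes — clips are too short by design, which is also why
CCI rather than the classical caval index feeds the models; no automatic
initialization (reference points, ROI and axis hint are user inputs); no
DICOM network ingestion — sequences arrive as image stacks with a JSON
calibration sidecar; SVM decision values are not calibrated
probabilities; and all quantitative claims about classifier accuracy on
real patients are outside what synthetic cohorts can establish.
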