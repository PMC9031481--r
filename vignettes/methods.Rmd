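---
title: "Gesture recognition in palsy faces: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gesture recognition in palsy faces: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palsygest)
```

## The model

`palsygest` recognizes six posed facial gestures (rest, eyebrow elevation,
eye closure, wide-open smile, closed-mouth smile, pucker) from a single
frame's landmark coordinates, in faces where unilateral palsy makes one
hemiface move less than the other. The pipeline is geometric end to end:
no appearance information is used, so anything that does not move a landmark
is invisible to the method.

The working assumptions are:

* **Frame-based**: each face is classified independently; no temporal
  information.
* **Landmarks are given.** The package starts from a 68-point face-shape
  prediction (or directly from 51 reorganized points). Face detection and
  landmark prediction from pixels are out of scope; an external predictor's
  output can be adapted via `select_51()`.
* **Asymmetry carries the signal.** Most features compare a left-side
  measure against its right-side counterpart as `max(a/b, b/a)`, which is
  1 for perfect balance and grows with asymmetry regardless of which side
  is affected. Angle features use `∠(Pa, Pb) = arctan2(Δx, Δy)·180/π` —
  the x-difference deliberately first, exactly as the formula is printed in
  the source methodology, so a horizontally level pair reads 90° and
  deviation from 90° measures how far one endpoint has risen relative to
  the other. A constant offset like this is irrelevant to a trained
  classifier; fidelity to the printed convention wins, and the conventional
  `atan2(Δy, Δx)` order remains available via
  `angle_between(..., convention = "atan2_yx")` for sensitivity analysis.
* **Coordinates are image pixels**: origin top-left, y increasing downward.
  A raised eyebrow therefore has a *smaller* y. This is stated once here
  and used consistently everywhere.

## The 51-point reindexing

The 68-point layout loses its 17 jaw-contour points; the remaining 51 are
reorganized as P0–P9 eyebrows (outer-left to outer-right), P10–P15 left eye
from the outer corner, P16–P21 right eye ending at the outer corner P19,
P22–P27 nose base/nostril block, P28–P39 outer lip (P28 left corner, P31
top-mid, P34 right corner, P37 bottom-mid), P40–P47 inner lip, P48–P50 nose
bridge. The published figure of the reorganized points is pictorial only, so
this mapping is the package's own, fixed once (`landmark_index_map()`) and
constraint-checked in the tests: it honors every index the feature formulas
reference. The three nose-bridge points sit at the end because the formulas
pin the mouth block to start at P28, leaving only six nose indices before it.

Head width, mouth-to-chin and eye-to-head-side distances need boundary
references that the 51 inner points cannot supply, so the chin and the two
outermost jaw points are retained as named auxiliaries (`chin`,
`left_face_side`, `right_face_side`) and transformed along with the primary
points.

## Measures and features

Thirty measures are computed per face: 28 distances plus the two mean
eyebrow heights `L` and `M`. Three choices here were genuinely open and are
worth recording:

* **Eyebrow "height"** is the mean elevation of the five brow points above
  the outer-eye-corner line, not an absolute image coordinate. Absolute
  coordinates would make the ratio `max(L/M, M/L)` depend on where the face
  sits in the frame, violating the translation invariance every other
  feature has; elevation above a face-intrinsic line keeps the measure
  positive, translation-invariant and proportional to face scale.
* **Eye-opening bookkeeping.** Each eye contributes two upper/lower lid
  openings. The `N` measures belong to the left eye and the `O` measures to
  the right; the second subscript is the lid pair's horizontal position in
  the image (`l` toward image left, `r` toward image right). So
  `N = (Nl + Nr)/2` is the left eye's mean opening, `O` the right eye's, and
  the outer-opening ratio pairs `Nl` with `Or`, the inner-opening ratio `Nr`
  with `Ol`. This is the only assignment under which the average-opening
  ratio responds to one-sided eye closure *and* all three opening ratios
  equal 1 on a perfectly symmetric face — both of which the tests assert.
* **Mouth half-widths** `Vl`, `Vr` are measured from each mouth corner to
  the midpoint of the top-mid and bottom-mid outer-lip points, so a corner
  pulled sideways *or* vertically on one side registers.

The full endpoint ledger — one documented endpoint pair per distance — is in
`R/measures.R`. Several endpoints (notably the head-side references for
`D`/`E`) cannot be recovered unambiguously from a pictorial source; the
ledger is a documented best effort, and every downstream number in this
package is defined with respect to it.

Degenerate inputs are handled by convention rather than exception so that
batch feature extraction never dies mid-run: coincident points give angle 0,
a vertical pair gives a slope sentinel of ±10⁶, and eye/mouth openings that
enter ratio denominators are floored at 10⁻³ of the inter-ocular distance
(the one-pixel-ish floor a real lid landmark pair keeps). A face with zero
mouth or head width is rejected with a degenerate-geometry error.

## Tilt correction

The correction transform is the pure rotation about the outer-eye-corner
midpoint that levels those corners; the corner midpoint and inter-corner
distance are preserved. A general similarity transform could also rescale,
but every feature is a ratio, angle or slope, so scale is irrelevant and
the minimal conforming transform is preferred. "Level" means the corner
y-difference is below 10⁻⁶ of the inter-ocular distance; correction is
idempotent to the same tolerance.

## The classifier

The MLP reproduces the behavioral contract of the classic Weka-style
perceptron the methodology was developed with: one hidden layer of `H`
sigmoid units (a single numeric `H` in that tool means exactly one hidden
layer), six sigmoid outputs, squared-error online backpropagation with
learning rate `L` and momentum `M`, per-epoch reshuffling, weights drawn
uniformly from (-0.5, 0.5), and min–max normalization of each attribute to
[-1, 1] computed **on the training split only** (the fitted normalizer
travels with the model; this is asserted against leakage in the tests).
Defaults are the published optimized values `L = 0.2045`, `M = 0.1909`,
`H = 95`, `S = 0`, `N = 5000`. No weight decay, validation split or early
stopping — the cited tool's defaults. Randomness comes from a private
splitmix64 generator seeded by `S`, so training is bit-reproducible across
platforms and independent of R's RNG stream. The core loop is C++ (via
Rcpp), as `N = 5000` online epochs over a few thousand samples is
impractical in interpreted R.

No pre-installed R package offers this exact contract (seeded momentum-SGD
sigmoid MLP with external normalization), which is why the ~100 lines of
backpropagation are implemented here rather than delegated.

## The experimental protocol

Rotation augmentation creates `2m + 1` copies per face for `m` magnitudes
(default ±5°, ±10°, ±15° — the magnitudes are not specified by the source,
which cites prior work; small angles match the head-tilt regime the
correction handles). Because features are extracted after tilt correction,
a rotated copy's noise-free features equal its original's to 10⁻⁶ — the
augmentation is simultaneously a built-in rotation-invariance check.

Cross-validation uses a stratified k-fold split that by default keeps all
augmented copies of one original photograph in the same fold. Plain
per-sample splitting (`group = FALSE`) is also provided, since the
original experiment's per-fold arithmetic (560 test samples per fold from
2800) suggests augmented copies were split freely; both modes are tested.
Fold metrics use the one-vs-rest formulas; a metric whose denominator is
zero (a class absent from a fold) is reported as 0 and flagged rather than
raising.

## The synthetic generator: what it emulates and what it does not

The generator exists because the patient image collections this method
targets are available only on request. It poses a bilaterally symmetric
51-point template (inter-ocular distance 100 px, the scale unit for all
displacement magnitudes) through hand-designed per-gesture displacement
fields: brow raise lifts the brows ~12 px and widens the lids (raising the
brows demonstrably co-opens the eyes in posed photographs); eye closure
converges the lids; the wide-open smile pulls the corners out/up and parts
the lips; the closed-mouth smile stretches the mouth with lips together;
pucker narrows the mouth toward the midline. Palsy is one-sided
attenuation: displacement on the affected half is scaled by `1 − severity`
(midline points by `1 − severity/2`), and a severity-scaled resting droop
(brow ptosis, lid sag, fallen mouth corner) is added to the affected half in
*every* gesture, so higher grades are asymmetric even at rest. Eight posed
movements per subject map onto the six classes: rest→0, brow→1, light and
full eye closure→2, full smile and lip depression→3, pucker→5, and the
light smile lands in class 3 or 4 depending on whether its drawn
lip-parting fraction exceeds a threshold (default 0.5) — mirroring
assignment-by-appearance for a movement that straddles two classes.

Defaults: coordinate noise SD 0.5 px (half a percent of the inter-ocular
distance, a typical landmark-predictor jitter), head tilt uniform in ±10°,
severity drawn uniformly within each grade band (normal ≤ 0.05 up to
complete ≥ 0.85), affected side random per subject, grades cycled over
subjects. Amplitudes were chosen once so that the clean classes are
separable by the 29 features, and validated by test — not tuned against any
accuracy target afterwards.

What a green synthetic test establishes: the geometry, features, classifier
and protocol interlock correctly, asymmetry grows monotonically with
severity, and the six classes are recoverable from the stated feature set.
What it does not establish: performance on real patients. Real faces vary
in proportion between subjects (one template is used here), landmark
predictors fail in structured, non-Gaussian ways, palsy phenotypes (flaccid
vs non-flaccid) differ in more than amplitude, and posed clinical
photographs have composition regularities no generator reproduces. The
published headline accuracies on real patient data (around 90% overall)
are therefore *not* reproduction targets for the synthetic suite; the
suite's ≥ 85% five-fold bound on 60 clean synthetic subjects is the
qualitative analogue only.

## Numerical and budget choices

* Test-suite cross-validation runs use `N = 600` epochs instead of the
  default 5000: the clean synthetic problem converges well before 600
  epochs, and the full budget would spend minutes per fold for no change in
  outcome. `N = 5000` remains the package default for real use.
* Model files store every weight as a `%.17g` decimal string: standard JSON
  number emission rounds near the 15th significant digit, which would break
  the save/load contract that reloaded models predict bit-identically.
* Argmax ties in prediction break toward the lowest class index,
  deterministically.
* The k-fold dealer rotates its starting fold between classes so small
  classes spread across folds instead of piling onto fold 1; a class with
  fewer groups than folds triggers a warning and approximate stratification
  rather than failure.

## Known limitations

* The 51-point reindexing and the distance-endpoint ledger are
  constraint-consistent reconstructions of pictorial definitions; they are
  documented and frozen, but not guaranteed identical to the original
  authors' choices.
* Exactly which of the 30 measures the original 29-feature set discarded is
  unknowable from the published material; this package computes all 30
  measures and exactly the 29 documented features.
* Gesture intensity is not measured (light vs full eye closure collapse
  into one class by design), and no per-action-unit detection is attempted.
* The image adapter (photograph → landmarks) is intentionally absent from
  the core; the package consumes coordinates.
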