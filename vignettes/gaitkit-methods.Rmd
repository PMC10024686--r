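---
title: "Mobility scoring from pose keypoints: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mobility scoring from pose keypoints: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitkit)
```

`gaitkit` scores dairy-cattle mobility from pose-estimation output: 15
anatomical keypoints per animal per video frame, for cows walking in single
file past a fixed side-view camera. This vignette records the scientific
model behind each stage, the conventions and tunable parameters, and the
design decisions taken where more than one reasonable choice existed. It
states no empirical result beyond what the package's test suite and
acceptance script themselves compute.

## Coordinate and data conventions

All geometry is in image pixel coordinates: origin top-left, y increasing
downward. Every pose stores 15 keypoints in a fixed canonical order
(`keypoint_names()`), with COCO-style ternary visibility (absent /
occluded / visible); features use visible points only, because hooves and
knees are the least reliably detected landmarks in dark-floor footage and
the format must be able to express that. Sequences are normalized so cows
travel toward +x (tracks with negative net displacement are mirrored),
which makes the sign of the neck gradients comparable across camera
orientations; the RMSE and area features are unaffected by mirroring.
Keypoint files are a small JSON dialect written at full double precision so
that write-then-read reproduces coordinates bit-for-bit.

## Back posture

The topline is the ordered five-point dorsal chain tail setting → hook
bone → back centre → withers → scapula. Two complementary measures:

* **Regression RMSE.** Ordinary least squares of y on x through the five
  points; the root mean squared vertical residual grows with back arching.
  OLS of y on x (not orthogonal regression) is used because the residuals
  of interest are vertical offsets of the spine from a straight back line.
  The fit degenerates when the points have no x spread (a cow walking
  directly at the camera); that is reported as an error rather than a
  feature value.
* **Area sections.** The chord from tail setting to scapula is the
  baseline; interior points are projected onto it and their perpendicular
  heights accumulated as trapezoids between consecutive projections. With
  end heights zero this trapezoid sum equals the area of the closed
  five-point polygon (the test suite checks it against a shoelace oracle).
  Heights are signed: a sway-backed segment below the baseline contributes
  negative area rather than being clamped, which preserves the identity
  total = rear + front + neck sections. The rear section spans two
  trapezoids (tail → hook → centre), the front and neck sections one each
  (centre → withers, withers → scapula) — the partition that exhausts all
  four trapezoids while matching the three named regions of the back.

## Head carriage

The back-line fit is extended forward past the scapula and evaluated at the
head and nose x positions. The elevation is the squared vertical distance,
negated when the point lies below the line: in image coordinates
`y_line < y_keypoint` means the keypoint is physically lower. Squaring
emphasises large head drops; the sign preserves whether the head is carried
above or below the back line, which distinguishes an alert carriage from
the lowered, bobbing head of a lame cow. The head and nose values are
combined per frame by their mean — the least-structured combiner for a
single per-frame series; both are also available individually. The neck
angle uses the standard angle-between-lines identity
`atan((m1 - m2)/(1 + m1 m2))` with m1 the withers→scapula gradient and m2
the scapula→head gradient; the perpendicular case `1 + m1 m2 = 0` returns
±π/2 by the sign of `m1 − m2`, and a vertical segment is a reported
geometry error. The denominator constant is 1: any other value would break
the defining property that equal gradients give a zero angle.

## Tracking

Multi-animal footage needs per-animal time series, so detections are
re-associated across frames with a SORT-style tracker: a constant-velocity
Kalman filter on each track's bounding-box centre, area and aspect ratio
(aspect held constant), predictions matched to detections by minimising
1 − IoU with the Hungarian algorithm, matches below the IoU threshold
rejected. Noise covariances follow the values commonly used with this
parameterization, scalable via `tracker_config()`. Unmatched detections
spawn tentative tracks that must accumulate `min_hits_to_confirm` (default
3) hits before contributing features — the standard guard against spurious
detections — and tracks are retired after `max_misses` (default 5)
consecutive missed frames. The single-file walkway constraint means cows
cannot swap positions, which is what makes IoU-only association (no
appearance model) adequate; crossing animals are explicitly out of scope.
Inputs that already carry track ids can bypass the tracker
(`trust_input_ids`).

## Aggregation

Each per-frame feature series is collapsed to seven statistics: min, max,
mean, median, standard deviation, skew and kurtosis. Conventions, fixed and
documented because several definitions coexist: the standard deviation uses
one delta degree of freedom (n − 1); skew and kurtosis are the biased
(population) moment estimators with kurtosis reported as excess (Fisher)
kurtosis; a constant series is assigned skew and kurtosis 0 rather than NaN
so feature tables stay numeric (flagged implicitly by its zero standard
deviation). The default table has 48 columns — 7 features × 7 statistics
minus the head/nose elevation median, whose information is carried by the
mean and extrema of the same series; `full_stats = TRUE` restores it. Cows
with fewer than `min_frames` (default 10) valid back frames are excluded
with a warning: shorter tracks give unstable higher moments.

Rater scores on the 4-point mobility scale are consolidated by arithmetic
mean rounded to the nearest whole score, halves away from zero (three
raters on an integer scale cannot produce an exact half; the rule is fixed
anyway so two-rater inputs behave deterministically). Feature screening
uses Pearson correlation with two-sided p-values, banded † p<0.10, \*
p<0.05, \*\* p<0.01, \*\*\*\* p<0.001. No multiple-testing correction is
applied across the 48 screens; the screen is descriptive, the classifier is
the inferential instrument. Inter-rater agreement uses Kendall's
coefficient of concordance with tie correction — essential, since integer
scores on a 4-point scale are heavily tied — with the chi-square
approximation χ² = m(n−1)W for its p-value.

## Classification and evaluation

Four label schemes map the mobility scale onto classification targets: all
four scores; sound (0) vs lame (1–3); little-or-no (0–1) vs clearly lame
(2–3); not-obviously (0–2) vs severely lame (3). The learner is
gradient-boosted decision trees (xgboost, exact greedy splits — midpoint
thresholds generalise better than histogram bin edges at these sample
sizes), depth 4, learning rate 0.1, at most 300 rounds; the boosting
machinery is deliberately a commodity component — the object under test is
the feature set and the evaluation protocol, not the booster.

"Threefold cross-validation" here means three *independent* stratified
80/20 shuffle-splits, each freshly re-drawn, with the three holdout
accuracies averaged — not disjoint 3-fold partitioning, which
`strict_kfold = TRUE` provides as the conventional alternative. Splits are
stratified by class because the severely-lame class is rare (~6%) and
would otherwise vanish from folds; a flag disables stratification. Early
stopping (patience 20 rounds) monitors a further stratified 20% carve-out
of each fold's training portion, so no holdout information reaches
training. Everything downstream of the seed is deterministic: identical
seeds give byte-identical evaluation reports.

Reported per scheme: per-fold and mean ± sd accuracy; the pooled confusion
matrix (truth in rows); Cohen's kappa with the large-sample standard error
under the alternative (the Fleiss–Cohen–Everitt form), a 95% CI of
κ ± 1.96·ASE, and separately the z-test of κ = 0 under the null variance;
macro-averaged precision and recall (the per-class table is also returned,
and a binary positive-class convention is available via the `positive`
argument — macro is the default because single reported values otherwise
hide the rare class). Feature importances are booster gains normalized to
sum 1, sorted, with a running cumulative sum; all-zero importances yield a
flagged uniform fallback. Recursive feature elimination retrains on a
fresh split each iteration, records the holdout error, and drops the
lowest-importance feature until a floor is reached, returning the error
curve and removal order. The per-scorer mode repeats the full protocol
against each individual rater's scores to check that consolidating raters
by averaging does not hide rater-specific structure.

## The synthetic cohort

The simulator generates what the analysis assumes about real footage, with
known ground truth. Each cow's topline is a parabola through two baseline
endpoints whose peak height is a static score-dependent arch amplitude plus
a sinusoidal flexing term over the stride cycle; the head rides ahead of
the scapula at a score-dependent mean elevation with sinusoidal bobbing;
the animal advances at a score-dependent speed; i.i.d. Gaussian jitter
(default sd 1 px) models detection noise. The defaults (arch 0/3/7/12 px,
flex 0.5/1.5/3/6 px, head elevation +25/+10/−5/−25 px, bob 1/3/7/14 px,
speed 6/5/4/2.5 px/frame for scores 0–3, stride 1.2 Hz, 30 fps) encode the
qualitative orderings the field reports — more arching, more flexing, a
lower and more mobile head, slower gait with increasing lameness — at
magnitudes chosen once to be separable but not trivial against the default
noise; the simulator claims correlational structure, not biomechanical
realism. True scores are drawn from a herd-realistic mix
(25.2/43.2/25.6/6.0% for scores 0–3); three simulated raters report the
truth, deviating by ±1 with probability 0.15 (clamped to the scale), with
no systematic bias by default. Single-file sequences stagger cows so their
x-extents stay disjoint for the whole clip even when a faster cow follows
a slower one. `scale_gait_effects()` shrinks all score-dependent effects
about their means — scale 0 yields a null cohort in which every score
produces statistically identical gait.

What passing tests on this cohort do **not** show: robustness to occlusion
and missed detections (the simulator emits complete, always-visible
poses), to cows pausing or crossing, to camera distortion or perspective
foreshortening, or to the real failure modes of a pose estimator (the
jitter is homoscedastic and Gaussian). Simulated raters disagree more
tidily than human scorers, so the concordance measured here is an upper
bound on field inter-rater agreement. Null-cohort evaluations are compared
against the chance-agreement level of the class priors (the sum of squared
prior probabilities — the same chance level Cohen's kappa corrects for),
because a signal-free boosted model fits noise and predicts at roughly the
prior mix rather than collapsing to the majority class.

## Problem sizes and numerical choices

The validation suite works at desk scale: cohorts of 40–250 cows, 25
single-file sequences of up to 10 animals, 30–60 frames (1–2 s of walking
at 30 fps) per sequence — sizes at which every injected effect is
measurable while a full run of tests plus the acceptance script stays in
the minutes. Geometry oracles (brute-force OLS residuals, shoelace
polygon areas, permutation-enumerated assignments) agree with the
implementations to 1e-12/1e-9; ties in RFE's importance ranking break
toward the first-listed feature; degenerate geometry (no x spread,
zero-length baseline, vertical neck segments) is always a reported error,
never a silent NaN.

## Known limitations

The package deliberately stops at the pose-estimation boundary: no video
decoding or pixel inference. Hoof-placement ("tracking-up") and
movement-speed features are not implemented — they depend on the foot
keypoints that real systems detect least reliably. The tracker has no
appearance model and is not intended for animals that pass each other.
Real-data performance claims require real scored video; everything
measured here characterises the pipeline's correctness and its power to
recover effects of the injected size, not on-farm accuracy.
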