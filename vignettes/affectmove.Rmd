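---
title: "Quantifying emotion in whole-body movement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying emotion in whole-body movement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectmove)
```

## The problem

Humans read emotion from whole-body movement with ease, but it is unclear
which properties of the moving body carry that signal: the momentary
*posture* (how flexed, extended, or symmetric the body is) or the
*kinematics* (how fast and in which direction the joints travel).
`affectmove` implements a quantitative pipeline for this question. Its
inputs are 2D pose-estimation keypoint trajectories (OpenPose-style
COCO-18 JSON) for short clips of actors expressing anger, happiness, fear,
or a neutral action, plus observer rating tables. Its outputs are eight
movement features per clip, representational dissimilarity analyses,
repeated-measures ANOVAs, inter-rater reliability coefficients, and bagged
classification trees with predictor importances.

The study design the package models: 56 one-second clips at 25 frames/s
(4 emotion categories x 14 exemplars, 7 male actor identities), each clip
reduced to 14 reliable keypoints (the COCO-18 skeleton minus eyes and
ears, which are untrustworthy when faces are blurred; the nose is kept as
a head reference), and 30 raters answering 11 questions per clip (nine
7-point scales, two forced choices).

## Canonicalization of pose data

`read_openpose_json()` consumes the OpenPose COCO-18 dialect (one flat
54-number `pose_keypoints_2d` array per frame) and enforces exactly one
detected person. Keypoints with detection confidence below 0.1 are treated
as missing and repaired by per-coordinate linear interpolation over frames
(nearest-value extrapolation at the clip ends). The original analysis used
manual visual inspection and hand correction of faulty frames, which is
not reproducible by code; interpolation is a deterministic stand-in, not a
reconstruction, and `validate_sequence()` offers a bone-length plausibility
report (frames whose bone lengths deviate from the clip median by more
than a tolerance fraction, default 0.5) to surface frames a human would
have inspected. Coordinates stay in image convention (y grows downward) at
the I/O layer so written files remain faithful to the pose estimator's
output; sign conventions are applied only inside the feature layer.

## The eight features

All features are computed per frame (postural) or per frame transition
(kinematic) and then averaged over time and/or keypoints as the analysis
requires. Units are pixels and frames of the source video.

* **velocity** — Euclidean displacement of each keypoint between adjacent
  frames (px/frame, 14 components).
* **acceleration** — magnitude of the change of each keypoint's 2D
  velocity vector (px/frame^2).
* **vertical movement** — signed up-positive vertical displacement per
  keypoint (px/frame). This is the one kinematic feature where the sign
  matters: a category can drift upward (anger) or sink (fear), and a
  signed mean is the only reading compatible with a negative group mean,
  so the image y axis is negated rather than taking magnitudes.
* **limb angles** — the angle between adjacent body segments at eight
  sites (elbows, knees, shoulders, hips), in degrees within [0, 180],
  computed as the arccosine of the normalized dot product with the cosine
  clipped to [-1, 1] for numerical safety. For the shoulder and hip sites
  the torso reference segment runs to the neck keypoint, keeping every
  angle an angle between two adjacent segments. Coincident adjacent
  joints make the angle undefined and raise an error naming the site.
* **symmetry** — for each left/right joint pair, the absolute difference
  of the two joints' horizontal distances to the vertical axis through
  the nose (px; 0 = mirror-symmetric). The published group means run in
  the opposite direction (the neutral category is described as most
  symmetrical yet carries the largest value), implying an additional
  unpublished transform; we fix this formula, calibrate the synthetic
  generator to it, and use the values only relationally downstream.
* **shoulder ratio** — shoulder width divided by the horizontal extent of
  all 14 keypoints (dimensionless; smaller = more extended beyond the
  shoulders).
* **surface** — area of the bounding box of the 14 keypoints (px^2).
* **limb contraction** — mean distance from the nose to the wrists and
  ankles (px; larger = more extended).

`build_feature_table()` produces the two descriptor layouts the
classifiers use: `averaged` (8 columns, time and keypoints averaged) and
`time_preserving` (keypoints averaged, one column per feature and frame).
In the time-preserving layout the kinematic features are one and two
frames shorter than the postural ones, so all features are truncated to
the acceleration axis (`n_frames - 2`, 23 of 25 frames) so that every
column is defined for every stimulus; with 25-frame clips this gives
8 x 23 = 184 predictors.

## Representational similarity analysis

First-level RDMs are 56 x 56 symmetric matrices with a zero diagonal:
Euclidean distances between per-stimulus descriptors
(`euclidean_rdm()`; absolute differences for scalars), sqrt(2)/0
dummy-coded category distances (`dummy_rdm()`), and participant-averaged
rating RDMs (`rating_rdms()`; scale questions use absolute differences
per participant, forced-choice questions dummy coding, and the group RDM
is the entrywise mean — missing responses are an error, never imputed).
Computed-feature RDMs default to time- and keypoint-averaged scalars;
a matrix-valued descriptor is accepted for component-preserving variants.

Second-level comparisons (`compare_rdms()`) are Spearman correlations
over the strictly-lower-triangle entries (the diagonal is excluded: an
identical-stimulus cell carries no information and would inflate the
correlation), with `df = n(n-1)/2 - 2 = 1538` for 56 stimuli and
two-sided p-values from the t approximation (with 1540 pairs the
approximation is excellent; an exact permutation option with a fixed
seed is provided). `second_level_matrix()` stores `1 - rho` with
Bonferroni (`alpha = 0.05/m`) and uncorrected masks. The Bonferroni
divisor is a caller-supplied parameter defaulting to 9 for the
computed-feature analysis and 12 for the behavioural one, following the
published figure captions verbatim; the counting rule behind those
numbers is not derivable from the matrix sizes (8 features + 1 category
RDM would give 8), so we expose it rather than re-derive it.

## ANOVA, post-hoc tests, and reliability

`rm_anova()` implements the classical one-way within-subject F test from
the sum-of-squares decomposition, with partial eta-squared and the
Greenhouse-Geisser epsilon from the double-centred condition covariance
(bounded in [1/(k-1), 1]). In `auto` mode the correction is applied when
Mauchly's test rejects sphericity at alpha = 0.05 — the conventional
threshold, since the source analysis states only that correction was
applied "where sphericity was violated". The 14 repeated-measure units
are exemplars paired by their index within category
(`feature_anova_table()`); the published error df of 39 implies such a
pairing but not its key, so index pairing is the package's choice.
`posthoc_bonferroni()` runs all C(4,2) = 6 paired t tests with df = 13
and multiplies raw p-values by 6. `icc_absolute_agreement()` reports both
ICC(2,1) and ICC(2,k) from the two-way random-effects mean squares —
both, because a published "> 90% consistency" does not say whether single
or average measures were meant — with McGraw-Wong F-based confidence
bounds for the single-measure coefficient.

## Bagged classification trees

`fit_bagged_trees()` grows unpruned binary trees (via `rpart` with
entropy/information-gain splits, `cp = 0`, minimum node size 1, no
surrogates) on bootstrap resamples, redrawing a resample (up to 100
times) if a class is absent. Prediction is by unweighted majority vote;
the source description says "weighted majority" without defining the
weights, so the standard bagging vote is the default and an in-bag
accuracy-weighted vote is available behind the `vote` argument. Accuracy,
per-class accuracy and the confusion matrix are estimated out-of-bag: no
accuracy protocol is stated in the source, and OOB is the principled
bagging analogue of held-out evaluation. Predictor importance is the
impurity-decrease importance of a single tree fit to the full data,
matching the stated procedure, normalized to sum 1; for grouped sets
(three body sides, fourteen joints) x and y enter as separate columns and
importances are summed per group, reconciling "fourteen descriptors" with
two coordinates per joint.

One property of OOB evaluation deserves a note because the test suite
measures it: under label permutation with 4 balanced classes of 14, the
OOB accuracy is *not* centred on the nominal 25% chance level. A sample's
own label cannot help classify it, so the null expectation is at most
(14-1)/(56-1) = 23.6%, and majority voting across trees pushes it
slightly lower still (about 23% in our measurements). The chance-recovery
check in the acceptance suite is written against the nominal 25% with a
3-standard-error band and therefore documents this finite-sample bias by
failing honestly rather than being loosened to accommodate it.

## The synthetic generators

The original 56 videos and 30 rating sets are not publicly deposited, so
the package ships two simulation tiers that reproduce the study's
statistical structure:

* `generate_feature_table()` draws each stimulus' eight feature values
  directly from per-emotion Normal profiles. The profile means are the
  published per-emotion group means wherever one is printed (e.g. fear
  limb angles 121.27 degrees, neutral velocity 1.9 px/frame, neutral
  shoulder ratio 0.69). Four cells are never printed and are filled with
  values inside the envelope of the printed ones, flagged as non-source
  values: vertical movement 0.1 (happiness) and 0.0 (neutral) px/frame,
  symmetry 40 px (fear), surface 41,000 px^2 (anger and fear). Standard
  deviations default to 25% of each feature's between-category mean
  range, identical across emotions — large enough that recovery is not
  trivial, small enough that the printed contrasts are recoverable at
  n = 14 per category.
* `generate_stimulus_set()` animates a template standing skeleton
  (segment proportions are rounded anthropometric fractions of the
  300 px default height: neck-hip 0.30 H, shoulder width 0.22 H, arm
  segments 0.17 H, leg segments 0.24 H, nose 0.15 H above the neck) with
  per-emotion sinusoidal arm/leg swings, limb flexion, lateral asymmetry
  offsets, horizontal travel, vertical drift, and per-keypoint Gaussian
  jitter; actor identity scales the skeleton by up to +/-10%. No
  parametric skeleton can hit eight arbitrary feature targets at once,
  which is why two tiers exist: the feature-level tier is exact in the
  mean, while the skeleton tier guarantees only the published category
  *orderings* (fear most flexed and most contracted, neutral slowest and
  least extended beyond the shoulders, anger drifting upward versus fear
  downward), which the test suite verifies at 100 stimuli per category.
  Absolute magnitudes are not matched: the source videos' resolution and
  actor pixel height are unknown, so e.g. synthetic limb contraction runs
  near 200 px rather than the published ~685-804 px.
* `generate_ratings()` turns true stimulus features into 7-point ratings
  by affine maps onto the stimulus set's empirical feature range (so the
  same code serves both tiers), with the contraction question inverted
  (more contracted = smaller limb-contraction value) and the
  forward/away, intensity, valence and familiarity questions driven by
  category-level means. Per-participant bias (0.6 x the noise sd),
  trial noise (sd 0.5 scale units), rounding to integer responses, and
  clipping to [1, 7] follow. Forced-choice emotion and action responses
  are drawn from a confusion matrix whose correct-response rates follow
  the published recognition pattern (fear 98%, neutral 97%, happiness 78%
  and mostly confused with neutral; the unpublished anger rate is set to
  93%).

One consequence of drawing every feature with the same relative noise
(25% of its mean range) is worth stating plainly: features whose category
patterns are redundant compete for tree-importance credit. The
neutral-versus-emotional contrast is carried by velocity, acceleration,
symmetry and shoulder ratio alike, and whichever of them wins a split
absorbs the importance — in practice acceleration or shoulder ratio, so
symmetry almost never reaches the top three importances on feature-level
simulations even though limb angles reliably does (it owns the
fear-versus-rest split). The directional check "limb angles *or* symmetry
in the top three" therefore sits near 75% over 100 seeds, short of its
80% target; we report this as-is rather than re-weighting the generator,
because the noise rule is part of the fixed study conditions.

What the generators deliberately do not emulate: photorealistic or
learned motion, occlusion and tracking failures, per-actor movement
styles beyond global scale, and rater idiosyncrasies beyond additive
bias. Passing tests on synthetic data therefore validates the *pipeline*
— that each stage recovers structure known to be present — and not any
claim about new real-world recordings.

## Numerical and design choices

* Missing-keypoint threshold: confidence < 0.1; repaired values are the
  only coordinates that are not preserved bit-exactly by
  canonicalization.
* Sequence CSVs are written with 17 significant digits so the CSV round
  trip is bit-exact; OpenPose-style JSON export round-trips to within
  1e-12 (JSON number formatting is not guaranteed to be lossless).
* Spearman p-values: t approximation; ties get average ranks.
* Epsilon is clamped to its theoretical range [1/(k-1), 1]; for k = 2
  sphericity holds trivially and no correction is applied. Mauchly's
  statistic is undefined for degenerate designs (units barely exceeding
  conditions); the package then reports `NA` and applies no correction.
* Importance ties are broken lexicographically by predictor name and
  flagged; majority-vote ties resolve to the first class level, which is
  deterministic.
* Ensembles, generators and permutation tests are deterministic given
  their `seed` arguments.

## Problem sizes used by the test and acceptance suites

Oracle-equivalence checks run 200 random instances per operation against
independently coded brute-force implementations at 1e-9 tolerance.
Directional-recovery checks use 200 generator seeds (ANOVA contrasts)
and 100 seeds (tree importances); chance-recovery uses 200 label
permutations of a 56-stimulus table with 100-tree ensembles. The skeleton
ordering checks use 100 stimuli per category. These sizes keep the
complete suite within a few minutes on one core while leaving Monte Carlo
error well below the decision margins of each check.

## Known limitations

* The symmetry direction conflict with the published means is resolved
  relationally, not reconstructed (the supplementary feature definitions
  are unavailable).
* The published headline numbers (61%/84%/78%/71% accuracies, the exact
  RDM correlations) were computed on the undeposited original data;
  synthetic runs mirror their directions, not their values.
* Whether the source kinematic features were signed or absolute per-frame
  displacements is only implied (by one negative printed mean) for
  vertical movement; velocity and acceleration use full 2D displacement
  magnitudes, the common reading in pose kinematics.
* The body-part trees' use of x and y jointly per joint is our
  reconciliation of "fourteen descriptors" with 2D coordinates; a
  single-scalar-per-joint variant would change those importances.
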