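# affectmove

Quantitative analysis of emotion in whole-body movement from 2D pose
keypoints.

People recognise anger, fear or happiness from the way a body moves, but
which properties of the movement carry that signal — the momentary
*posture* (limb flexion, symmetry, extension) or the *kinematics*
(velocity, acceleration, vertical displacement) — is an open question in
affective science. `affectmove` is aimed at researchers in affective
computing and movement science who work with pose-estimation output: it
turns OpenPose-style COCO-18 keypoint sequences into a fixed battery of
eight movement features and relates them to emotion categories and to
observer ratings through the field's standard statistical machinery.

## What it computes

For each clip (frames × 14 canonical keypoints, eyes/ears dropped):

* **Kinematic features** — velocity ‖p_k(t+1) − p_k(t)‖, acceleration
  ‖v_k(t+1) − v_k(t)‖, and signed up-positive vertical movement
  −Δy_k(t), per keypoint and frame transition.
* **Postural features** — limb angles (the angle between adjacent body
  segments at elbows, knees, shoulders, hips, via the arccosine of the
  normalized dot product), symmetry (per joint pair
  ||x_L − x_nose| − |x_R − x_nose||), shoulder ratio (shoulder width /
  horizontal body extent), bounding-box surface, and limb contraction
  (mean wrist/ankle distance to the nose).

Downstream analyses:

* **Representational similarity analysis** — 56×56 Euclidean
  dissimilarity matrices per descriptor, √2/0 dummy-coded category RDMs,
  participant-averaged rating RDMs, and second-level Spearman
  comparisons of RDM lower triangles (ρ with df = n(n−1)/2 − 2 = 1538
  for 56 stimuli) under Bonferroni control.
* **Repeated-measures ANOVA** — one-way within-subject F per feature
  with partial η², Greenhouse-Geisser ε and Mauchly-gated correction,
  plus Bonferroni-corrected paired post-hocs.
* **Inter-rater reliability** — ICC(2,1) and ICC(2,k), two-way random
  effects, absolute agreement.
* **Bagged classification trees** — bootstrap-aggregated entropy-split
  trees grown to purity, out-of-bag accuracy/confusion, and
  impurity-decrease predictor importance from a full-data tree
  (grouped importances for body-side and per-joint predictor sets).
* **Synthetic generators** — a feature-level simulator that draws
  stimuli from per-emotion Normal profiles (means follow the published
  group means), a skeleton-level simulator that animates a parametric
  stick figure whose emergent features preserve the published category
  orderings, and a rating simulator with participant noise and a
  forced-choice confusion structure. These stand in for the original
  (undeposited) 56 videos and 30 raters and make every stage testable.

## Worked example

```r
library(affectmove)

stim     <- generate_stimulus_set(config = generator_config(seed = 1))
features <- build_feature_table(stim, "averaged")

# Does limb flexion differ by emotion? (exemplars paired by index)
rm_anova(feature_anova_table(features, "limb_angles"))
#> Repeated-measures ANOVA: F(3, 39) = 140.515, p = 6.018e-21, partial eta^2 = 0.915

# Which categories drive it? Fear is the most flexed (smallest angles):
ph <- posthoc_bonferroni(feature_anova_table(features, "limb_angles"))
ph[ph$condition_b == "fear", c(1, 2, 3, 4, 7)]
#>   condition_a condition_b mean_diff    t p_bonferroni
#> 3       anger        fear      18.1 13.1     4.41e-08
#> 5   happiness        fear      23.1 18.7     5.22e-10
#> 6     neutral        fear      21.7 20.4     1.81e-10

# How categorical is the limb-angle representation? (second-level RSA)
emo <- dummy_rdm(features$emotion, ids = features$stimulus_id)
la  <- euclidean_rdm(feature_matrix(features)[, "limb_angles"],
                     ids = features$stimulus_id, source = "limb_angles")
compare_rdms(la, emo, m = 9)
#> <rdm_comparison> limb_angles ~ emotion: rho(1538) = 0.439, p = 1.56e-73 (Bonferroni x9: 1.404e-72)

# Classify emotion from the eight features:
fit <- fit_bagged_trees(build_predictor_set(features, "features_averaged"),
                        n_trees = 100, seed = 2)
fit
#> <tree_ensemble_report> features_averaged: 100 trees, OOB accuracy 98.2% (chance 25.0%)
#> Per-class accuracy: anger 93%, fear 100%, happiness 100%, neutral 100%
#> Top predictors: symmetry (0.50), velocity (0.25), vertical_movement (0.25)
```

Reading the numbers: the ANOVA F with error df 39 comes from 14 exemplar
units × 4 emotion levels; every post-hoc contrast pits fear's flexed
limbs (mean angle ≈ 18–23° smaller) against the other categories at
df = 13; the RDM correlation of 0.439 over 1540 stimulus pairs says the
limb-angle geometry partially mirrors the categorical structure; and the
out-of-bag accuracy of 98.2% on clean synthetic skeletons is measured on
stimuli each tree never saw during its bootstrap (real video data are far
noisier — published accuracies on comparable designs are 61–84%).

The whole pipeline (simulate → extract → RSA → ANOVA → ICC → classify,
with CSV/JSON artifacts and a manifest) runs from one call:

```r
run_pipeline(pipeline_config(mode = "synthetic", out_dir = "run1", seed = 1))
```

or from the shell via `Rscript inst/cli/affectmove.R all --out run1 --seed 1`.

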