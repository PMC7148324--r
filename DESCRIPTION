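Package: affectmove
Title: Kinematic and Postural Feature Analysis of Emotional Body Movements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of emotional whole-body movement from 2D
    pose-estimation keypoints. Reads OpenPose-style COCO-18 keypoint
    sequences, computes three kinematic (velocity, acceleration, vertical
    movement) and five postural (limb angles, symmetry, shoulder ratio,
    bounding-box surface, limb contraction) features, and relates them to
    emotion categories through representational similarity analysis,
    repeated-measures ANOVA with Greenhouse-Geisser correction, intraclass
    correlation for inter-rater reliability, and bagged classification
    trees with impurity-based predictor importance. Includes a synthetic
    skeleton-motion and behavioural-rating generator so the full pipeline
    can be exercised and validated without access to original video
    stimuli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rpart,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
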