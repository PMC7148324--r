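# In-code fixtures shared across test files.

random_sequence <- function(n_frames = 10, id = "stim", emotion = "anger",
                            lo = 0, hi = 200) {
  coords <- array(stats::runif(n_frames * 14 * 2, lo, hi),
                  c(n_frames, 14, 2))
  pose_sequence(coords, id, emotion)
}

# upright stick figure with straight arms/legs; no degenerate angles
template_skeleton_frame <- function(cx = 100, cy = 100) {
  H <- 200
  neck <- c(cx, cy)
  rbind(nose = neck + c(0, -0.15 * H),
        neck = neck,
        r_shoulder = neck + c(-0.11 * H, 0),
        r_elbow = neck + c(-0.13 * H, 0.17 * H),
        r_wrist = neck + c(-0.15 * H, 0.34 * H),
        l_shoulder = neck + c(0.11 * H, 0),
        l_elbow = neck + c(0.13 * H, 0.17 * H),
        l_wrist = neck + c(0.15 * H, 0.34 * H),
        r_hip = neck + c(-0.06 * H, 0.30 * H),
        r_knee = neck + c(-0.07 * H, 0.54 * H),
        r_ankle = neck + c(-0.08 * H, 0.78 * H),
        l_hip = neck + c(0.06 * H, 0.30 * H),
        l_knee = neck + c(0.07 * H, 0.54 * H),
        l_ankle = neck + c(0.08 * H, 0.78 * H))
}

skeleton_sequence <- function(n_frames = 5, shift = c(0, 0), id = "stick",
                              emotion = "neutral") {
  f <- template_skeleton_frame()
  coords <- array(NA_real_, c(n_frames, 14, 2))
  for (t in seq_len(n_frames)) {
    coords[t, , 1] <- f[, 1] + (t - 1) * shift[1]
    coords[t, , 2] <- f[, 2] + (t - 1) * shift[2]
  }
  pose_sequence(coords, id, emotion)
}

# raw OpenPose-style 18-keypoint array from a canonical 14-keypoint frame
raw18_from14 <- function(coords14, conf = 1) {
  nf <- dim(coords14)[1]
  raw <- array(0, c(nf, 18, 3))
  raw[, 1:14, 1:2] <- coords14
  raw[, 1:14, 3] <- conf
  # junk eyes/ears with high confidence: must be ignored regardless
  raw[, 15:18, 1:2] <- 9999
  raw[, 15:18, 3] <- 1
  raw
}

write_openpose_fixture <- function(seq, path) {
  write_openpose_json(seq, path)
  path
}

transform_sequence <- function(seq, scale = 1, angle = 0, shift = c(0, 0),
                               mirror = FALSE) {
  co <- seq$coords
  out <- co
  for (t in seq_len(seq$n_frames)) {
    xy <- co[t, , ]
    if (mirror) xy[, 1] <- -xy[, 1]
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
    xy <- scale * (xy %*% t(R))
    xy[, 1] <- xy[, 1] + shift[1]
    xy[, 2] <- xy[, 2] + shift[2]
    out[t, , ] <- xy
  }
  pose_sequence(out, seq$stimulus_id, seq$emotion, seq$actor_id, seq$fps)
}

# swap left/right keypoint components to relabel a mirrored skeleton
mirror_relabel <- function(seq) {
  kp <- canonical_keypoints()
  swap <- kp
  for (i in seq_along(kp)) {
    if (startsWith(kp[i], "l_")) swap[i] <- sub("^l_", "r_", kp[i])
    if (startsWith(kp[i], "r_")) swap[i] <- sub("^r_", "l_", kp[i])
  }
  co <- seq$coords
  co2 <- co
  co2[, match(swap, kp), ] <- co
  co2[, , 1] <- -co2[, , 1] + 400   # mirror about x = 200
  pose_sequence(co2, seq$stimulus_id, seq$emotion, seq$actor_id, seq$fps)
}

# printed group means used as directional references by several suites
printed_contrasts <- function() {
  list(
    velocity = list(c("anger", "neutral", 1), c("happiness", "neutral", 1),
                    c("fear", "neutral", 1)),
    acceleration = list(c("anger", "neutral", 1), c("happiness", "neutral", 1),
                        c("fear", "neutral", 1)),
    vertical_movement = list(c("anger", "fear", 1)),
    limb_angles = list(c("anger", "fear", 1), c("happiness", "fear", 1),
                       c("neutral", "fear", 1)),
    symmetry = list(c("anger", "neutral", -1), c("happiness", "neutral", -1)),
    shoulder_ratio = list(c("anger", "neutral", -1),
                          c("happiness", "neutral", -1),
                          c("fear", "neutral", -1)),
    surface = list(c("happiness", "neutral", 1)),
    limb_contraction = list(c("anger", "fear", 1), c("happiness", "fear", 1),
                            c("neutral", "fear", 1)))
}

# does one generated feature table recover every printed contrast?
recovers_contrasts <- function(ft, alpha = 0.05) {
  for (f in names(printed_contrasts())) {
    tab <- feature_anova_table(ft, f)
    an <- rm_anova(tab, correct = "auto")
    if (an$p >= alpha) return(FALSE)
    ph <- posthoc_bonferroni(tab)
    for (ct in printed_contrasts()[[f]]) {
      row <- ph[(ph$condition_a == ct[1] & ph$condition_b == ct[2]) |
                (ph$condition_a == ct[2] & ph$condition_b == ct[1]), ]
      d <- if (row$condition_a == ct[1]) row$mean_diff else -row$mean_diff
      if (row$p_bonferroni >= alpha || sign(d) != as.numeric(ct[3]))
        return(FALSE)
    }
  }
  TRUE
}
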