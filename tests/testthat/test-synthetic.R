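test_that("default profiles carry the published per-emotion feature means", {
  p <- default_profiles()
  expect_equal(p$fear$feature_means[["limb_angles"]], 121.27)
  expect_equal(p$neutral$feature_means[["shoulder_ratio"]], 0.69)
  expect_equal(p$anger$feature_means[["vertical_movement"]], 0.39)
  expect_equal(p$fear$feature_means[["vertical_movement"]], -0.28)
  expect_equal(p$neutral$feature_means[["velocity"]], 1.9)
  expect_equal(p$happiness$feature_means[["velocity"]], 3.71)
  expect_equal(p$neutral$feature_means[["symmetry"]], 50.68)
  expect_equal(p$fear$feature_means[["limb_contraction"]], 684.63)
  expect_equal(p$happiness$feature_means[["surface"]], 47054.6)
  # identical sds across emotions: a quarter of the between-category range
  expect_equal(p$anger$feature_sds[["velocity"]], 0.25 * (3.71 - 1.9))
  expect_equal(p$fear$feature_sds, p$neutral$feature_sds)
})

test_that("profile invariants are enforced", {
  p <- default_profiles()$anger
  expect_error(emotion_profile("anger", p$feature_means,
                               replace(p$feature_sds, 1, -1),
                               p$motion_params),
               class = "affectmove_config_error")
  mp <- p$motion_params; mp$swing_freq <- 0
  expect_error(emotion_profile("anger", p$feature_means, p$feature_sds, mp),
               class = "affectmove_config_error")
  mp <- p$motion_params; mp$limb_flexion <- 190
  expect_error(emotion_profile("anger", p$feature_means, p$feature_sds, mp),
               class = "affectmove_config_error")
  expect_error(generator_config(n_per_category = 4, n_actors = 7),
               class = "affectmove_config_error")
})

test_that("feature-level generator is deterministic, balanced, and exact at sd 0", {
  ft1 <- generate_feature_table(config = generator_config(seed = 123))
  ft2 <- generate_feature_table(config = generator_config(seed = 123))
  expect_identical(ft1, ft2)
  expect_identical(nrow(ft1), 56L)
  expect_identical(unname(tabulate(match(ft1$emotion, emotion_levels()))),
                   rep(14L, 4))

  p0 <- default_profiles()
  for (e in emotion_levels()) p0[[e]]$feature_sds[] <- 0
  ft0 <- generate_feature_table(p0, generator_config(seed = 1))
  for (e in emotion_levels()) {
    rows <- feature_matrix(ft0)[ft0$emotion == e, , drop = FALSE]
    for (f in feature_names())
      expect_equal(unname(rows[, f]),
                   rep(p0[[e]]$feature_means[[f]], 14), tolerance = 1e-12)
  }
})

test_that("skeleton generator emits the full design and is seed-deterministic", {
  cfg <- generator_config(seed = 42)
  st <- generate_stimulus_set(config = cfg)
  expect_length(st, 56L)
  expect_identical(st$n_frames, 25)
  expect_identical(dim(st$sequences[[1]]$coords), c(25L, 14L, 2L))
  expect_identical(unname(as.integer(st$category_counts)), rep(14L, 4))
  st2 <- generate_stimulus_set(config = cfg)
  expect_identical(st$sequences[["fear_07"]]$coords,
                   st2$sequences[["fear_07"]]$coords)
  expect_error(generate_stimulus_set(config = generator_config(n_frames = 2)),
               class = "affectmove_config_error")
})

test_that("a motionless configuration yields (near-)zero velocity", {
  p <- default_profiles()
  for (e in emotion_levels()) {
    p[[e]]$motion_params$swing_amp <- 0
    p[[e]]$motion_params$speed_scale <- 0
    p[[e]]$motion_params$vertical_drift <- 0
  }
  st <- generate_stimulus_set(p, generator_config(n_per_category = 2,
                                                  n_actors = 1, jitter_sd = 0,
                                                  seed = 3))
  for (s in st$sequences)
    expect_lt(feature_scalar(s, "velocity"), 1e-9)
})

test_that("generated features preserve the published category orderings", {
  cfg <- generator_config(n_per_category = 100, n_actors = 7, seed = 77)
  st <- generate_stimulus_set(config = cfg)
  ft <- build_feature_table(st, "averaged")
  fm <- feature_matrix(ft)
  mean_by <- function(f) tapply(fm[, f], ft$emotion, mean)[emotion_levels()]

  la <- mean_by("limb_angles")
  expect_true(la[["fear"]] < min(la[c("anger", "happiness", "neutral")]))
  v <- mean_by("velocity")
  expect_true(v[["neutral"]] < min(v[c("anger", "happiness", "fear")]))
  a <- mean_by("acceleration")
  expect_true(a[["neutral"]] < min(a[c("anger", "happiness", "fear")]))
  sr <- mean_by("shoulder_ratio")
  expect_true(sr[["neutral"]] > max(sr[c("anger", "happiness", "fear")]))
  lc <- mean_by("limb_contraction")
  expect_true(lc[["fear"]] < min(lc[c("anger", "happiness", "neutral")]))
  vm <- mean_by("vertical_movement")
  expect_gt(vm[["anger"]], vm[["fear"]])
})

test_that("rating generator matches the design counts and is deterministic", {
  ft <- generate_feature_table(config = generator_config(seed = 9))
  rt <- generate_ratings(ft, rating_generator_config(seed = 10))
  expect_identical(nrow(rt), 30L * 56L * 11L)  # 18,480 responses
  rt2 <- generate_ratings(ft, rating_generator_config(seed = 10))
  expect_identical(as.data.frame(rt), as.data.frame(rt2))
  expect_setequal(unique(rt$question),
                  c(rating_questions()$scale, rating_questions()$categorical))
})

test_that("zero noise and identity confusion give perfect agreement", {
  ft <- generate_feature_table(config = generator_config(seed = 11))
  cfg <- rating_generator_config(participant_noise_sd = 0,
                                 confusion = diag(4), seed = 12)
  rt <- generate_ratings(ft, cfg)
  m <- rating_matrix(rt, "amount")
  for (p in 2:nrow(m)) expect_identical(m[p, ], m[1, ])
  icc <- icc_absolute_agreement(m)
  expect_equal(icc$icc_single, 1)
  expect_equal(icc$icc_average, 1)
  # forced-choice responses equal the true category
  emo <- rt[rt$question == "emotion", ]
  expect_identical(emo$choice, emo$emotion)
})

test_that("happy stimuli keep 'happy' as modal response under the default confusion", {
  ft <- generate_feature_table(config = generator_config(seed = 13))
  rt <- generate_ratings(ft, rating_generator_config(seed = 14))
  emo <- rt[rt$question == "emotion" & rt$emotion == "happiness", ]
  tab <- sort(table(emo$choice), decreasing = TRUE)
  expect_identical(names(tab)[1], "happiness")
  # and the correct-response rate is near the configured 78%
  expect_gt(mean(emo$choice == "happiness"), 0.65)
  expect_lt(mean(emo$choice == "happiness"), 0.9)
  expect_error(rating_generator_config(confusion = matrix(1, 4, 4)),
               class = "affectmove_config_error")
})
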