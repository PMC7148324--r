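test_that("canonical predictor sets have the documented shapes and exclusions", {
  cfg <- generator_config(n_per_category = 3, n_actors = 1, n_frames = 10,
                          seed = 61)
  st <- generate_stimulus_set(config = cfg)
  ps_avg <- build_predictor_set(st, "features_averaged")
  expect_identical(dim(ps_avg$x), c(12L, 8L))
  ps_tp <- build_predictor_set(st, "features_time_preserving")
  expect_identical(ncol(ps_tp$x), 8L * 8L)       # 10 frames -> 8 kept

  ft <- generate_feature_table(config = generator_config(seed = 62))
  rt <- generate_ratings(ft, rating_generator_config(n_participants = 4,
                                                     seed = 63))
  ps9 <- build_predictor_set(rt, "ratings_nine")
  expect_identical(ncol(ps9$x), 9L)
  ps6 <- build_predictor_set(rt, "ratings_six")
  expect_identical(ncol(ps6$x), 6L)
  expect_setequal(setdiff(colnames(ps9$x), colnames(ps6$x)),
                  c("intensity", "valence", "familiarity"))
  expect_false(any(c("emotion", "action") %in% colnames(ps9$x)))

  ps3 <- build_predictor_set(st, "bodyside_three")
  expect_identical(ncol(ps3$x), 6L)
  expect_identical(unname(sort(unique(ps3$groups))),
                   c("centre", "left", "right"))
  ps14 <- build_predictor_set(st, "joints_fourteen")
  expect_identical(ncol(ps14$x), 28L)
  expect_identical(length(unique(ps14$groups)), 14L)

  expect_error(build_predictor_set(st, "ratings_nine"),
               class = "affectmove_data_error")
})

test_that("a perfectly separating predictor dominates accuracy and importance", {
  set.seed(64)
  labels <- rep(emotion_levels(), each = 14)
  sep <- rep(c(0, 10, 20, 30), each = 14) + stats::runif(56, 0, 1)
  noise <- matrix(stats::rnorm(56 * 3), 56, 3,
                  dimnames = list(NULL, c("n1", "n2", "n3")))
  ps <- predictor_set(cbind(sep = sep, noise), labels, "sep")
  rep1 <- fit_bagged_trees(ps, n_trees = 100, seed = 1)
  expect_gte(rep1$oob_accuracy, 0.95)
  expect_equal(unname(rep1$importances["sep"]), 1, tolerance = 1e-12)
  expect_identical(importance_ranking(rep1)$predictor[1], "sep")
})

test_that("ensembles are deterministic given a seed", {
  ft <- generate_feature_table(config = generator_config(seed = 65))
  ps <- build_predictor_set(ft, "features_averaged")
  a <- fit_bagged_trees(ps, n_trees = 30, seed = 7)
  b <- fit_bagged_trees(ps, n_trees = 30, seed = 7)
  expect_identical(a$oob_accuracy, b$oob_accuracy)
  expect_identical(a$importances, b$importances)
  expect_identical(a$confusion, b$confusion)
  c <- fit_bagged_trees(ps, n_trees = 30, seed = 8)
  expect_false(identical(a$confusion, c$confusion))
})

test_that("confusion rows sum to per-class OOB counts and accuracy is bounded", {
  ft <- generate_feature_table(config = generator_config(seed = 66))
  ps <- build_predictor_set(ft, "features_averaged")
  r <- fit_bagged_trees(ps, n_trees = 50, seed = 2)
  expect_true(r$oob_accuracy >= 0 && r$oob_accuracy <= 1)
  expect_identical(sum(r$confusion), r$n_oob_covered)
  expect_equal(sum(r$importances), 1, tolerance = 1e-12)
  expect_true(all(r$importances >= 0))
  expect_equal(unname(diag(r$confusion) / rowSums(r$confusion)),
               unname(r$per_class_accuracy))
})

test_that("duplicated predictors share importance without changing accuracy", {
  ft <- generate_feature_table(config = generator_config(seed = 67))
  ps <- build_predictor_set(ft, "features_averaged")
  x2 <- cbind(ps$x, limb_angles_copy = ps$x[, "limb_angles"])
  ps2 <- predictor_set(x2, ps$labels, "dup")
  r1 <- fit_bagged_trees(ps, n_trees = 40, seed = 3)
  r2 <- fit_bagged_trees(ps2, n_trees = 40, seed = 3)
  expect_equal(r2$oob_accuracy, r1$oob_accuracy, tolerance = 1e-12)
  expect_equal(unname(r2$importances["limb_angles"] +
                      r2$importances["limb_angles_copy"]),
               unname(r1$importances["limb_angles"]), tolerance = 1e-9)
  others <- setdiff(names(r1$importances), "limb_angles")
  expect_equal(r2$importances[others], r1$importances[others],
               tolerance = 1e-9)
})

test_that("grouped sets report one importance per group", {
  cfg <- generator_config(n_per_category = 4, n_actors = 2, n_frames = 8,
                          seed = 68)
  st <- generate_stimulus_set(config = cfg)
  r14 <- fit_bagged_trees(build_predictor_set(st, "joints_fourteen"),
                          n_trees = 20, seed = 4)
  expect_identical(length(r14$importances), 14L)
  expect_identical(nrow(importance_ranking(r14)), 14L)
  r3 <- fit_bagged_trees(build_predictor_set(st, "bodyside_three"),
                         n_trees = 20, seed = 4)
  expect_setequal(names(r3$importances), c("centre", "left", "right"))
})

test_that("importance ranking recovers a construction-controlled postural signal", {
  # postural means diverge across categories, kinematic means equal
  p <- default_profiles()
  for (e in emotion_levels()) {
    p[[e]]$feature_means[c("velocity", "acceleration", "vertical_movement")] <-
      c(3, 4, 0.1)
  }
  ft <- generate_feature_table(p, generator_config(seed = 69))
  r <- fit_bagged_trees(build_predictor_set(ft, "features_averaged"),
                        n_trees = 20, seed = 5)
  top <- importance_ranking(r)$predictor[1]
  expect_true(top %in% c("limb_angles", "symmetry", "shoulder_ratio",
                         "surface", "limb_contraction"))
})

test_that("model comparison ranks by OOB accuracy and checks labels", {
  ft <- generate_feature_table(config = generator_config(seed = 70))
  ps <- build_predictor_set(ft, "features_averaged")
  r1 <- fit_bagged_trees(ps, n_trees = 30, seed = 6)
  set.seed(71)
  perm <- predictor_set(ps$x, sample(ps$labels), "permuted")
  r2 <- fit_bagged_trees(perm, n_trees = 30, seed = 6)
  expect_error(compare_models(list(a = r1, b = r2)),
               class = "affectmove_data_error")  # labels differ

  cmp <- compare_models(list(real = r1, self = r1))
  expect_true(all(cmp$tied))

  r3 <- fit_bagged_trees(predictor_set(ps$x[, "velocity", drop = FALSE],
                                       ps$labels, "velocity_only"),
                         n_trees = 30, seed = 6)
  cmp2 <- compare_models(list(full = r1, one_feature = r3))
  expect_identical(cmp2$model[cmp2$rank == 1][1], "full")
})

test_that("ensemble predictions work on new data", {
  ft <- generate_feature_table(config = generator_config(seed = 72))
  ps <- build_predictor_set(ft, "features_averaged")
  r <- fit_bagged_trees(ps, n_trees = 50, seed = 9)
  pred <- predict(r, ps$x)
  expect_identical(length(pred), nrow(ps$x))
  # resubstitution on trees grown to purity is near-perfect
  expect_gte(mean(as.character(pred) == ps$labels), 0.95)
})
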