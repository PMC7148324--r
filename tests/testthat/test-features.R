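make_seq <- function(frames) {
  # frames: list of 14x2 matrices
  co <- array(NA_real_, c(length(frames), 14, 2))
  for (t in seq_along(frames)) co[t, , ] <- frames[[t]]
  pose_sequence(co, "t", "anger")
}

test_that("velocity matches hand-computed displacements and edge cases", {
  f <- template_skeleton_frame()
  f2 <- f; f2["r_wrist", ] <- f["r_wrist", ] + c(3, 4)
  s <- make_seq(list(f, f2))
  v <- compute_velocity(s)
  expect_equal(unname(v$values[1, "r_wrist"]), 5)        # 3-4-5 triangle
  expect_equal(sum(v$values[1, -5]), 0)          # everything else static
  expect_error(compute_velocity(make_seq(list(f))),
               class = "affectmove_data_error")
  static <- skeleton_sequence(6)
  expect_true(all(compute_velocity(static)$values == 0))
})

test_that("acceleration is zero under uniform motion and spikes at speed changes", {
  s <- skeleton_sequence(8, shift = c(2, 1))     # constant velocity vector
  expect_true(all(abs(compute_acceleration(s)$values) < 1e-12))

  f <- template_skeleton_frame()
  f3 <- f; f3["l_wrist", ] <- f["l_wrist", ] + c(0, 5)
  s2 <- make_seq(list(f, f, f3))                 # rest then a 5 px jump
  a <- compute_acceleration(s2)
  expect_equal(unname(a$values[1, "l_wrist"]), 5)
})

test_that("vertical movement is signed and up-positive", {
  f <- template_skeleton_frame()
  f2 <- f; f2[, 2] <- f[, 2] - 3                 # image y decreases: upward
  vm <- compute_vertical_movement(make_seq(list(f, f2)))
  expect_true(all(vm$values == 3))
  f3 <- f; f3[, 1] <- f[, 1] + 10                # horizontal-only motion
  expect_true(all(compute_vertical_movement(make_seq(list(f, f3)))$values == 0))
})

test_that("limb angles reproduce straight and right-angle configurations", {
  f <- template_skeleton_frame()
  # straight right arm along +x from shoulder
  f["r_shoulder", ] <- c(0, 0); f["r_elbow", ] <- c(1, 0); f["r_wrist", ] <- c(2, 0)
  a <- compute_limb_angles(make_seq(list(f)))
  expect_equal(unname(a$values[1, "r_elbow"]), 180)
  f["r_wrist", ] <- c(1, 1)                      # right angle at the elbow
  a2 <- compute_limb_angles(make_seq(list(f)))
  expect_equal(unname(a2$values[1, "r_elbow"]), 90)
  expect_true(all(a2$values >= 0 & a2$values <= 180))

  f["r_wrist", ] <- f["r_elbow", ]               # coincident joints
  expect_error(compute_limb_angles(make_seq(list(f))), "r_elbow",
               class = "affectmove_data_error")
})

test_that("limb angles are invariant to translation, rotation and scaling", {
  set.seed(21)
  s <- random_sequence(4)
  base <- compute_limb_angles(s)$values
  tr <- compute_limb_angles(transform_sequence(s, shift = c(37, -12)))$values
  ro <- compute_limb_angles(transform_sequence(s, angle = 0.7))$values
  sc <- compute_limb_angles(transform_sequence(s, scale = 3.2))$values
  expect_equal(tr, base, tolerance = 1e-9)
  expect_equal(ro, base, tolerance = 1e-9)
  expect_equal(sc, base, tolerance = 1e-9)
})

test_that("symmetry measures pairwise asymmetry about the nose axis", {
  f <- template_skeleton_frame()
  nose_x <- f["nose", 1]
  f["l_wrist", 1] <- nose_x + 5; f["r_wrist", 1] <- nose_x - 5
  sy <- compute_symmetry(make_seq(list(f)))
  expect_equal(unname(sy$values[1, "wrist"]), 0)          # mirror pose
  f["l_wrist", 1] <- nose_x + 2; f["r_wrist", 1] <- nose_x - 6
  sy2 <- compute_symmetry(make_seq(list(f)))
  expect_equal(unname(sy2$values[1, "wrist"]), 4)         # |2 - 6|
})

test_that("mirror reflection leaves bilateral features unchanged and swaps angle sides", {
  set.seed(22)
  s <- random_sequence(5)
  m <- mirror_relabel(s)
  expect_equal(compute_symmetry(m)$values, compute_symmetry(s)$values,
               tolerance = 1e-9)
  expect_equal(compute_shoulder_ratio(m)$values,
               compute_shoulder_ratio(s)$values, tolerance = 1e-9)
  expect_equal(compute_surface(m)$values, compute_surface(s)$values,
               tolerance = 1e-9)
  expect_equal(compute_limb_contraction(m)$values,
               compute_limb_contraction(s)$values, tolerance = 1e-9)
  am <- compute_limb_angles(m)$values
  as <- compute_limb_angles(s)$values
  swap <- c("l_elbow", "r_elbow", "l_knee", "r_knee",
            "l_shoulder", "r_shoulder", "l_hip", "r_hip")
  expect_equal(unname(am[, swap]), unname(as), tolerance = 1e-9)
})

test_that("shoulder ratio and surface follow their geometric definitions", {
  f <- template_skeleton_frame()
  # squeeze all x inside the shoulder span -> extent equals shoulder width
  sw <- abs(f["l_shoulder", 1] - f["r_shoulder", 1])
  f[, 1] <- pmin(pmax(f[, 1], f["r_shoulder", 1]), f["l_shoulder", 1])
  f["l_shoulder", 2] <- f["r_shoulder", 2]       # level shoulders
  sr <- compute_shoulder_ratio(make_seq(list(f)))
  expect_equal(unname(sr$values[1, 1]), 1)
  # arms stretched to double the shoulder span
  f["l_wrist", 1] <- f["l_shoulder", 1] + sw / 2
  f["r_wrist", 1] <- f["r_shoulder", 1] - sw / 2
  expect_equal(unname(compute_shoulder_ratio(make_seq(list(f)))$values[1, 1]), 0.5)

  g <- matrix(0, 14, 2)
  g[, 1] <- seq(0, 10, length.out = 14)
  g[, 2] <- seq(0, 20, length.out = 14)
  expect_equal(unname(compute_surface(make_seq(list(g)))$values[1, 1]), 200)
  # translation invariance and quadratic scaling
  s <- random_sequence(3)
  expect_equal(compute_surface(transform_sequence(s, shift = c(9, 9)))$values,
               compute_surface(s)$values, tolerance = 1e-9)
  expect_equal(compute_surface(transform_sequence(s, scale = 2))$values,
               4 * compute_surface(s)$values, tolerance = 1e-9)
})

test_that("limb contraction averages extremity-to-nose distances", {
  f <- template_skeleton_frame()
  f["nose", ] <- c(0, 0)
  f["l_wrist", ] <- c(100, 0); f["r_wrist", ] <- c(0, 100)
  f["l_ankle", ] <- c(-100, 0); f["r_ankle", ] <- c(0, -100)
  expect_equal(unname(compute_limb_contraction(make_seq(list(f)))$values[1, 1]), 100)
  f["l_wrist", ] <- c(50, 0); f["r_wrist", ] <- c(0, 50)
  f["l_ankle", ] <- c(-150, 0); f["r_ankle", ] <- c(0, -150)
  expect_equal(unname(compute_limb_contraction(make_seq(list(f)))$values[1, 1]), 100)
})

test_that("kinematic features scale linearly and translate invariantly", {
  set.seed(23)
  s <- random_sequence(6)
  for (fun in list(compute_velocity, compute_acceleration)) {
    expect_equal(fun(transform_sequence(s, shift = c(11, -4)))$values,
                 fun(s)$values, tolerance = 1e-9)
    expect_equal(fun(transform_sequence(s, scale = 2.5))$values,
                 2.5 * fun(s)$values, tolerance = 1e-9)
  }
  expect_equal(compute_symmetry(transform_sequence(s, shift = c(5, 5)))$values,
               compute_symmetry(s)$values, tolerance = 1e-9)
})

test_that("every feature matches its brute-force oracle on random sequences", {
  set.seed(24)
  for (i in 1:25) {
    s <- random_sequence(sample(3:12, 1))
    expect_equal(unname(compute_velocity(s)$values), orc_velocity(s),
                 tolerance = 1e-9)
    expect_equal(unname(compute_acceleration(s)$values), orc_acceleration(s),
                 tolerance = 1e-9)
    expect_equal(unname(compute_vertical_movement(s)$values), orc_vertical(s),
                 tolerance = 1e-9)
    expect_equal(unname(compute_limb_angles(s)$values), orc_limb_angles(s),
                 tolerance = 1e-9)
    expect_equal(unname(compute_symmetry(s)$values), orc_symmetry(s),
                 tolerance = 1e-9)
    expect_equal(unname(compute_shoulder_ratio(s)$values[, 1]),
                 orc_shoulder_ratio(s), tolerance = 1e-9)
    expect_equal(unname(compute_surface(s)$values[, 1]), orc_surface(s),
                 tolerance = 1e-9)
    expect_equal(unname(compute_limb_contraction(s)$values[, 1]),
                 orc_contraction(s), tolerance = 1e-9)
  }
})

test_that("aggregation means commute and preserve constants", {
  set.seed(25)
  s <- random_sequence(8)
  v <- compute_velocity(s)
  tc <- aggregate_series(aggregate_series(v, TRUE, FALSE), FALSE, TRUE)
  ct <- aggregate_series(aggregate_series(v, FALSE, TRUE), TRUE, FALSE)
  expect_equal(as.numeric(tc$values), as.numeric(ct$values), tolerance = 1e-12)
  expect_equal(as.numeric(tc$values), mean(v$values), tolerance = 1e-12)

  const <- v; const$values[] <- 4.2
  expect_equal(as.numeric(aggregate_series(const)$values), 4.2)
  # aggregating an already-scalar axis is a no-op, not an error
  expect_equal(as.numeric(aggregate_series(aggregate_series(v))$values),
               mean(v$values), tolerance = 1e-12)
})

test_that("feature tables have the documented shapes and agree with aggregate()", {
  set.seed(26)
  cfg <- generator_config(n_per_category = 2, n_actors = 1, n_frames = 25,
                          seed = 7)
  st <- generate_stimulus_set(config = cfg)
  ft <- build_feature_table(st, "averaged")
  expect_identical(dim(feature_matrix(ft)), c(8L, 8L))
  s1 <- st$sequences[[ft$stimulus_id[1]]]
  expect_equal(ft$velocity[1], feature_scalar(s1, "velocity"),
               tolerance = 1e-12)
  expect_equal(ft$limb_angles[1], feature_scalar(s1, "limb_angles"),
               tolerance = 1e-12)

  tp <- build_feature_table(st, "time_preserving")
  expect_identical(ncol(feature_matrix(tp)), 8L * 23L)  # truncated to n - 2

  # mixed frame counts are rejected at set construction
  a <- random_sequence(5, id = "a"); b <- random_sequence(6, id = "b")
  expect_error(stimulus_set(list(a, b)), class = "affectmove_data_error")
})
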