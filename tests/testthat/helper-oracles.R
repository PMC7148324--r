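# Independent brute-force oracles: naive loops and textbook formulas, kept
# deliberately separate from the package's vectorized implementations.

orc_velocity <- function(seq) {
  co <- seq$coords
  out <- matrix(NA_real_, seq$n_frames - 1L, 14L)
  for (t in seq_len(seq$n_frames - 1L)) for (k in 1:14) {
    dx <- co[t + 1, k, 1] - co[t, k, 1]
    dy <- co[t + 1, k, 2] - co[t, k, 2]
    out[t, k] <- sqrt(dx^2 + dy^2)
  }
  out
}

orc_acceleration <- function(seq) {
  co <- seq$coords
  out <- matrix(NA_real_, seq$n_frames - 2L, 14L)
  for (t in seq_len(seq$n_frames - 2L)) for (k in 1:14) {
    v1 <- c(co[t + 1, k, 1] - co[t, k, 1], co[t + 1, k, 2] - co[t, k, 2])
    v2 <- c(co[t + 2, k, 1] - co[t + 1, k, 1], co[t + 2, k, 2] - co[t + 1, k, 2])
    out[t, k] <- sqrt(sum((v2 - v1)^2))
  }
  out
}

orc_vertical <- function(seq) {
  co <- seq$coords
  out <- matrix(NA_real_, seq$n_frames - 1L, 14L)
  for (t in seq_len(seq$n_frames - 1L)) for (k in 1:14)
    out[t, k] <- -(co[t + 1, k, 2] - co[t, k, 2])
  out
}

# angle via atan2 of the two segment bearings (different route than the
# package's arccos of the normalized dot product)
orc_angle <- function(a, b, c) {
  th1 <- atan2(a[2] - b[2], a[1] - b[1])
  th2 <- atan2(c[2] - b[2], c[1] - b[1])
  d <- abs(th1 - th2) %% (2 * pi)
  if (d > pi) d <- 2 * pi - d
  d * 180 / pi
}

orc_limb_angles <- function(seq) {
  co <- seq$coords
  kp <- canonical_keypoints()
  g <- function(t, name) co[t, match(name, kp), ]
  sites <- list(
    c("r_shoulder", "r_elbow", "r_wrist"), c("l_shoulder", "l_elbow", "l_wrist"),
    c("r_hip", "r_knee", "r_ankle"), c("l_hip", "l_knee", "l_ankle"),
    c("neck", "r_shoulder", "r_elbow"), c("neck", "l_shoulder", "l_elbow"),
    c("neck", "r_hip", "r_knee"), c("neck", "l_hip", "l_knee"))
  out <- matrix(NA_real_, seq$n_frames, 8L)
  for (t in seq_len(seq$n_frames)) for (j in 1:8) {
    s <- sites[[j]]
    out[t, j] <- orc_angle(g(t, s[1]), g(t, s[2]), g(t, s[3]))
  }
  out
}

orc_symmetry <- function(seq) {
  co <- seq$coords
  kp <- canonical_keypoints()
  pairs <- list(c("l_shoulder", "r_shoulder"), c("l_elbow", "r_elbow"),
                c("l_wrist", "r_wrist"), c("l_hip", "r_hip"),
                c("l_knee", "r_knee"), c("l_ankle", "r_ankle"))
  out <- matrix(NA_real_, seq$n_frames, 6L)
  for (t in seq_len(seq$n_frames)) {
    nx <- co[t, match("nose", kp), 1]
    for (j in 1:6) {
      dl <- abs(co[t, match(pairs[[j]][1], kp), 1] - nx)
      dr <- abs(co[t, match(pairs[[j]][2], kp), 1] - nx)
      out[t, j] <- abs(dl - dr)
    }
  }
  out
}

orc_shoulder_ratio <- function(seq) {
  co <- seq$coords
  kp <- canonical_keypoints()
  sapply(seq_len(seq$n_frames), function(t) {
    sl <- co[t, match("l_shoulder", kp), ]
    sr <- co[t, match("r_shoulder", kp), ]
    sqrt(sum((sl - sr)^2)) / (max(co[t, , 1]) - min(co[t, , 1]))
  })
}

orc_surface <- function(seq) {
  co <- seq$coords
  sapply(seq_len(seq$n_frames), function(t)
    (max(co[t, , 1]) - min(co[t, , 1])) * (max(co[t, , 2]) - min(co[t, , 2])))
}

orc_contraction <- function(seq) {
  co <- seq$coords
  kp <- canonical_keypoints()
  ext <- c("l_wrist", "r_wrist", "l_ankle", "r_ankle")
  sapply(seq_len(seq$n_frames), function(t) {
    nose <- co[t, match("nose", kp), ]
    mean(sapply(ext, function(e)
      sqrt(sum((co[t, match(e, kp), ] - nose)^2))))
  })
}

orc_euclidean_rdm <- function(values) {
  v <- if (is.null(dim(values))) matrix(values, ncol = 1) else values
  n <- nrow(v)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- sqrt(sum((v[i, ] - v[j, ])^2))
  m
}

# rank-then-Pearson with explicit moment formula
orc_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# within-subject F via aov + Error stratum, epsilon via eigenvalues
orc_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(y = as.vector(m),
                     unit = factor(rep(seq_len(n), k)),
                     cond = factor(rep(seq_len(k), each = n)))
  s <- summary(stats::aov(y ~ cond + Error(unit / cond), data = long))
  tab <- s[["Error: unit:cond"]][[1]]
  C <- diag(k) - 1 / k
  S <- stats::cov(m)
  ev <- Re(eigen(C %*% S %*% C, only.values = TRUE)$values)
  list(F = tab["cond", "F value"],
       p = tab["cond", "Pr(>F)"],
       eta = tab["cond", "Sum Sq"] /
         (tab["cond", "Sum Sq"] + tab["Residuals", "Sum Sq"]),
       epsilon = sum(ev)^2 / ((k - 1) * sum(ev^2)))
}

# ICC(2,1)/(2,k) via the two-way aov mean squares
orc_icc <- function(m) {  # raters x stimuli
  k <- nrow(m); n <- ncol(m)
  long <- data.frame(y = as.vector(t(m)),
                     stim = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ stim + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  list(single = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
       average = (msr - mse) / (msr + (msc - mse) / n))
}
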