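# The eight movement features. Kinematic features (velocity, acceleration,
# vertical movement) describe between-frame motion; postural features (limb
# angles, symmetry, shoulder ratio, surface, limb contraction) describe the
# within-frame body configuration.

.FEATURES <- c("velocity", "acceleration", "vertical_movement",
               "limb_angles", "symmetry", "shoulder_ratio",
               "surface", "limb_contraction")

#' Feature names
#'
#' @return Character vector of the eight feature names, kinematic first.
#' @export
feature_names <- function() .FEATURES

.feature_series <- function(feature, values, components, units,
                            aggregated = character(0)) {
  values <- as.matrix(values)
  colnames(values) <- components
  structure(list(feature = feature, values = values,
                 components = components, units = units,
                 aggregated = aggregated),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s [%s]: %d frame(s) x %d component(s)%s\n",
              x$feature, x$units, nrow(x$values), ncol(x$values),
              if (length(x$aggregated))
                sprintf(" (averaged over %s)",
                        paste(x$aggregated, collapse = ", ")) else ""))
  invisible(x)
}

.xy <- function(seq) {
  x <- seq$coords[, , 1, drop = TRUE]
  y <- seq$coords[, , 2, drop = TRUE]
  if (seq$n_frames == 1L) { x <- matrix(x, 1L); y <- matrix(y, 1L) }
  colnames(x) <- colnames(y) <- .KEYPOINTS14
  list(x = x, y = y)
}

#' Per-keypoint velocity
#'
#' Euclidean displacement of each keypoint between adjacent frames, in
#' pixels/frame; one value per frame transition and keypoint.
#'
#' @param seq A [pose_sequence] with at least 2 frames.
#' @return A `feature_series` with `n_frames - 1` rows and 14 components.
#' @export
compute_velocity <- function(seq) {
  if (seq$n_frames < 2L)
    stop_data("velocity needs at least 2 frames, got %d", seq$n_frames)
  p <- .xy(seq)
  v <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  .feature_series("velocity", v, .KEYPOINTS14, "px/frame")
}

#' Per-keypoint acceleration
#'
#' Magnitude of the change of each keypoint's 2D velocity vector between
#' successive frame transitions, in pixels/frame^2.
#'
#' @param seq A [pose_sequence] with at least 3 frames.
#' @return A `feature_series` with `n_frames - 2` rows and 14 components.
#' @export
compute_acceleration <- function(seq) {
  if (seq$n_frames < 3L)
    stop_data("acceleration needs at least 3 frames, got %d", seq$n_frames)
  p <- .xy(seq)
  ax <- diff(p$x, differences = 2)
  ay <- diff(p$y, differences = 2)
  a <- sqrt(ax^2 + ay^2)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  .feature_series("acceleration", a, .KEYPOINTS14, "px/frame^2")
}

#' Per-keypoint vertical movement
#'
#' Signed vertical displacement of each keypoint between adjacent frames,
#' up-positive (the image y axis, which grows downward, is negated), in
#' pixels/frame.
#'
#' @param seq A [pose_sequence] with at least 2 frames.
#' @return A `feature_series` with `n_frames - 1` rows and 14 components.
#' @export
compute_vertical_movement <- function(seq) {
  if (seq$n_frames < 2L)
    stop_data("vertical movement needs at least 2 frames, got %d", seq$n_frames)
  p <- .xy(seq)
  vm <- -diff(p$y)
  if (is.null(dim(vm))) vm <- matrix(vm, nrow = 1L)
  .feature_series("vertical_movement", vm, .KEYPOINTS14, "px/frame")
}

# angle at vertex b between segments b->a and b->c, degrees in [0, 180]
.angle_deg <- function(ax, ay, bx, by, cx, cy, site, frame) {
  u <- c(ax - bx, ay - by)
  v <- c(cx - bx, cy - by)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_data("undefined angle at %s in frame %d: coincident adjacent joints",
              site, frame)
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

.ANGLE_SITES <- list(
  r_elbow = c("r_shoulder", "r_elbow", "r_wrist"),
  l_elbow = c("l_shoulder", "l_elbow", "l_wrist"),
  r_knee = c("r_hip", "r_knee", "r_ankle"),
  l_knee = c("l_hip", "l_knee", "l_ankle"),
  r_shoulder = c("neck", "r_shoulder", "r_elbow"),
  l_shoulder = c("neck", "l_shoulder", "l_elbow"),
  r_hip = c("neck", "r_hip", "r_knee"),
  l_hip = c("neck", "l_hip", "l_knee")
)

#' Limb angles
#'
#' The angle between adjacent body segments at eight sites (left/right
#' elbows, knees, shoulders and hips), in degrees within \[0, 180\]. Elbow:
#' angle between elbow-shoulder and elbow-wrist; knee: knee-hip and
#' knee-ankle; shoulder: shoulder-neck and shoulder-elbow; hip: hip-neck
#' and hip-knee. Smaller values mean more flexed limbs.
#'
#' @param seq A [pose_sequence].
#' @return A `feature_series` with `n_frames` rows and 8 components.
#' @export
compute_limb_angles <- function(seq) {
  p <- .xy(seq)
  sites <- names(.ANGLE_SITES)
  out <- matrix(NA_real_, seq$n_frames, length(sites))
  for (j in seq_along(sites)) {
    tri <- .ANGLE_SITES[[j]]
    for (t in seq_len(seq$n_frames)) {
      out[t, j] <- .angle_deg(
        p$x[t, tri[1]], p$y[t, tri[1]],
        p$x[t, tri[2]], p$y[t, tri[2]],
        p$x[t, tri[3]], p$y[t, tri[3]],
        sites[j], t)
    }
  }
  .feature_series("limb_angles", out, sites, "degrees")
}

.SYM_PAIRS <- list(
  shoulder = c("l_shoulder", "r_shoulder"),
  elbow = c("l_elbow", "r_elbow"),
  wrist = c("l_wrist", "r_wrist"),
  hip = c("l_hip", "r_hip"),
  knee = c("l_knee", "r_knee"),
  ankle = c("l_ankle", "r_ankle")
)

#' Lateral asymmetry about the nose axis
#'
#' For each left/right joint pair, the absolute difference between the two
#' joints' horizontal distances to the vertical axis through the nose, in
#' pixels. Zero means the pair is mirror-symmetric about the nose axis;
#' larger values mean more asymmetric postures.
#'
#' @param seq A [pose_sequence].
#' @return A `feature_series` with `n_frames` rows and 6 components
#'   (shoulder, elbow, wrist, hip, knee, ankle pairs).
#' @export
compute_symmetry <- function(seq) {
  p <- .xy(seq)
  nose_x <- p$x[, "nose"]
  out <- sapply(.SYM_PAIRS, function(pair) {
    abs(abs(p$x[, pair[1]] - nose_x) - abs(p$x[, pair[2]] - nose_x))
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  .feature_series("symmetry", out, names(.SYM_PAIRS), "px")
}

#' Shoulder ratio
#'
#' Shoulder width (Euclidean distance between the shoulders) divided by the
#' horizontal extent of the whole skeleton (max x minus min x over the 14
#' keypoints), per frame. Dimensionless; smaller values mean the body
#' extends further beyond the shoulder span.
#'
#' @param seq A [pose_sequence].
#' @return A single-component `feature_series` with `n_frames` rows.
#' @export
compute_shoulder_ratio <- function(seq) {
  p <- .xy(seq)
  sw <- sqrt((p$x[, "l_shoulder"] - p$x[, "r_shoulder"])^2 +
             (p$y[, "l_shoulder"] - p$y[, "r_shoulder"])^2)
  extent <- apply(p$x, 1, max) - apply(p$x, 1, min)
  if (any(extent == 0))
    stop_data("degenerate pose: zero horizontal extent in frame %d",
              which(extent == 0)[1])
  .feature_series("shoulder_ratio", sw / extent, "shoulder_ratio", "ratio")
}

#' Bounding-box surface
#'
#' Area of the axis-aligned bounding box of the 14 keypoints (horizontal
#' extent times vertical extent), per frame, in pixels^2.
#'
#' @param seq A [pose_sequence].
#' @return A single-component `feature_series` with `n_frames` rows.
#' @export
compute_surface <- function(seq) {
  p <- .xy(seq)
  w <- apply(p$x, 1, max) - apply(p$x, 1, min)
  h <- apply(p$y, 1, max) - apply(p$y, 1, min)
  .feature_series("surface", w * h, "surface", "px^2")
}

#' Limb contraction
#'
#' Mean Euclidean distance from the nose to the four extremities (both
#' wrists and both ankles), per frame, in pixels. Larger values mean a more
#' extended body.
#'
#' @param seq A [pose_sequence].
#' @return A single-component `feature_series` with `n_frames` rows.
#' @export
compute_limb_contraction <- function(seq) {
  p <- .xy(seq)
  ext <- c("l_wrist", "r_wrist", "l_ankle", "r_ankle")
  d <- sapply(ext, function(k)
    sqrt((p$x[, k] - p$x[, "nose"])^2 + (p$y[, k] - p$y[, "nose"])^2))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
  .feature_series("limb_contraction", rowMeans(d), "limb_contraction", "px")
}

.FEATURE_FUNS <- list(
  velocity = compute_velocity,
  acceleration = compute_acceleration,
  vertical_movement = compute_vertical_movement,
  limb_angles = compute_limb_angles,
  symmetry = compute_symmetry,
  shoulder_ratio = compute_shoulder_ratio,
  surface = compute_surface,
  limb_contraction = compute_limb_contraction
)

#' Compute all eight features of a sequence
#'
#' @param seq A [pose_sequence] with at least 3 frames.
#' @return Named list of `feature_series`, one per feature.
#' @export
compute_all_features <- function(seq) {
  lapply(.FEATURE_FUNS, function(f) f(seq))
}

#' Average a feature series over time and/or components
#'
#' Arithmetic means over the requested axes; because means commute, the
#' order of aggregation does not matter. Aggregating an axis that is
#' already length one is a no-op.
#'
#' @param series A `feature_series`.
#' @param over_time Average over the frame axis?
#' @param over_components Average over the component axis?
#' @return A `feature_series` with the reduced axes; its `aggregated` field
#'   records which axes were averaged.
#' @export
aggregate_series <- function(series, over_time = TRUE, over_components = TRUE) {
  stopifnot(inherits(series, "feature_series"))
  v <- series$values
  comp <- series$components
  agg <- series$aggregated
  if (over_components && ncol(v) > 0L) {
    v <- matrix(rowMeans(v), ncol = 1L)
    comp <- "mean"
    agg <- union(agg, "components")
  }
  if (over_time) {
    v <- matrix(colMeans(v), nrow = 1L)
    agg <- union(agg, "time")
  }
  .feature_series(series$feature, v, comp, series$units, aggregated = agg)
}

#' Fully averaged scalar value of a feature
#'
#' @param seq A [pose_sequence].
#' @param feature One of [feature_names()].
#' @return Numeric scalar: the feature averaged over time and components.
#' @export
feature_scalar <- function(seq, feature) {
  feature <- match.arg(feature, .FEATURES)
  s <- aggregate_series(.FEATURE_FUNS[[feature]](seq), TRUE, TRUE)
  as.numeric(s$values)
}

.feature_table <- function(df, mode, aggregation) {
  structure(df, mode = mode, aggregation = aggregation,
            class = c("feature_table", "data.frame"))
}

#' Build the stimulus-by-feature table
#'
#' In `averaged` mode, each feature is averaged over time and keypoints,
#' yielding one column per feature (8 columns). In `time_preserving` mode,
#' each feature is averaged over components only and one column per feature
#' and frame index is kept; all features are truncated to the shortest
#' frame axis (`n_frames - 2`, the acceleration axis) so every column is
#' defined for every stimulus, yielding `8 * (n_frames - 2)` columns.
#'
#' @param stimuli A [stimulus_set] whose sequences share a frame count of at
#'   least 3.
#' @param mode `"averaged"` or `"time_preserving"`.
#' @return A `feature_table`: a data frame with `stimulus_id`, `emotion`,
#'   `actor_id` and the feature columns; attribute `aggregation` records
#'   which axes were averaged.
#' @export
build_feature_table <- function(stimuli, mode = c("averaged", "time_preserving")) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  mode <- match.arg(mode)
  if (stimuli$n_frames < 3L)
    stop_data("feature table needs at least 3 frames per sequence")
  meta <- data.frame(
    stimulus_id = stimuli$stimulus_ids,
    emotion = stimuli$emotions,
    actor_id = vapply(stimuli$sequences, `[[`, character(1), "actor_id"),
    stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  if (mode == "averaged") {
    vals <- t(vapply(stimuli$sequences, function(s)
      vapply(.FEATURES, function(f) feature_scalar(s, f), numeric(1)),
      numeric(length(.FEATURES))))
    out <- cbind(meta, as.data.frame(vals))
    return(.feature_table(out, mode,
                          list(time = TRUE, components = TRUE)))
  }
  nt <- stimuli$n_frames - 2L
  cols <- unlist(lapply(.FEATURES, function(f)
    sprintf("%s_f%02d", f, seq_len(nt))))
  vals <- t(vapply(stimuli$sequences, function(s) {
    unlist(lapply(.FEATURES, function(f) {
      v <- aggregate_series(.FEATURE_FUNS[[f]](s),
                            over_time = FALSE, over_components = TRUE)$values
      v[seq_len(nt), 1]
    }))
  }, numeric(length(cols))))
  colnames(vals) <- cols
  out <- cbind(meta, as.data.frame(vals))
  .feature_table(out, mode, list(time = FALSE, components = TRUE,
                                 frames_kept = nt))
}

#' Feature columns of a feature table
#'
#' @param table A `feature_table`.
#' @return Numeric matrix of the feature columns (metadata columns dropped),
#'   with stimulus ids as row names.
#' @export
feature_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  meta <- intersect(c("stimulus_id", "emotion", "actor_id"), names(table))
  m <- as.matrix(table[, setdiff(names(table), meta), drop = FALSE])
  rownames(m) <- table$stimulus_id
  m
}

#' Write a feature table with a JSON metadata sidecar
#'
#' @param table A `feature_table`.
#' @param path CSV output path; the sidecar is written to `paste0(path,
#'   ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  units <- c(velocity = "px/frame", acceleration = "px/frame^2",
             vertical_movement = "px/frame", limb_angles = "degrees",
             symmetry = "px", shoulder_ratio = "ratio",
             surface = "px^2", limb_contraction = "px")
  jsonlite::write_json(
    list(mode = attr(table, "mode"),
         aggregation = attr(table, "aggregation"),
         units = as.list(units)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
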