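# Keypoint order after canonicalization: COCO-18 indices 0-13 (eyes and ears,
# indices 14-17, are dropped; the nose is kept as a head reference).
.KEYPOINTS14 <- c(
  "nose", "neck",
  "r_shoulder", "r_elbow", "r_wrist",
  "l_shoulder", "l_elbow", "l_wrist",
  "r_hip", "r_knee", "r_ankle",
  "l_hip", "l_knee", "l_ankle"
)

.EMOTIONS <- c("anger", "happiness", "neutral", "fear")

#' Canonical keypoint names
#'
#' The 14 keypoints retained after canonicalization of a COCO-18 skeleton:
#' the eye and ear keypoints are discarded (they are unreliable when faces
#' are blurred), while the nose is kept as a reference for head position.
#'
#' @return Character vector of 14 keypoint names, in canonical order
#'   (COCO-18 indices 0 to 13).
#' @export
canonical_keypoints <- function() .KEYPOINTS14

#' Emotion category levels
#'
#' @return Character vector of the four emotion categories used throughout
#'   the package, in fixed order.
#' @export
emotion_levels <- function() .EMOTIONS

#' Construct a canonical pose sequence
#'
#' A pose sequence holds the 2D trajectory of the 14 canonical keypoints of
#' one actor over the frames of one stimulus clip. Coordinates are in image
#' convention: x grows rightward, y grows downward.
#'
#' @param coords Numeric array of dimension `n_frames x 14 x 2`
#'   (frames x keypoints x (x, y)); no missing values allowed.
#' @param stimulus_id Character scalar identifying the stimulus.
#' @param emotion One of `emotion_levels()`.
#' @param actor_id Character scalar identifying the actor (may be `NA`).
#' @param fps Frames per second of the source clip.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(coords, stimulus_id, emotion,
                          actor_id = NA_character_, fps = 25) {
  if (!is.array(coords) || length(dim(coords)) != 3L)
    stop_data("coords must be a 3-d array (frames x keypoints x 2)")
  d <- dim(coords)
  if (d[2] != 14L || d[3] != 2L)
    stop_data("coords must have 14 keypoints and 2 coordinates, got %d x %d",
              d[2], d[3])
  if (d[1] < 1L)
    stop_data("pose sequence must contain at least one frame")
  if (anyNA(coords) || any(!is.finite(coords)))
    stop_data("coords contain missing or non-finite values")
  if (!emotion %in% .EMOTIONS)
    stop_data("unknown emotion '%s' (expected one of: %s)",
              emotion, paste(.EMOTIONS, collapse = ", "))
  dimnames(coords) <- list(NULL, .KEYPOINTS14, c("x", "y"))
  structure(
    list(stimulus_id = as.character(stimulus_id),
         emotion = emotion,
         actor_id = as.character(actor_id),
         coords = coords,
         n_frames = d[1],
         fps = as.numeric(fps)),
    class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %s (%s, actor %s): %d frames x 14 keypoints @ %g fps\n",
              x$stimulus_id, x$emotion, x$actor_id, x$n_frames, x$fps))
  invisible(x)
}

#' Bundle pose sequences into a stimulus set
#'
#' @param sequences List of [pose_sequence] objects with unique stimulus ids
#'   and equal frame counts.
#' @return An object of class `stimulus_set`.
#' @export
stimulus_set <- function(sequences) {
  if (!length(sequences))
    stop_data("stimulus set must contain at least one sequence")
  ok <- vapply(sequences, inherits, logical(1), "pose_sequence")
  if (!all(ok))
    stop_data("all elements must be pose_sequence objects")
  ids <- vapply(sequences, `[[`, character(1), "stimulus_id")
  if (anyDuplicated(ids))
    stop_data("duplicated stimulus ids: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  nf <- vapply(sequences, `[[`, numeric(1), "n_frames")
  if (length(unique(nf)) != 1L)
    stop_data("all sequences must share the same frame count (found: %s)",
              paste(unique(nf), collapse = ", "))
  names(sequences) <- ids
  emo <- vapply(sequences, `[[`, character(1), "emotion")
  structure(
    list(sequences = sequences,
         stimulus_ids = ids,
         emotions = emo,
         category_counts = table(factor(emo, levels = .EMOTIONS)),
         n_frames = nf[1]),
    class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d stimuli x %d frames\n",
              length(x$sequences), x$n_frames))
  print(x$category_counts)
  invisible(x)
}

#' @export
length.stimulus_set <- function(x) length(x$sequences)

.parse_openpose_frame <- function(frame, where) {
  people <- frame$people
  if (is.null(people) || length(people) == 0L)
    stop_data("no person detected in %s", where)
  if (length(people) > 1L)
    stop_data("ambiguous pose: %d people detected in %s (expected exactly 1)",
              length(people), where)
  kp <- unlist(people[[1]]$pose_keypoints_2d)
  if (!is.numeric(kp) || length(kp) != 54L)
    stop_data("malformed keypoint array in %s: expected 54 numbers, got %d",
              where, length(kp))
  matrix(kp, ncol = 3L, byrow = TRUE) # 18 x (x, y, confidence)
}

#' Read an OpenPose COCO-18 keypoint sequence
#'
#' Reads OpenPose-style JSON output (COCO-18 layout: one
#' `people[[1]]$pose_keypoints_2d` flat array of 54 numbers per frame) and
#' canonicalizes it: eye and ear keypoints are dropped, and keypoints whose
#' detection confidence falls below `conf_threshold` are treated as missing
#' and repaired by per-coordinate linear interpolation across frames
#' (nearest-value extrapolation at the sequence ends).
#'
#' @param path Either a directory containing one JSON file per frame (read
#'   in lexicographic order) or a single JSON file holding an array of
#'   per-frame objects.
#' @param stimulus_id,emotion,actor_id Stimulus metadata (see
#'   [pose_sequence]).
#' @param fps Frames per second.
#' @param conf_threshold Confidence below which a detection counts as
#'   missing (default 0.1).
#' @return A [pose_sequence].
#' @export
read_openpose_json <- function(path, stimulus_id, emotion,
                               actor_id = NA_character_, fps = 25,
                               conf_threshold = 0.1) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (!length(files))
      stop_data("no JSON files found in directory '%s'", path)
    frames <- lapply(seq_along(files), function(i) {
      frame <- tryCatch(
        jsonlite::fromJSON(files[i], simplifyVector = FALSE),
        error = function(e) stop_data("malformed JSON in frame file '%s': %s",
                                      basename(files[i]), conditionMessage(e)))
      .parse_openpose_frame(frame, sprintf("frame file '%s'", basename(files[i])))
    })
  } else {
    if (!file.exists(path))
      stop_data("pose file '%s' does not exist", path)
    parsed <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = FALSE),
      error = function(e) stop_data("malformed JSON in '%s': %s",
                                    path, conditionMessage(e)))
    if (!is.null(parsed$people)) parsed <- list(parsed)
    frames <- lapply(seq_along(parsed), function(i)
      .parse_openpose_frame(parsed[[i]], sprintf("frame %d of '%s'", i, path)))
  }
  raw <- array(NA_real_, c(length(frames), 18L, 3L))
  for (i in seq_along(frames)) raw[i, , ] <- frames[[i]]
  canonicalize_keypoints(raw, stimulus_id = stimulus_id, emotion = emotion,
                         actor_id = actor_id, fps = fps,
                         conf_threshold = conf_threshold)
}

#' Canonicalize a raw COCO-18 keypoint array
#'
#' Drops the eye/ear keypoints (COCO indices 14-17), marks detections with
#' confidence below `conf_threshold` as missing, and repairs missing
#' coordinates by linear interpolation over frames (nearest value at the
#' ends). Coordinates of retained confident keypoints are preserved
#' bit-exactly.
#'
#' @param raw Numeric array `n_frames x 18 x 3` of (x, y, confidence).
#' @inheritParams read_openpose_json
#' @return A [pose_sequence].
#' @export
canonicalize_keypoints <- function(raw, stimulus_id, emotion,
                                   actor_id = NA_character_, fps = 25,
                                   conf_threshold = 0.1) {
  if (!is.array(raw) || length(dim(raw)) != 3L ||
      dim(raw)[2] != 18L || dim(raw)[3] != 3L)
    stop_data("raw keypoints must be an n_frames x 18 x 3 array")
  nf <- dim(raw)[1]
  coords <- raw[, 1:14, 1:2, drop = FALSE]
  conf <- raw[, 1:14, 3, drop = TRUE]
  if (nf == 1L) conf <- matrix(conf, nrow = 1L)
  miss <- conf < conf_threshold
  if (any(miss)) {
    for (k in seq_len(14L)) {
      if (!any(miss[, k])) next
      obs <- which(!miss[, k])
      if (!length(obs))
        stop_data("keypoint '%s' missing in every frame; cannot interpolate",
                  .KEYPOINTS14[k])
      for (d in 1:2) {
        if (length(obs) == 1L) {
          coords[, k, d] <- coords[obs, k, d]
        } else {
          coords[, k, d] <- stats::approx(obs, coords[obs, k, d],
                                          xout = seq_len(nf), rule = 2)$y
        }
      }
    }
  }
  pose_sequence(coords, stimulus_id = stimulus_id, emotion = emotion,
                actor_id = actor_id, fps = fps)
}

# Bones used for plausibility checks: each side's arm and leg chain plus the
# neck-shoulder and neck-hip links.
.BONES <- list(
  c("neck", "r_shoulder"), c("neck", "l_shoulder"),
  c("r_shoulder", "r_elbow"), c("l_shoulder", "l_elbow"),
  c("r_elbow", "r_wrist"), c("l_elbow", "l_wrist"),
  c("neck", "r_hip"), c("neck", "l_hip"),
  c("r_hip", "r_knee"), c("l_hip", "l_knee"),
  c("r_knee", "r_ankle"), c("l_knee", "l_ankle")
)

#' Flag frames with implausible bone lengths
#'
#' Computes the length of each skeleton bone (neck-shoulder, shoulder-elbow,
#' elbow-wrist, neck-hip, hip-knee, knee-ankle; both sides) in every frame
#' and flags frames where a bone deviates from its sequence-median length by
#' more than `bone_length_tolerance` as a fraction of the median. A
#' programmatic stand-in for visual inspection of pose-estimation output;
#' the input is never modified.
#'
#' @param seq A [pose_sequence].
#' @param bone_length_tolerance Allowed fractional deviation (default 0.5).
#' @return An object of class `pose_validation`: a list with `flags` (data
#'   frame of frame/bone violations), `flagged_frames`, and the tolerance.
#' @export
validate_sequence <- function(seq, bone_length_tolerance = 0.5) {
  stopifnot(inherits(seq, "pose_sequence"))
  x <- seq$coords[, , 1, drop = TRUE]
  y <- seq$coords[, , 2, drop = TRUE]
  if (seq$n_frames == 1L) {
    x <- matrix(x, nrow = 1L); y <- matrix(y, nrow = 1L)
  }
  colnames(x) <- colnames(y) <- .KEYPOINTS14
  rows <- list()
  for (b in .BONES) {
    len <- sqrt((x[, b[1]] - x[, b[2]])^2 + (y[, b[1]] - y[, b[2]])^2)
    med <- stats::median(len)
    bad <- which(abs(len - med) > bone_length_tolerance * med)
    if (length(bad))
      rows[[length(rows) + 1L]] <- data.frame(
        frame = bad, bone = paste(b[1], b[2], sep = "-"),
        length = len[bad], median_length = med)
  }
  flags <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), bone = character(),
               length = numeric(), median_length = numeric())
  flags <- flags[order(flags$frame), , drop = FALSE]
  rownames(flags) <- NULL
  structure(list(stimulus_id = seq$stimulus_id,
                 flags = flags,
                 flagged_frames = sort(unique(flags$frame)),
                 tolerance = bone_length_tolerance),
            class = "pose_validation")
}

#' @export
print.pose_validation <- function(x, ...) {
  cat(sprintf("<pose_validation> %s: %d flagged frame(s) at tolerance %g\n",
              x$stimulus_id, length(x$flagged_frames), x$tolerance))
  if (nrow(x$flags)) print(x$flags)
  invisible(x)
}

# %.17g survives a text round trip bit-exactly for doubles.
.fmt_num <- function(v) sprintf("%.17g", v)

#' Write a pose sequence as long-format CSV
#'
#' One row per frame x keypoint, with columns `stimulus_id`, `emotion`,
#' `actor_id`, `fps`, `frame`, `keypoint`, `x`, `y`. Coordinates are written
#' with 17 significant digits so that [read_sequence_csv] reproduces the
#' sequence bit-exactly.
#'
#' @param seq A [pose_sequence].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_csv <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  nf <- seq$n_frames
  df <- data.frame(
    stimulus_id = seq$stimulus_id,
    emotion = seq$emotion,
    actor_id = seq$actor_id,
    fps = seq$fps,
    frame = rep(seq_len(nf), each = 14L),
    keypoint = rep(.KEYPOINTS14, times = nf),
    x = .fmt_num(as.vector(t(seq$coords[, , 1]))),
    y = .fmt_num(as.vector(t(seq$coords[, , 2]))),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_data("cannot write sequence CSV to '%s'", path)
  invisible(path)
}

#' Read a pose sequence written by [write_sequence_csv]
#'
#' @param path CSV file path.
#' @return A [pose_sequence].
#' @export
read_sequence_csv <- function(path) {
  if (!file.exists(path)) stop_data("sequence CSV '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus_id", "emotion", "actor_id", "fps",
            "frame", "keypoint", "x", "y")
  if (!all(need %in% names(df)))
    stop_data("sequence CSV '%s' is missing columns: %s", path,
              paste(setdiff(need, names(df)), collapse = ", "))
  nf <- max(df$frame)
  coords <- array(NA_real_, c(nf, 14L, 2L))
  k_idx <- match(df$keypoint, .KEYPOINTS14)
  if (anyNA(k_idx))
    stop_data("unknown keypoint names in '%s'", path)
  coords[cbind(df$frame, k_idx, 1L)] <- df$x
  coords[cbind(df$frame, k_idx, 2L)] <- df$y
  pose_sequence(coords,
                stimulus_id = df$stimulus_id[1], emotion = df$emotion[1],
                actor_id = as.character(df$actor_id[1]),
                fps = as.numeric(df$fps[1]))
}

#' Write a pose sequence as OpenPose-style JSON
#'
#' Emits one concatenated JSON array with one `{people: [{pose_keypoints_2d:
#' ...}]}` object per frame, padding the eye/ear slots (COCO indices 14-17)
#' with zero-confidence entries. Useful for emitting synthetic stimuli in
#' the format the reader consumes.
#'
#' @param seq A [pose_sequence].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_openpose_json <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  frames <- lapply(seq_len(seq$n_frames), function(i) {
    kp <- numeric(54L)
    for (k in 1:14) {
      kp[(k - 1L) * 3L + 1L] <- seq$coords[i, k, 1]
      kp[(k - 1L) * 3L + 2L] <- seq$coords[i, k, 2]
      kp[(k - 1L) * 3L + 3L] <- 1
    }
    list(people = list(list(pose_keypoints_2d = kp)))
  })
  jsonlite::write_json(frames, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write every sequence of a stimulus set to a directory
#'
#' @param set A [stimulus_set].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (long CSV per sequence) or `"json"` (OpenPose-style).
#' @return Character vector of written file paths, invisibly.
#' @export
write_stimulus_set <- function(set, dir, format = c("csv", "json")) {
  stopifnot(inherits(set, "stimulus_set"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "csv") "csv" else "json"
  paths <- vapply(set$sequences, function(s) {
    p <- file.path(dir, sprintf("%s.%s", s$stimulus_id, ext))
    if (format == "csv") write_sequence_csv(s, p) else write_openpose_json(s, p)
    p
  }, character(1))
  invisible(unname(paths))
}

#' Read a directory of sequence CSVs into a stimulus set
#'
#' @param dir Directory containing CSV files written by
#'   [write_sequence_csv].
#' @return A [stimulus_set].
#' @export
read_stimulus_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop_data("no sequence CSVs found in '%s'", dir)
  stimulus_set(lapply(files, read_sequence_csv))
}
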