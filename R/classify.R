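# Bagged classification trees: bootstrap-aggregated binary trees with
# information-gain (entropy) splits grown to purity, out-of-bag accuracy
# and confusion, and impurity-decrease predictor importance taken from a
# single tree fit to the full data.

.PREDICTOR_SETS <- c("features_averaged", "features_time_preserving",
                     "ratings_nine", "ratings_six",
                     "bodyside_three", "joints_fourteen")

#' Construct a predictor set
#'
#' @param x Numeric predictor matrix or data frame (stimuli in rows).
#' @param labels Per-stimulus emotion labels.
#' @param name Descriptive name of the set.
#' @param groups Optional named character vector mapping each column to a
#'   grouped descriptor (importances are summed within groups).
#' @return An object of class `predictor_set`.
#' @export
predictor_set <- function(x, labels, name = "custom", groups = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    stop_data("predictors must be numeric and complete")
  if (nrow(x) != length(labels))
    stop_data("labels length (%d) does not match row count (%d)",
              length(labels), nrow(x))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("p%02d", seq_len(ncol(x)))
  if (!is.null(groups)) {
    if (length(groups) != ncol(x) || is.null(names(groups)))
      groups <- stats::setNames(rep_len(groups, ncol(x)), colnames(x))
    groups <- groups[colnames(x)]
  }
  structure(list(x = x, labels = as.character(labels), name = name,
                 groups = groups),
            class = "predictor_set")
}

.mean_xy_columns <- function(set, joints) {
  # time-averaged (x, y) of a group of keypoints, averaged over the group
  t(vapply(set$sequences, function(s) {
    c(mean(s$coords[, joints, 1]), mean(s$coords[, joints, 2]))
  }, numeric(2)))
}

#' Build one of the six canonical predictor sets
#'
#' * `features_averaged`: the 8 features averaged over time and keypoints
#'   (from an averaged `feature_table`).
#' * `features_time_preserving`: the 8 features averaged over keypoints
#'   with the frame axis kept (from a time-preserving `feature_table`).
#' * `ratings_nine`: per-stimulus participant-mean ratings of all nine
#'   scale questions (the forced-choice emotion/action questions excluded).
#' * `ratings_six`: as above, additionally excluding intensity, valence
#'   and familiarity.
#' * `bodyside_three`: per-stimulus time-averaged (x, y) of the body
#'   centre (nose, neck), the six left-side joints and the six right-side
#'   joints; 6 columns grouped into 3 descriptors (from a
#'   [stimulus_set]).
#' * `joints_fourteen`: per-joint time-averaged (x, y); 28 columns grouped
#'   into 14 descriptors.
#'
#' @param source A `feature_table`, `rating_table` or [stimulus_set]
#'   matching the requested set.
#' @param name One of the six canonical set names.
#' @return A `predictor_set`.
#' @export
build_predictor_set <- function(source, name) {
  name <- match.arg(name, .PREDICTOR_SETS)
  if (name %in% c("features_averaged", "features_time_preserving")) {
    if (inherits(source, "stimulus_set"))
      source <- build_feature_table(
        source, if (name == "features_averaged") "averaged" else "time_preserving")
    if (!inherits(source, "feature_table"))
      stop_data("predictor set '%s' needs a feature_table or stimulus_set", name)
    want <- if (name == "features_averaged") "averaged" else "time_preserving"
    if (attr(source, "mode") != want)
      stop_data("feature table mode '%s' does not match requested set '%s'",
                attr(source, "mode"), name)
    return(predictor_set(feature_matrix(source), source$emotion, name))
  }
  if (name %in% c("ratings_nine", "ratings_six")) {
    if (!inherits(source, "rating_table"))
      stop_data("predictor set '%s' needs a rating_table", name)
    qs <- .SCALE_QUESTIONS
    if (name == "ratings_six")
      qs <- setdiff(qs, c("intensity", "valence", "familiarity"))
    stims <- unique(source$stimulus_id)
    x <- sapply(qs, function(q) colMeans(rating_matrix(source, q)[, stims,
                                                                  drop = FALSE]))
    labels <- source$emotion[match(stims, source$stimulus_id)]
    return(predictor_set(x, labels, name))
  }
  if (!inherits(source, "stimulus_set"))
    stop_data("predictor set '%s' needs a stimulus_set", name)
  left <- c("l_shoulder", "l_elbow", "l_wrist", "l_hip", "l_knee", "l_ankle")
  right <- c("r_shoulder", "r_elbow", "r_wrist", "r_hip", "r_knee", "r_ankle")
  labels <- source$emotions
  if (name == "bodyside_three") {
    x <- cbind(.mean_xy_columns(source, c("nose", "neck")),
               .mean_xy_columns(source, left),
               .mean_xy_columns(source, right))
    colnames(x) <- c("centre_x", "centre_y", "left_x", "left_y",
                     "right_x", "right_y")
    groups <- stats::setNames(rep(c("centre", "left", "right"), each = 2),
                              colnames(x))
    return(predictor_set(x, labels, name, groups))
  }
  xs <- lapply(.KEYPOINTS14, function(k) .mean_xy_columns(source, k))
  x <- do.call(cbind, xs)
  colnames(x) <- as.vector(rbind(paste0(.KEYPOINTS14, "_x"),
                                 paste0(.KEYPOINTS14, "_y")))
  groups <- stats::setNames(rep(.KEYPOINTS14, each = 2), colnames(x))
  predictor_set(x, labels, name, groups)
}

.purity_tree <- function(df) {
  rpart::rpart(.class ~ ., data = df, method = "class",
               parms = list(split = "information"),
               control = rpart::rpart.control(
                 minsplit = 2, minbucket = 1, cp = 0, xval = 0,
                 maxsurrogate = 0, maxcompete = 0))
}

.tree_importance <- function(tree, predictors) {
  imp <- stats::setNames(rep(0, length(predictors)), predictors)
  vi <- tree$variable.importance
  if (!is.null(vi)) imp[names(vi)] <- vi
  imp
}

#' Fit a bagged ensemble of classification trees
#'
#' Grows `n_trees` binary classification trees, each on a bootstrap
#' resample of the stimuli (redrawn, at most 100 times, if a class is
#' missing from the resample), with entropy (information-gain) splits and
#' no pruning. Prediction is by majority vote (optionally weighted by each
#' tree's in-bag accuracy); accuracy, per-class accuracy and the confusion
#' matrix are estimated out-of-bag. Predictor importances are the
#' impurity-decrease importances of a single tree fit to the full data,
#' summed within groups for grouped predictor sets and normalized to
#' sum 1.
#'
#' @param pset A `predictor_set` with at least two classes present.
#' @param n_trees Number of bootstrap trees (default 100).
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @param vote `"majority"` (unweighted, default) or `"accuracy_weighted"`.
#' @return An object of class `tree_ensemble_report`.
#' @export
fit_bagged_trees <- function(pset, n_trees = 100, seed = NULL,
                             vote = c("majority", "accuracy_weighted")) {
  stopifnot(inherits(pset, "predictor_set"))
  vote <- match.arg(vote)
  if (n_trees < 1) stop_config("n_trees must be at least 1")
  classes <- sort(unique(pset$labels))
  if (length(classes) < 2L)
    stop_data("need at least 2 classes, got %d", length(classes))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pset$x)
  df <- data.frame(.class = factor(pset$labels, levels = classes),
                   pset$x, check.names = TRUE)
  predictors <- setdiff(names(df), ".class")

  full_tree <- .purity_tree(df)
  imp <- .tree_importance(full_tree, predictors)
  names(imp) <- colnames(pset$x)  # undo any make.names mangling
  if (!is.null(pset$groups))
    imp <- tapply(imp, pset$groups[names(imp)], sum)[unique(pset$groups)]
  imp_total <- sum(imp)
  importances <- if (imp_total > 0) imp / imp_total else
    stats::setNames(rep(1 / length(imp), length(imp)), names(imp))

  vote_counts <- matrix(0, n, length(classes),
                        dimnames = list(NULL, classes))
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    for (attempt in seq_len(100L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(df$.class[idx])) == length(classes)) break
      if (attempt == 100L)
        stop_data("could not draw a bootstrap containing every class in 100 attempts")
    }
    fit <- .purity_tree(df[idx, , drop = FALSE])
    trees[[b]] <- fit
    oob <- setdiff(seq_len(n), unique(idx))
    w <- 1
    if (vote == "accuracy_weighted") {
      inbag_pred <- predict(fit, df[idx, , drop = FALSE], type = "class")
      w <- mean(inbag_pred == df$.class[idx])
    }
    if (length(oob)) {
      pred <- predict(fit, df[oob, , drop = FALSE], type = "class")
      vote_counts[cbind(oob, as.integer(pred))] <-
        vote_counts[cbind(oob, as.integer(pred))] + w
    }
  }
  covered <- rowSums(vote_counts) > 0
  oob_pred <- factor(classes[max.col(vote_counts, ties.method = "first")],
                     levels = classes)
  truth <- df$.class
  acc <- mean(oob_pred[covered] == truth[covered])
  confusion <- table(true = truth[covered], predicted = oob_pred[covered])
  per_class <- diag(confusion) / rowSums(confusion)

  structure(list(n_trees = n_trees,
                 oob_accuracy = acc,
                 per_class_accuracy = per_class,
                 confusion = unclass(confusion),
                 importances = importances,
                 importance_source = "full_data_tree",
                 classes = classes,
                 labels = pset$labels,
                 predictor_set = pset$name,
                 n_oob_covered = sum(covered),
                 vote = vote,
                 seed = seed,
                 full_tree = full_tree,
                 trees = trees),
            class = "tree_ensemble_report")
}

#' @export
print.tree_ensemble_report <- function(x, ...) {
  cat(sprintf("<tree_ensemble_report> %s: %d trees, OOB accuracy %.1f%% (chance %.1f%%)\n",
              x$predictor_set, x$n_trees, 100 * x$oob_accuracy,
              100 / length(x$classes)))
  cat("Per-class accuracy:",
      paste(sprintf("%s %.0f%%", names(x$per_class_accuracy),
                    100 * x$per_class_accuracy), collapse = ", "), "\n")
  top <- utils::head(importance_ranking(x), 3)
  cat("Top predictors:",
      paste(sprintf("%s (%.2f)", top$predictor, top$importance),
            collapse = ", "), "\n")
  invisible(x)
}

#' Predict emotion labels with a fitted ensemble
#'
#' @param object A `tree_ensemble_report`.
#' @param newdata Numeric matrix or data frame with the same predictors.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.tree_ensemble_report <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata, check.names = TRUE)
  votes <- matrix(0, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (fit in object$trees) {
    pred <- predict(fit, newdata, type = "class")
    votes[cbind(seq_len(nrow(newdata)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(newdata)), as.integer(pred))] + 1
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Rank predictors by importance
#'
#' @param report A `tree_ensemble_report`.
#' @return Data frame sorted by descending importance; exact ties are
#'   broken lexicographically by predictor name and flagged in the `tied`
#'   column.
#' @export
importance_ranking <- function(report) {
  stopifnot(inherits(report, "tree_ensemble_report"))
  imp <- report$importances
  ord <- order(-imp, names(imp))
  out <- data.frame(predictor = names(imp)[ord],
                    importance = as.numeric(imp[ord]),
                    stringsAsFactors = FALSE)
  out$tied <- duplicated(out$importance) |
    duplicated(out$importance, fromLast = TRUE)
  out$rank <- seq_len(nrow(out))
  out
}

#' Compare fitted ensembles by out-of-bag accuracy
#'
#' @param reports Named list of at least two `tree_ensemble_report`s
#'   fitted to the same stimulus labels.
#' @return Data frame ordered by decreasing OOB accuracy with per-class
#'   accuracies, ranks, and a `tied` flag for equal accuracies.
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2L) stop_data("need at least 2 reports to compare")
  nm <- names(reports)
  if (is.null(nm)) nm <- paste0("model", seq_along(reports))
  labs <- lapply(reports, `[[`, "labels")
  for (i in seq_along(labs)[-1])
    if (length(labs[[i]]) != length(labs[[1]]) ||
        !all(labs[[i]] == labs[[1]]))
      stop_data("reports were not fitted to the same labels")
  acc <- vapply(reports, `[[`, numeric(1), "oob_accuracy")
  per_class <- t(vapply(reports, `[[`,
                        numeric(length(reports[[1]]$classes)),
                        "per_class_accuracy"))
  out <- data.frame(model = nm, oob_accuracy = acc,
                    per_class, stringsAsFactors = FALSE)
  out$rank <- rank(-acc, ties.method = "min")
  out$tied <- duplicated(acc) | duplicated(acc, fromLast = TRUE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize an ensemble report as JSON (trees excluded)
#'
#' @param report A `tree_ensemble_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ensemble_report <- function(report, path) {
  stopifnot(inherits(report, "tree_ensemble_report"))
  jsonlite::write_json(
    list(predictor_set = report$predictor_set,
         n_trees = report$n_trees,
         oob_accuracy = report$oob_accuracy,
         per_class_accuracy = as.list(report$per_class_accuracy),
         confusion = report$confusion,
         importances = as.list(report$importances),
         importance_source = report$importance_source,
         vote = report$vote,
         n_oob_covered = report$n_oob_covered,
         seed = report$seed),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
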