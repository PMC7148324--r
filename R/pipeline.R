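# End-to-end orchestration: simulate (or load) stimuli and ratings, extract
# features, run the RSA, ANOVA/ICC and classification stages, and write all
# artifacts plus a manifest into a run directory.

.PIPELINE_STAGES <- c("simulate", "features", "rsa", "anova", "icc", "classify")

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate stimuli and ratings), `"pose_dir"`
#'   (read sequence CSVs from `pose_dir`; rating stages are skipped) or
#'   `"ratings_file"` (read a rating CSV; pose stages are skipped).
#' @param out_dir Output run directory.
#' @param seed Master seed; every random stage receives a seed derived
#'   deterministically from it.
#' @param generator A [generator_config] for synthetic mode.
#' @param ratings A [rating_generator_config] for synthetic mode.
#' @param pose_dir Directory of sequence CSVs (mode `"pose_dir"`).
#' @param ratings_file Rating CSV path (mode `"ratings_file"`).
#' @param m_features Bonferroni divisor for the computed-feature
#'   second-level analysis (default 9).
#' @param m_ratings Bonferroni divisor for the behavioural-rating
#'   second-level analysis (default 12).
#' @param n_trees Trees per bagged ensemble.
#' @param stages Subset of pipeline stages to run.
#' @param force Re-run even if an identical completed run exists.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "pose_dir", "ratings_file"),
                            out_dir, seed = 1L,
                            generator = generator_config(),
                            ratings = rating_generator_config(),
                            pose_dir = NULL, ratings_file = NULL,
                            m_features = 9L, m_ratings = 12L,
                            n_trees = 100L,
                            stages = .PIPELINE_STAGES,
                            force = FALSE) {
  mode <- match.arg(mode)
  bad <- character(0)
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1L)
    bad <- c(bad, "out_dir")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    bad <- c(bad, "seed")
  if (!inherits(generator, "generator_config")) bad <- c(bad, "generator")
  if (!inherits(ratings, "rating_generator_config")) bad <- c(bad, "ratings")
  if (mode == "pose_dir" && (is.null(pose_dir) || !dir.exists(pose_dir)))
    bad <- c(bad, "pose_dir")
  if (mode == "ratings_file" &&
      (is.null(ratings_file) || !file.exists(ratings_file)))
    bad <- c(bad, "ratings_file")
  if (!all(stages %in% .PIPELINE_STAGES)) bad <- c(bad, "stages")
  if (n_trees < 1) bad <- c(bad, "n_trees")
  if (length(bad))
    stop_config("invalid pipeline configuration fields: %s",
                paste(bad, collapse = ", "))
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 generator = generator, ratings = ratings,
                 pose_dir = pose_dir, ratings_file = ratings_file,
                 m_features = m_features, m_ratings = m_ratings,
                 n_trees = as.integer(n_trees), stages = stages,
                 force = force),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  keep <- config[setdiff(names(config), "force")]
  jsonlite::write_json(keep, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.log_msg <- function(...) message(sprintf(...))

#' Run the analysis pipeline
#'
#' Executes the configured stages in order (simulate/load, feature
#' extraction, RSA, ANOVA, ICC, classification) and writes every artifact
#' into the run directory together with a `manifest.json` recording the
#' configuration hash, seeds, versions and artifact list. Re-running a
#' completed configuration is a no-op unless `force` is set. Stages whose
#' inputs are unavailable in the chosen mode are skipped with a warning.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the run directory, manifest, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  if (!config$force && file.exists(manifest_path)) {
    old <- tryCatch(jsonlite::fromJSON(manifest_path), error = function(e) NULL)
    if (!is.null(old) && identical(old$config_hash[[1]], hash[[1]]) &&
        isTRUE(old$completed)) {
      .log_msg("run already completed for this configuration (use force to re-run)")
      return(invisible(list(out_dir = config$out_dir, manifest = old,
                            results = NULL)))
    }
  }
  seeds <- list(generator = config$seed + 1L,
                ratings = config$seed + 2L,
                classify = config$seed + 3L)
  artifacts <- character(0)
  res <- list()
  add <- function(path) artifacts <<- c(artifacts, basename(path))

  stimuli <- NULL; ratings_tab <- NULL
  if (config$mode == "synthetic") {
    if ("simulate" %in% config$stages) {
      gen <- config$generator; gen$seed <- seeds$generator
      stimuli <- generate_stimulus_set(config = gen)
      .log_msg("simulated %d stimuli (%d frames each)",
               length(stimuli), stimuli$n_frames)
      stim_dir <- file.path(config$out_dir, "stimuli")
      write_stimulus_set(stimuli, stim_dir, format = "csv")
      artifacts <- c(artifacts, file.path("stimuli",
                                          paste0(stimuli$stimulus_ids, ".csv")))
      rcfg <- config$ratings; rcfg$seed <- seeds$ratings
      ratings_tab <- generate_ratings(stimuli, rcfg)
      write_rating_table(ratings_tab, file.path(config$out_dir, "ratings.csv"))
      add("ratings.csv")
    }
  } else if (config$mode == "pose_dir") {
    stimuli <- read_stimulus_set(config$pose_dir)
    .log_msg("loaded %d stimuli from %s", length(stimuli), config$pose_dir)
  } else {
    ratings_tab <- read_rating_table(config$ratings_file)
    .log_msg("loaded ratings from %s", config$ratings_file)
  }

  ft_avg <- ft_time <- NULL
  if ("features" %in% config$stages) {
    if (is.null(stimuli)) {
      warning("feature stage skipped: no pose data in this mode")
    } else {
      ft_avg <- build_feature_table(stimuli, "averaged")
      ft_time <- build_feature_table(stimuli, "time_preserving")
      write_feature_table(ft_avg, file.path(config$out_dir,
                                            "features_averaged.csv"))
      write_feature_table(ft_time, file.path(config$out_dir,
                                             "features_time_preserving.csv"))
      add("features_averaged.csv"); add("features_time_preserving.csv")
      res$features <- ft_avg
    }
  }

  feature_rdms <- NULL
  if ("rsa" %in% config$stages) {
    if (!is.null(ft_avg)) {
      fm <- feature_matrix(ft_avg)
      feature_rdms <- lapply(.FEATURES, function(f)
        euclidean_rdm(fm[, f], ids = ft_avg$stimulus_id, source = f))
      names(feature_rdms) <- .FEATURES
      emo_rdm <- dummy_rdm(ft_avg$emotion, ids = ft_avg$stimulus_id,
                           source = "emotion_category")
      all_rdms <- c(feature_rdms, list(emotion_category = emo_rdm))
      for (nm in names(all_rdms)) {
        p <- file.path(config$out_dir, sprintf("rdm_%s.csv", nm))
        write_rdm(all_rdms[[nm]], p); add(p)
      }
      sl <- second_level_matrix(all_rdms, m_per_item = config$m_features)
      utils::write.csv(sl$one_minus_rho,
                       file.path(config$out_dir, "second_level_features.csv"))
      add("second_level_features.csv")
      res$rsa_features <- sl
    }
    if (!is.null(ratings_tab)) {
      r_rdms <- rating_rdms(ratings_tab)
      slr <- second_level_matrix(r_rdms, m_per_item = config$m_ratings)
      utils::write.csv(slr$one_minus_rho,
                       file.path(config$out_dir, "second_level_ratings.csv"))
      add("second_level_ratings.csv")
      res$rsa_ratings <- slr
      if (!is.null(feature_rdms)) {
        cross <- cross_rdm_table(r_rdms, feature_rdms,
                                 m_per_item = config$m_ratings)
        utils::write.csv(cross,
                         file.path(config$out_dir,
                                   "second_level_ratings_vs_features.csv"),
                         row.names = FALSE)
        add("second_level_ratings_vs_features.csv")
      }
    }
    if (is.null(ft_avg) && is.null(ratings_tab))
      warning("rsa stage skipped: no inputs available")
  }

  if ("anova" %in% config$stages) {
    if (is.null(ft_avg)) {
      warning("anova stage skipped: no feature table available")
    } else {
      rows <- list(); ph_rows <- list()
      for (f in .FEATURES) {
        tab <- feature_anova_table(ft_avg, f)
        an <- rm_anova(tab, correct = "auto")
        ph <- posthoc_bonferroni(tab)
        rows[[f]] <- data.frame(
          feature = f, F = an$F, df1 = an$df1, df2 = an$df2, p = an$p,
          partial_eta_squared = an$partial_eta_squared,
          epsilon = an$epsilon, gg_corrected = an$corrected,
          stringsAsFactors = FALSE)
        ph$feature <- f
        ph_rows[[f]] <- as.data.frame(ph)
      }
      anova_tab <- do.call(rbind, rows); rownames(anova_tab) <- NULL
      utils::write.csv(anova_tab, file.path(config$out_dir, "anova.csv"),
                       row.names = FALSE)
      utils::write.csv(do.call(rbind, ph_rows),
                       file.path(config$out_dir, "posthoc.csv"),
                       row.names = FALSE)
      add("anova.csv"); add("posthoc.csv")
      res$anova <- anova_tab
    }
  }

  if ("icc" %in% config$stages) {
    if (is.null(ratings_tab)) {
      warning("icc stage skipped: no ratings available")
    } else {
      icc_rows <- lapply(.SCALE_QUESTIONS, function(q) {
        icc <- icc_absolute_agreement(rating_matrix(ratings_tab, q))
        data.frame(question = q, icc_single = icc$icc_single,
                   icc_average = icc$icc_average,
                   lower = icc$lower, upper = icc$upper,
                   stringsAsFactors = FALSE)
      })
      icc_tab <- do.call(rbind, icc_rows)
      utils::write.csv(icc_tab, file.path(config$out_dir, "icc.csv"),
                       row.names = FALSE)
      add("icc.csv")
      res$icc <- icc_tab
    }
  }

  if ("classify" %in% config$stages) {
    psets <- list()
    if (!is.null(ft_avg)) {
      psets$features_averaged <- build_predictor_set(ft_avg, "features_averaged")
      psets$features_time_preserving <-
        build_predictor_set(ft_time, "features_time_preserving")
    }
    if (!is.null(ratings_tab)) {
      psets$ratings_nine <- build_predictor_set(ratings_tab, "ratings_nine")
      psets$ratings_six <- build_predictor_set(ratings_tab, "ratings_six")
    }
    if (!is.null(stimuli)) {
      psets$bodyside_three <- build_predictor_set(stimuli, "bodyside_three")
      psets$joints_fourteen <- build_predictor_set(stimuli, "joints_fourteen")
    }
    if (!length(psets)) {
      warning("classify stage skipped: no predictor sets available")
    } else {
      reports <- list()
      for (i in seq_along(psets)) {
        nm <- names(psets)[i]
        rep_i <- fit_bagged_trees(psets[[nm]], n_trees = config$n_trees,
                                  seed = seeds$classify + i)
        reports[[nm]] <- rep_i
        p <- file.path(config$out_dir, sprintf("classifier_%s.json", nm))
        write_ensemble_report(rep_i, p); add(p)
        utils::write.csv(importance_ranking(rep_i),
                         file.path(config$out_dir,
                                   sprintf("importance_%s.csv", nm)),
                         row.names = FALSE)
        add(sprintf("importance_%s.csv", nm))
      }
      if (length(reports) >= 2L) {
        utils::write.csv(compare_models(reports),
                         file.path(config$out_dir, "model_comparison.csv"),
                         row.names = FALSE)
        add("model_comparison.csv")
      }
      res$classifiers <- reports
    }
  }

  manifest <- list(
    package = "affectmove",
    package_version = as.character(utils::packageVersion("affectmove")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = hash[[1]],
    mode = config$mode,
    master_seed = config$seed,
    stage_seeds = seeds,
    n_stimuli = if (!is.null(stimuli)) length(stimuli) else NA,
    n_rdms = if (!is.null(feature_rdms)) length(feature_rdms) + 1L else 0L,
    stages = config$stages,
    artifacts = sort(unique(artifacts)),
    completed = TRUE)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(out_dir = config$out_dir, manifest = manifest, results = res))
}
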