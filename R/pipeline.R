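# End-to-end orchestration: simulate -> extract -> analyze -> predict,
# with a YAML run configuration, parameter echo, content hashes and
# stage-level resume.

.known_run_keys <- c("cohort", "features", "analysis", "prediction",
                     "seed_pipeline")
.known_cohort_keys <- c("n_subjects", "films", "rest_duration", "seed",
                        "genre_emg_d", "rating_engagement_r",
                        "rating_valence_r", "sfreq_eeg", "sfreq_emg",
                        "sfreq_ppg", "sfreq_eda", "engagement_coupling",
                        "valence_coupling", "emg_burst_amplitude",
                        "emg_genre_sd", "rating_mean", "rating_subject_sd",
                        "rating_total_sd")

#' Validate a run configuration
#'
#' Accepts a YAML file path or a nested list; unknown keys are rejected
#' by name before any computation.
#'
#' @param config path to a YAML file or a list with (optional) entries
#'   `cohort`, `features` (`families`), `analysis`
#'   (`bh_scope`: "channel" or "global"), `prediction` (`task`, `models`,
#'   `k`, `global_selection`), `seed_pipeline`.
#' @return validated list of class `run_config` with defaults filled in.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .known_run_keys)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  ck <- config$cohort
  unknown <- setdiff(names(ck), .known_cohort_keys)
  if (length(unknown) > 0)
    stop("unknown cohort config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(ck$films) && !is.data.frame(ck$films))
    ck$films <- do.call(rbind, lapply(ck$films, as.data.frame))
  cohort_cfg <- do.call(cohort_config, if (is.null(ck)) list() else ck)
  out <- list(
    cohort = cohort_cfg,
    features = utils::modifyList(
      list(families = c("eeg", "complexity", "cardiac", "emg", "eda")),
      if (is.null(config$features)) list() else config$features),
    analysis = utils::modifyList(list(bh_scope = "channel"),
                                 if (is.null(config$analysis)) list()
                                 else config$analysis),
    prediction = utils::modifyList(
      list(task = "classification", models = NULL, k = 15,
           global_selection = FALSE),
      if (is.null(config$prediction)) list() else config$prediction),
    seed_pipeline = if (is.null(config$seed_pipeline)) 1L
    else as.integer(config$seed_pipeline)
  )
  structure(out, class = "run_config")
}

# genre comparison + feature-rating correlation tables for a feature df
.analyze_features <- function(features, bh_scope = "channel") {
  cols <- setdiff(names(features),
                  c("subject_id", "film_id", "genre", "rating"))
  # paired genre comparison of per-subject means
  cmp <- list()
  for (j in cols) {
    ag <- stats::aggregate(features[[j]],
                           by = list(subject = features$subject_id,
                                     genre = features$genre),
                           FUN = mean, na.rm = TRUE)
    w <- stats::reshape(ag, idvar = "subject", timevar = "genre",
                        direction = "wide")
    res <- tryCatch(paired_test(w$x.comedy, w$x.drama),
                    error = function(e) NULL)
    if (!is.null(res)) cmp[[j]] <- cbind(feature = j, res)
  }
  comparisons <- if (length(cmp)) do.call(rbind, cmp) else NULL
  # trialwise correlations with rating
  cors <- list()
  for (j in cols) {
    ch <- if (grepl("^(eeg|cplx)_", j)) strsplit(j, "_")[[1]][2] else
      NA_character_
    res <- tryCatch(correlate(features[[j]], features$rating,
                              feature = j, channel = ch),
                    error = function(e) NULL)
    if (!is.null(res)) cors[[j]] <- res
  }
  correlations <- do.call(rbind, cors)
  if (!is.null(correlations)) {
    grp <- if (bh_scope == "channel") {
      ifelse(is.na(correlations$channel), "scalar", correlations$channel)
    } else rep("all", nrow(correlations))
    correlations$q <- bh_adjust(correlations$p, grp)
  }
  rownames(comparisons) <- rownames(correlations) <- NULL
  list(comparisons = comparisons, correlations = correlations)
}

#' Run the full pipeline
#'
#' simulate -> extract -> analyze -> predict, writing every stage's
#' output and a run manifest (parameter echo, seeds, md5 content hashes)
#' into `out_dir`. Stages whose outputs already exist in `out_dir` are
#' skipped, so an interrupted run resumes at the first incomplete stage.
#' Re-running a completed directory with the same configuration
#' reproduces identical hashes.
#'
#' @param config a [run_config()], a YAML path, or a plain list.
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, verbose = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  p <- function(f) file.path(out_dir, f)

  say("stage 1/4: simulate cohort")
  cohort <- generate_cohort(cfg$cohort)
  utils::write.csv(cohort$manifest, p("cohort_manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, p("cohort_truth.csv"), row.names = FALSE)

  feat_path <- p("features.csv")
  if (file.exists(feat_path)) {
    say("stage 2/4: features present, resuming")
    features <- utils::read.csv(feat_path, stringsAsFactors = FALSE)
  } else {
    say("stage 2/4: extract features (%d trials)", nrow(cohort$manifest))
    features <- extract_cohort_features(cohort, cfg$features$families,
                                        verbose = verbose)
    utils::write.csv(features, feat_path, row.names = FALSE)
  }

  say("stage 3/4: statistical analysis")
  ana <- .analyze_features(features, cfg$analysis$bh_scope)
  if (!is.null(ana$comparisons))
    utils::write.csv(ana$comparisons, p("genre_comparisons.csv"),
                     row.names = FALSE)
  utils::write.csv(ana$correlations, p("rating_correlations.csv"),
                   row.names = FALSE)

  say("stage 4/4: prediction (%s)", cfg$prediction$task)
  mat <- assemble_matrix(features)
  report <- lofo_evaluate(mat, task = cfg$prediction$task,
                          models = cfg$prediction$models,
                          k = cfg$prediction$k,
                          seed = cfg$seed_pipeline,
                          global_selection = cfg$prediction$global_selection)
  utils::write.csv(report$per_film, p("prediction_per_film.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(task = report$task, mean = as.list(report$mean),
         selected = lapply(report$selected, function(s) s$feature),
         settings = report$settings),
    p("prediction_report.json"), auto_unbox = TRUE, digits = NA)

  files <- setdiff(list.files(out_dir), "run_manifest.json")
  manifest <- list(
    config = list(cohort = unclass(cfg$cohort)[setdiff(names(cfg$cohort), "films")],
                  films = cfg$cohort$films,
                  features = cfg$features, analysis = cfg$analysis,
                  prediction = report$settings,
                  seed_pipeline = cfg$seed_pipeline),
    files = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
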