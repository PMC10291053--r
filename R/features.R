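# Per-trial feature extraction and assembly of the subjects x films
# feature matrix. Every feature enters the matrix rest-baseline
# corrected; column names are fully qualified as
# <stream>_<channel>_<feature>_blc (scalars omit the channel).

#' Extract all physiological features of one trial
#'
#' Runs the full reduction chain on a [generate_trial()] recording (or a
#' trial read from disk): EEG preprocessing, Welch band powers, band
#' ratios and engagement/arousal/valence indices, the 11 complexity
#' measures per channel, PPG beat detection + Hampel cleaning + HRV,
#' rectified EMG means, and the SCR statistic; all baseline-corrected
#' against the trial's 60-s rest segment where a baseline is defined.
#' Complexity measures are computed on the cleaned film-segment EEG
#' (no rest correction: they are scale-free descriptors of the trial).
#'
#' @param trial a `trial_recording`.
#' @param families subset of `c("eeg", "complexity", "cardiac", "emg",
#'   "eda")` to extract.
#' @return named list of features (NA where a stream is missing or an
#'   index is undefined).
#' @export
extract_trial_features <- function(trial,
                                   families = c("eeg", "complexity",
                                                "cardiac", "emg", "eda")) {
  stopifnot(inherits(trial, "trial_recording"))
  feats <- list()
  st <- trial$streams

  if (any(c("eeg", "complexity") %in% families) && !is.null(st$eeg)) {
    prep_t <- preprocess_eeg(st$eeg$film, st$eog$film, st$eeg$sfreq)
    if ("eeg" %in% families) {
      prep_r <- preprocess_eeg(st$eeg$rest, st$eog$rest, st$eeg$sfreq)
      bp_t <- welch_band_powers(prep_t$eeg, prep_t$sfreq, prep_t$mask)
      bp_r <- welch_band_powers(prep_r$eeg, prep_r$sfreq, prep_r$mask)
      idx <- compute_indices(bp_t, bp_r)
      ch_corr <- idx$channel[idx$channel$phase == "corrected", ]
      for (col in c("theta_alpha", "theta_beta", "alpha_beta",
                    "engagement_abt", "engagement_ba")) {
        v <- ch_corr[[col]]
        names(v) <- paste0("eeg_", ch_corr$channel, "_", col, "_blc")
        feats <- c(feats, as.list(v))
      }
      # band powers themselves, baseline-corrected
      for (band in c("theta", "alpha", "beta")) {
        v <- bp_t[[band]] - bp_r[[band]][match(bp_t$channel, bp_r$channel)]
        names(v) <- paste0("eeg_", bp_t$channel, "_", band, "_blc")
        feats <- c(feats, as.list(v))
      }
      sc <- idx$scalar[idx$scalar$phase == "corrected", ]
      feats$eeg_arousal_blc <- sc$arousal
      feats$eeg_valence_blc <- sc$valence
    }
    if ("complexity" %in% families) {
      keep <- !prep_t$mask
      for (ch in colnames(prep_t$eeg)) {
        cx <- compute_complexity(prep_t$eeg[keep, ch], prep_t$sfreq)
        names(cx) <- paste0("cplx_", ch, "_", names(cx))
        feats <- c(feats, as.list(cx))
      }
    }
  }

  if ("cardiac" %in% families && !is.null(st$ppg)) {
    hv <- tryCatch({
      rt <- hampel_clean(detect_beats(st$ppg$film, st$ppg$sfreq))
      rr <- hampel_clean(detect_beats(st$ppg$rest, st$ppg$sfreq))
      hrv_features(rt, rr)
    }, error = function(e) NULL)
    nm <- c("hr", "sdnn", "rmssd", "sdsd", "pnn20", "pnn50", "mad",
            "sd1", "sd2", "sd1_sd2")
    v <- if (is.null(hv)) stats::setNames(rep(NA_real_, 10), nm) else
      stats::setNames(hv$corrected[match(nm, hv$feature)], nm)
    names(v) <- paste0("hrv_", nm, "_blc")
    feats <- c(feats, as.list(v))
  }

  if ("emg" %in% families) {
    for (mus in c("emg_zyg", "emg_corr")) {
      v <- if (is.null(st[[mus]])) NA_real_ else
        emg_trial_mean(st[[mus]]$film, st[[mus]]$sfreq, st[[mus]]$rest)$corrected
      feats[[paste0(mus, "_rectmean_blc")]] <- v
    }
  }

  if ("eda" %in% families) {
    feats$eda_scr_sum_per_s_blc <- if (is.null(st$eda)) NA_real_ else
      eda_scr_statistic(st$eda$film, st$eda$sfreq, st$eda$rest)$corrected
  }
  feats
}

#' Extract features for a whole cohort
#'
#' Materialises each trial in turn (constant memory), extracts its
#' features, and returns one row per subject x film.
#'
#' @param cohort a [generate_cohort()] result.
#' @param families feature families, see [extract_trial_features()].
#' @param verbose print progress.
#' @return data.frame: identifiers (`subject_id`, `film_id`, `genre`,
#'   `rating`) followed by feature columns.
#' @export
extract_cohort_features <- function(cohort,
                                    families = c("eeg", "complexity",
                                                 "cardiac", "emg", "eda"),
                                    verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  streams <- unique(c(if (any(c("eeg", "complexity") %in% families)) "eeg",
                      if ("cardiac" %in% families) "ppg",
                      if ("emg" %in% families) "emg",
                      if ("eda" %in% families) "eda"))
  man <- cohort$manifest
  rows <- vector("list", nrow(man))
  for (k in seq_len(nrow(man))) {
    trial <- if (!is.null(cohort$recordings)) {
      cohort$recordings[[paste(man$subject_id[k], man$film_id[k], sep = "_")]]
    } else {
      generate_trial(cohort, man$subject_id[k], man$film_id[k], streams)
    }
    rows[[k]] <- unlist(extract_trial_features(trial, families))
    if (verbose && k %% 10 == 0)
      message(sprintf("extracted %d/%d trials", k, nrow(man)))
  }
  feat <- as.data.frame(do.call(rbind, rows))
  cbind(man[c("subject_id", "film_id", "genre", "rating")], feat)
}

#' Assemble the prediction feature matrix
#'
#' One row per subject x film trial: identifier columns (`subject_id`,
#' `film_id`, `rating` -- never imputed, never used as predictors) and
#' all baseline-corrected feature columns.
#'
#' @param features data.frame from [extract_cohort_features()] (or
#'   rbind-compatible per-trial outputs).
#' @return object of class `feature_matrix` (a data.frame).
#' @export
assemble_matrix <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("subject_id", "film_id", "rating") %in% names(features)))
  if (anyDuplicated(features[c("subject_id", "film_id")]))
    stop("duplicated subject x film rows")
  drop <- intersect(names(features), "genre")
  out <- features[setdiff(names(features), drop)]
  class(out) <- c("feature_matrix", "data.frame")
  out
}

# names of predictor (feature) columns of a feature matrix
.feature_cols <- function(m) {
  setdiff(names(m), c("subject_id", "film_id", "genre", "rating", "label"))
}
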