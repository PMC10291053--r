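# Synthetic cohort: 21 subjects x 8 short films with planted effect
# structure (genre -> facial EMG, engagement/valence -> rating).

#' Default film set
#'
#' Eight short films, four comedies and four dramas, with durations
#' between 261 and 445 s.
#'
#' @return data.frame with columns `film_id`, `duration`, `genre`.
#' @export
default_films <- function() {
  data.frame(
    film_id = paste0("film", 1:8),
    duration = c(318, 395, 364, 445, 261, 391, 346, 394),
    genre = rep(c("comedy", "drama"), each = 4),
    stringsAsFactors = FALSE
  )
}

#' Cohort configuration
#'
#' Assembles and validates the full parameter set of the synthetic cohort
#' generator. The defaults emulate the reference study design: 21
#' subjects, 8 films (4 comedies, 4 dramas, 261-445 s), a 60-s pre-film
#' rest segment per trial, EEG/EOG/EMG recorded at 1000 Hz, and integer
#' ratings on a 1-10 scale.
#'
#' Effect sizes are planted as ground truth: `genre_emg_d` is the paired
#' Cohen's d of the genre contrast planted on zygomaticus (comedy high)
#' and corrugator (drama high) burst amplitudes; `rating_engagement_r` and
#' `rating_valence_r` are the target trialwise Pearson correlations
#' between the latent engagement/valence levels and the rating.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param films data.frame as [default_films()].
#' @param sfreq_eeg,sfreq_emg,sfreq_ppg,sfreq_eda per-stream sampling
#'   rates, Hz.
#' @param rest_duration rest-baseline length preceding each film, s.
#' @param genre_emg_d planted paired Cohen's d on facial EMG by genre.
#' @param rating_engagement_r,rating_valence_r target latent-rating
#'   correlations, absolute value < 1 and jointly admissible.
#' @param rating_mean,rating_subject_sd,rating_total_sd rating scale
#'   location, between-subject SD of subject means, and total pre-rounding
#'   SD of ratings.
#' @param engagement_coupling scale of latent-engagement modulation of the
#'   EEG beta band weight.
#' @param valence_coupling scale of latent-valence modulation of frontal
#'   alpha asymmetry.
#' @param emg_burst_amplitude,emg_genre_sd mean facial-EMG burst amplitude
#'   (µV) and between-subject SD of the planted genre contrast (µV).
#' @param seed master seed; every per-trial stream seed is derived from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 21, films = default_films(),
                          sfreq_eeg = 1000, sfreq_emg = 1000,
                          sfreq_ppg = 100, sfreq_eda = 20,
                          rest_duration = 60,
                          genre_emg_d = 0.7,
                          rating_engagement_r = 0.4,
                          rating_valence_r = 0.25,
                          rating_mean = 6.2, rating_subject_sd = 1,
                          rating_total_sd = 2.4,
                          engagement_coupling = 0.25,
                          valence_coupling = 0.3,
                          emg_burst_amplitude = 4, emg_genre_sd = 1.2,
                          seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("`n_subjects` must be >= 2")
  stopifnot(is.data.frame(films),
            all(c("film_id", "duration", "genre") %in% names(films)))
  if (nrow(films) < 2) stop("`films` must contain at least 2 films")
  if (any(films$duration <= 0)) stop("`films$duration` must be > 0")
  if (!all(films$genre %in% c("comedy", "drama")))
    stop("`films$genre` must be 'comedy' or 'drama'")
  if (anyDuplicated(films$film_id)) stop("`films$film_id` must be unique")
  .assert_scalar(genre_emg_d, "genre_emg_d")
  if (genre_emg_d != 0 && length(unique(films$genre)) < 2)
    stop("`films` needs at least one film per genre when `genre_emg_d` != 0")
  .assert_scalar(rating_engagement_r, "rating_engagement_r", -1 + 1e-9, 1 - 1e-9)
  .assert_scalar(rating_valence_r, "rating_valence_r", -1 + 1e-9, 1 - 1e-9)
  if (rating_engagement_r^2 + rating_valence_r^2 >=
      1 - (rating_subject_sd / rating_total_sd)^2)
    stop("`rating_engagement_r`/`rating_valence_r` jointly too large for the configured rating variance")
  .assert_scalar(rest_duration, "rest_duration", 0, strict_lo = TRUE)
  .assert_scalar(seed, "seed")
  for (nm in c("sfreq_eeg", "sfreq_emg", "sfreq_ppg", "sfreq_eda"))
    .assert_scalar(get(nm), nm, 0, strict_lo = TRUE)
  if (sfreq_emg < 700) stop("`sfreq_emg` must be >= 700 Hz")
  structure(list(
    n_subjects = as.integer(n_subjects), films = films,
    sfreq_eeg = sfreq_eeg, sfreq_emg = sfreq_emg, sfreq_ppg = sfreq_ppg,
    sfreq_eda = sfreq_eda, rest_duration = rest_duration,
    genre_emg_d = genre_emg_d,
    rating_engagement_r = rating_engagement_r,
    rating_valence_r = rating_valence_r,
    rating_mean = rating_mean, rating_subject_sd = rating_subject_sd,
    rating_total_sd = rating_total_sd,
    engagement_coupling = engagement_coupling,
    valence_coupling = valence_coupling,
    emg_burst_amplitude = emg_burst_amplitude, emg_genre_sd = emg_genre_sd,
    seed = seed
  ), class = "cohort_config")
}

# Solve the rating-model coefficients for the configured target
# correlations: rating* = mu_s + b_e z_e + b_v z_v + noise, with
# corr(z_e, rating*) = r_e requiring b_e = r_e * sigma_total, and the
# residual SD chosen to keep the total SD at its configured value.
.rating_betas <- function(config) {
  s_tot <- config$rating_total_sd
  b_e <- config$rating_engagement_r * s_tot
  b_v <- config$rating_valence_r * s_tot
  v_noise <- s_tot^2 - config$rating_subject_sd^2 - b_e^2 - b_v^2
  list(b_e = b_e, b_v = b_v, sd_noise = sqrt(v_noise))
}

#' Generate a synthetic cohort
#'
#' Draws all cohort-level latent variables (subject rating means, per-trial
#' engagement/valence/arousal levels, planted EMG genre contrasts) and the
#' integer ratings, and derives the per-trial stream seeds. Trial
#' waveforms are generated on demand with [generate_trial()]; with
#' `materialize = TRUE` all trial recordings are returned in memory (only
#' sensible for reduced configurations -- a full-length default cohort
#' would occupy on the order of 10 GB).
#'
#' Ratings are `round(clip(mu_s + b_e z_e + b_v z_v + noise, 1, 10))`
#' with coefficients solved so that the trialwise latent-rating
#' correlations hit the configured targets before rounding.
#'
#' @param config a [cohort_config()].
#' @param materialize logical; also generate every [generate_trial()]
#'   recording now.
#' @return object of class `cohort`: list with `manifest` (one row per
#'   subject x film: ids, genre, duration, rating), `truth` (latent
#'   engagement/valence/arousal and planted per-stream parameters per
#'   trial), `config`, and (if materialised) `recordings`.
#' @export
generate_cohort <- function(config = cohort_config(), materialize = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  ns <- config$n_subjects
  nf <- nrow(config$films)
  st <- .seed_table(config$seed, ns, nf)
  betas <- .rating_betas(config)

  grid <- expand.grid(subject = seq_len(ns), film = seq_len(nf),
                      KEEP.OUT.ATTRS = FALSE)
  cohort_lat <- .with_seed(st$cohort, {
    list(mu_s = stats::rnorm(ns, config$rating_mean, config$rating_subject_sd),
         # per-subject planted genre contrast on EMG burst amplitude (µV)
         delta_zyg = stats::rnorm(ns, config$genre_emg_d * config$emg_genre_sd,
                                  config$emg_genre_sd),
         delta_corr = stats::rnorm(ns, config$genre_emg_d * config$emg_genre_sd,
                                   config$emg_genre_sd),
         subj_rr = stats::rnorm(ns, 820, 60),
         subj_emg_gain = exp(stats::rnorm(ns, 0, 0.15)))
  })

  # trial latents from the per-trial "latent" seed stream
  lat <- t(vapply(seq_len(nrow(grid)), function(k) {
    i <- grid$subject[k]; j <- grid$film[k]
    .with_seed(st$trial[i, j, "latent"], {
      z_e <- stats::rnorm(1); z_v <- stats::rnorm(1)
      z_a <- 0.6 * z_e + 0.8 * stats::rnorm(1)
      noise <- stats::rnorm(1, 0, betas$sd_noise)
      c(z_e = z_e, z_v = z_v, z_a = z_a, noise = noise)
    })
  }, numeric(4)))

  rating_star <- cohort_lat$mu_s[grid$subject] +
    betas$b_e * lat[, "z_e"] + betas$b_v * lat[, "z_v"] + lat[, "noise"]
  rating <- as.integer(round(pmin(pmax(rating_star, 1), 10)))

  films <- config$films
  is_comedy <- films$genre[grid$film] == "comedy"
  # genre contrast planted on the deterministic EMG baseline envelope, so
  # the realized paired d is not diluted by Poisson burst noise
  lvl_zyg <- pmax(2 + ifelse(is_comedy, 0.5, -0.5) *
                    cohort_lat$delta_zyg[grid$subject], 0.3)
  lvl_corr <- pmax(2 + ifelse(is_comedy, -0.5, 0.5) *
                     cohort_lat$delta_corr[grid$subject], 0.3)
  beta_w <- pmax(1 + config$engagement_coupling * lat[, "z_e"], 0.05)

  manifest <- data.frame(
    subject_id = sprintf("s%02d", grid$subject),
    film_id = films$film_id[grid$film],
    genre = films$genre[grid$film],
    duration = films$duration[grid$film],
    rating = rating,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    subject_id = manifest$subject_id, film_id = manifest$film_id,
    engagement = lat[, "z_e"], valence = lat[, "z_v"], arousal = lat[, "z_a"],
    rating_star = rating_star,
    beta_weight = beta_w,
    emg_zyg_level = lvl_zyg, emg_corr_level = lvl_corr,
    emg_gain = cohort_lat$subj_emg_gain[grid$subject],
    mean_rr = cohort_lat$subj_rr[grid$subject],
    stringsAsFactors = FALSE
  )
  cohort <- structure(list(manifest = manifest, truth = truth,
                           config = config, seeds = st),
                      class = "cohort")
  if (materialize) {
    cohort$recordings <- lapply(seq_len(nrow(manifest)), function(k)
      generate_trial(cohort, manifest$subject_id[k], manifest$film_id[k]))
    names(cohort$recordings) <- paste(manifest$subject_id, manifest$film_id,
                                      sep = "_")
  }
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d films = %d trials (seed %s)\n",
              x$config$n_subjects, nrow(x$config$films), nrow(x$manifest),
              format(x$config$seed)))
  invisible(x)
}

#' Generate one trial recording
#'
#' Materialises the multimodal recording (rest + film segment for every
#' stream) of one subject x film trial, reproducibly from the cohort's
#' derived seed table. Streams: 18-channel EEG + EOG (1000 Hz), PPG,
#' zygomaticus and corrugator EMG, EDA, each with its own 60-s rest
#' segment.
#'
#' @param cohort a [generate_cohort()] result.
#' @param subject_id,film_id identifiers from the cohort manifest.
#' @param streams subset of `c("eeg","ppg","emg","eda")` to generate.
#' @return object of class `trial_recording`.
#' @export
generate_trial <- function(cohort, subject_id, film_id,
                           streams = c("eeg", "ppg", "emg", "eda")) {
  stopifnot(inherits(cohort, "cohort"))
  cfg <- cohort$config
  k <- which(cohort$manifest$subject_id == subject_id &
               cohort$manifest$film_id == film_id)
  if (length(k) != 1) stop("unknown subject_id/film_id combination")
  i <- match(subject_id, sprintf("s%02d", seq_len(cfg$n_subjects)))
  j <- match(film_id, cfg$films$film_id)
  man <- cohort$manifest[k, ]
  tru <- cohort$truth[k, ]
  dur <- man$duration
  rest <- cfg$rest_duration
  sd_tab <- cohort$seeds$trial
  out <- list(subject_id = subject_id, film_id = film_id,
              genre = man$genre, rating = man$rating, duration = dur,
              rest_duration = rest, sfreq = list(), streams = list())
  if ("eeg" %in% streams) {
    bw_film <- c(theta = 1, alpha = 1, beta = tru$beta_weight)
    # valence planted as frontal alpha asymmetry: F4 vs F3 alpha gain
    vshift <- cfg$valence_coupling * tru$valence
    g <- rep(1, 18); names(g) <- eeg_channels()
    film_eeg <- synth_eeg(dur, cfg$sfreq_eeg, bw_film,
                          seed = sd_tab[i, j, "eeg"])
    rest_eeg <- synth_eeg(rest, cfg$sfreq_eeg, c(theta = 1, alpha = 1, beta = 1),
                          seed = sd_tab[i, j, "eog"])
    # asymmetric alpha modulation of the film segment
    if (vshift != 0) {
      a_f4 <- fft_bandpass(film_eeg$eeg[, "F4"], cfg$sfreq_eeg, 8, 12, 0.5)
      a_f3 <- fft_bandpass(film_eeg$eeg[, "F3"], cfg$sfreq_eeg, 8, 12, 0.5)
      s4 <- sqrt(pmax(1 + vshift, 0.1)); s3 <- sqrt(pmax(1 - vshift, 0.1))
      film_eeg$eeg[, "F4"] <- film_eeg$eeg[, "F4"] + (s4 - 1) * a_f4
      film_eeg$eeg[, "F3"] <- film_eeg$eeg[, "F3"] + (s3 - 1) * a_f3
    }
    out$streams$eeg <- list(film = film_eeg$eeg, rest = rest_eeg$eeg,
                            sfreq = cfg$sfreq_eeg)
    out$streams$eog <- list(film = film_eeg$eog, rest = rest_eeg$eog,
                            sfreq = cfg$sfreq_eeg)
    out$sfreq$eeg <- cfg$sfreq_eeg
    out$sfreq$eog <- cfg$sfreq_eeg
  }
  if ("ppg" %in% streams) {
    cc <- synth_cardiac(dur + rest, mean_rr = tru$mean_rr,
                        sdnn_target = 50, phi = 0.8,
                        seed = sd_tab[i, j, "ppg"], sfreq = cfg$sfreq_ppg)
    nr <- round(rest * cfg$sfreq_ppg)
    out$streams$ppg <- list(film = cc$ppg[(nr + 1):length(cc$ppg)],
                            rest = cc$ppg[1:nr], sfreq = cfg$sfreq_ppg,
                            truth = list(beat_times = cc$beat_times))
    out$sfreq$ppg <- cfg$sfreq_ppg
  }
  if ("emg" %in% streams) {
    for (mus in c("emg_zyg", "emg_corr")) {
      lvl <- if (mus == "emg_zyg") tru$emg_zyg_level else tru$emg_corr_level
      seed_m <- sd_tab[i, j, mus]
      film_m <- synth_emg(dur, cfg$sfreq_emg, burst_rate = 8,
                          burst_amplitude = cfg$emg_burst_amplitude * tru$emg_gain,
                          baseline_level = lvl, seed = seed_m)
      rest_m <- synth_emg(rest, cfg$sfreq_emg, burst_rate = 2,
                          burst_amplitude = cfg$emg_burst_amplitude * 0.5,
                          baseline_level = 2, seed = seed_m - 1)
      out$streams[[mus]] <- list(film = film_m$emg, rest = rest_m$emg,
                                 sfreq = cfg$sfreq_emg,
                                 truth = film_m$truth)
      out$sfreq[[mus]] <- cfg$sfreq_emg
    }
  }
  if ("eda" %in% streams) {
    ee <- synth_eda(dur + rest, cfg$sfreq_eda, scr_rate = 4,
                    scr_amplitude = 0.5, seed = sd_tab[i, j, "eda"])
    nr <- round(rest * cfg$sfreq_eda)
    out$streams$eda <- list(film = ee$eda[(nr + 1):length(ee$eda)],
                            rest = ee$eda[1:nr], sfreq = cfg$sfreq_eda,
                            truth = ee$truth)
    out$sfreq$eda <- cfg$sfreq_eda
  }
  structure(out, class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("Trial %s / %s (%s, %ds film + %ds rest), rating %d; streams: %s\n",
              x$subject_id, x$film_id, x$genre, x$duration, x$rest_duration,
              x$rating, paste(names(x$streams), collapse = ", ")))
  invisible(x)
}
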