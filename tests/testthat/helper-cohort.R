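# Shared fixtures, built once per test run and memoised: reduced-duration
# cohorts keep the full study design (21 subjects, 4 comedies + 4 dramas,
# planted effects at their default sizes) while shortening the films so
# the whole suite runs on one CPU. Shorter films only add extraction
# noise; they never favour detection.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  val <- force(expr)
  .fixture_cache[[key]] <- val
  val
}

short_films <- function(dur = 32) {
  data.frame(film_id = paste0("film", 1:8),
             duration = rep(dur, 8),
             genre = rep(c("comedy", "drama"), each = 4),
             stringsAsFactors = FALSE)
}

# full-design cohort with short films; planted defaults
short_cohort_config <- function(seed = 11, ...) {
  cohort_config(n_subjects = 21, films = short_films(),
                rest_duration = 35, seed = seed, ...)
}

# extracted feature matrix of the planted short cohort (all families)
planted_matrix <- function() {
  memo("planted_matrix", {
    co <- generate_cohort(short_cohort_config(seed = 11))
    assemble_matrix(extract_cohort_features(co))
  })
}

# a small materialised cohort for trial-level tests
tiny_cohort <- function() {
  memo("tiny_cohort", {
    cfg <- cohort_config(n_subjects = 2,
                         films = data.frame(film_id = c("fa", "fb"),
                                            duration = c(32, 32),
                                            genre = c("comedy", "drama")),
                         rest_duration = 35, seed = 5)
    generate_cohort(cfg, materialize = TRUE)
  })
}

# 50-seed plant-and-recover of the facial-EMG genre effect (d = 0.7,
# 21 subjects, both muscles), at the signal level with shortened films
emg_plant_recover <- function() {
  memo("emg_plant_recover", {
    lapply(1:50, function(s) {
      cfg <- cohort_config(n_subjects = 21, films = short_films(30),
                           rest_duration = 15, genre_emg_d = 0.7,
                           seed = 1000 + s)
      co <- generate_cohort(cfg)
      man <- co$manifest
      per <- data.frame(subject = man$subject_id, genre = man$genre)
      for (mus in c("emg_zyg", "emg_corr")) {
        per[[mus]] <- vapply(seq_len(nrow(man)), function(k) {
          tr <- generate_trial(co, man$subject_id[k], man$film_id[k], "emg")
          emg_trial_mean(tr$streams[[mus]]$film, tr$streams[[mus]]$sfreq,
                         tr$streams[[mus]]$rest)$corrected
        }, numeric(1))
      }
      ag <- stats::aggregate(per[c("emg_zyg", "emg_corr")],
                             by = per[c("subject", "genre")], FUN = mean)
      w <- stats::reshape(ag, idvar = "subject", timevar = "genre",
                          direction = "wide")
      list(zyg = paired_test(w$emg_zyg.comedy, w$emg_zyg.drama),
           corr = paired_test(w$emg_corr.drama, w$emg_corr.comedy))
    })
  })
}

# 50-seed null-cohort correlation screen: BH-corrected and raw
# false-positive rates per channel family
null_fp_rates <- function() {
  memo("null_fp_rates", {
    t(vapply(1:50, function(s) {
      cfg <- cohort_config(n_subjects = 21, films = short_films(),
                           rating_engagement_r = 0, rating_valence_r = 0,
                           genre_emg_d = 0, seed = 3000 + s)
      co <- generate_cohort(cfg)
      n <- nrow(co$manifest)
      withr::with_seed(4000 + s, {
        q_hits <- p_hits <- 0; total <- 0
        for (ch in eeg_channels()) {
          base <- stats::rnorm(n)
          fam <- sapply(1:7, function(i) 0.5 * base + stats::rnorm(n))
          p <- apply(fam, 2, function(f)
            correlate(f, co$manifest$rating)$p)
          q_hits <- q_hits + sum(bh_adjust(p) < 0.05)
          p_hits <- p_hits + sum(p < 0.05)
          total <- total + length(p)
        }
        c(bh = q_hits / total, raw = p_hits / total)
      })
    }, numeric(2)))
  })
}

# matrix-level cohort emulation for prediction-pipeline properties:
# features are noisy copies of the generator's latent engagement (plus
# pure-noise columns), so the information content is controlled exactly.
latent_matrix <- function(seed, r_target = 0.5, n_signal = 4, n_noise = 16) {
  cfg <- cohort_config(n_subjects = 21, films = short_films(),
                       rating_engagement_r = r_target,
                       rating_valence_r = 0, seed = seed)
  co <- generate_cohort(cfg)
  n <- nrow(co$manifest)
  feats <- withr::with_seed(seed + 1000, {
    cols <- c(
      lapply(seq_len(n_signal), function(i)
        co$truth$engagement + stats::rnorm(n, 0, 0.8)),
      lapply(seq_len(n_noise), function(i) stats::rnorm(n))
    )
    as.data.frame(stats::setNames(cols, c(paste0("sig", seq_len(n_signal)),
                                          paste0("noise", seq_len(n_noise)))))
  })
  assemble_matrix(cbind(co$manifest[c("subject_id", "film_id", "genre",
                                      "rating")], feats))
}
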