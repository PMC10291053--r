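# synthetic signal generators: constructed spectra, beat statistics,
# envelope closed forms, SCR kernels, determinism

test_that("synth_eeg concentrates power in the requested band", {
  e <- synth_eeg(60, 1000, c(theta = 0, alpha = 1, beta = 0),
                 blink_rate = 0, seed = 2)
  ps <- welch_psd(e$eeg[, "Cz"], 1000, window = 4000)
  pow <- function(lo, hi) sum(ps$psd[ps$freq >= lo & ps$freq < hi])
  expect_gt(pow(8, 12) / pow(4, 30), 0.8)
  expect_equal(dim(e$eeg), c(60000L, 18L))
  expect_setequal(colnames(e$eeg), eeg_channels())
})

test_that("synth_eeg without blinks leaves the EOG as pure noise", {
  e <- synth_eeg(20, 1000, blink_rate = 0, seed = 3)
  expect_length(e$truth$blink_onsets, 0)
  expect_lt(max(abs(e$eog)), 12)          # gaussian noise, sd 2
  e2 <- synth_eeg(20, 1000, blink_rate = 20, seed = 3)
  expect_gt(max(e2$eog), 100)             # blink template peaks ~150 µV
})

test_that("doubling the beta weight increases every channel's beta/alpha index", {
  extract_ba <- function(w_beta) {
    e <- synth_eeg(40, 1000, c(theta = 1, alpha = 1, beta = w_beta),
                   blink_rate = 0, seed = 9)
    bp <- welch_band_powers(fft_decimate(e$eeg, 8, 1000), 125)
    bp$beta / bp$alpha
  }
  expect_true(all(extract_ba(2) > extract_ba(1)))
})

test_that("synth_cardiac hits the configured beat count and SDNN", {
  cc <- synth_cardiac(400, mean_rr = 800, sdnn_target = 0, seed = 4)
  expect_equal(length(cc$beat_times), 499, tolerance = 2)
  expect_lt(sd(cc$rr), 1e-6)              # constant RR series
  long <- synth_cardiac(10000 * 0.8, mean_rr = 800, sdnn_target = 50,
                        phi = 0.8, seed = 5, sfreq = 20)
  expect_gt(length(long$rr), 9000)
  expect_equal(sd(long$rr), 50, tolerance = 3)
})

test_that("synth_cardiac validates parameters", {
  expect_error(synth_cardiac(60, mean_rr = -5), "mean_rr")
  expect_error(synth_cardiac(60, phi = 1.2), "phi")
  expect_error(synth_cardiac(0), "duration")
})

test_that("synth_emg rectified mean follows the envelope closed form", {
  # no bursts: E|x| = baseline * E|carrier| with E|carrier| = sqrt(2/pi)
  e <- synth_emg(60, 1000, burst_rate = 0, baseline_level = 3, seed = 6)
  expect_equal(mean(abs(e$emg)), 3 * sqrt(2 / pi), tolerance = 0.05 * 3)
  # monotone in burst amplitude
  m1 <- emg_trial_mean(synth_emg(60, 1000, burst_rate = 10,
                                 burst_amplitude = 2, seed = 7)$emg)$rectified_mean
  m2 <- emg_trial_mean(synth_emg(60, 1000, burst_rate = 10,
                                 burst_amplitude = 4, seed = 7)$emg)$rectified_mean
  expect_gt(m2, m1)
})

test_that("two EMG seeds differ in waveform but agree in statistics", {
  a <- synth_emg(60, 1000, seed = 1)$emg
  b <- synth_emg(60, 1000, seed = 2)$emg
  expect_gt(max(abs(a - b)), 0.1)
  expect_equal(mean(abs(a)), mean(abs(b)), tolerance = 0.15 * mean(abs(a)))
})

test_that("bateman_peak matches the analytic kernel maximum", {
  bp <- bateman_peak(1, 4)
  tt <- seq(0, 20, by = 1e-4)
  k <- exp(-tt / 4) - exp(-tt / 1)
  expect_equal(bp$peak, max(k), tolerance = 1e-6)
  expect_equal(bp$t_peak, tt[which.max(k)], tolerance = 1e-3)
  expect_error(bateman_peak(4, 1), "tau_r")
})

test_that("synth_eda returns recoverable planted events", {
  e <- synth_eda(300, 20, scr_rate = 4, scr_amplitude = 0.5, seed = 8)
  expect_equal(length(e$truth$event_times), 20, tolerance = 10)
  res <- eda_scr_statistic(e$eda, 20)
  # at least 80% of planted events found within 3 s of a detected peak
  hits <- vapply(e$truth$event_times, function(tm)
    any(abs(res$peak_times - (tm + bateman_peak()$t_peak)) < 3), logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("generators are deterministic and leave the global RNG untouched", {
  set.seed(123); before <- rnorm(1)
  a <- synth_eeg(12, 1000, seed = 10)
  b <- synth_eeg(12, 1000, seed = 10)
  expect_identical(a, b)
  set.seed(123)
  expect_identical(rnorm(1), before)
})
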