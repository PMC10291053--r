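# EEG preprocessing chain and band-power indices

make_raw <- function(n_s = 20, sfreq = 1000, f0 = 10, amp = 20,
                     noise = 1, seed = 51) {
  withr::with_seed(seed, {
    t <- seq_len(n_s * sfreq) / sfreq
    base <- amp * sin(2 * pi * f0 * t)
    eeg <- sapply(seq_len(18), function(i) base + rnorm(length(t), 0, noise))
    colnames(eeg) <- eeg_channels()
    list(eeg = eeg, eog = rnorm(length(t), 0, 1), t = t)
  })
}

test_that("preprocessing downsamples, band-limits and validates input", {
  raw <- make_raw()
  out <- preprocess_eeg(raw$eeg, raw$eog, 1000)
  expect_equal(out$sfreq, 125)
  expect_equal(nrow(out$eeg), nrow(raw$eeg) / 8)
  expect_error(preprocess_eeg(raw$eeg[, 1:5], raw$eog, 1000), "18")
  expect_error(preprocess_eeg(raw$eeg[1:5000, ], raw$eog[1:5000], 1000),
               "10 s")
})

test_that("a 50 Hz tone is rejected by the 0.05-30 Hz chain", {
  withr::with_seed(52, {
    t <- seq_len(20000) / 1000
    tone <- 30 * sin(2 * pi * 50 * t)
    eeg <- sapply(1:18, function(i) tone + rnorm(20000, 0, 0.5))
    colnames(eeg) <- eeg_channels()
    out <- preprocess_eeg(eeg, rnorm(20000), 1000)
    bp <- welch_band_powers(out$eeg, out$sfreq, out$mask)
    pow_4_30 <- sum(bp$theta + bp$alpha + bp$beta)
    # input tone power is 450 µV²; virtually none may survive in 4-30 Hz
    expect_lt(pow_4_30, 0.01 * 450)
  })
})

test_that("a gross spike is masked and leaves the remaining PSD unchanged", {
  raw <- make_raw(n_s = 60)
  spiked <- raw$eeg
  # large enough to trip the z > 10 mask, small enough not to dominate
  # the channel's total power (that regime is handled by interpolation)
  spiked[30000, "Cz"] <- spiked[30000, "Cz"] + 3000
  clean <- preprocess_eeg(raw$eeg, raw$eog, 1000)
  spk <- preprocess_eeg(spiked, raw$eog, 1000)
  # the spike neighbourhood (30000/8 = 3750 at 125 Hz) is masked
  expect_true(any(spk$mask[3700:3800]))
  bp_c <- welch_band_powers(clean$eeg[, "F3"], 125, clean$mask)
  bp_s <- welch_band_powers(spk$eeg[, "F3"], 125, spk$mask)
  expect_equal(bp_s$alpha, bp_c$alpha, tolerance = 0.05)
  # an absurd spike turns the whole channel bad: neutralised by
  # interpolation, and the other channels' PSD is unaffected
  spiked2 <- raw$eeg
  spiked2[30000, "Cz"] <- 1e12
  spk2 <- preprocess_eeg(spiked2, raw$eog, 1000)
  expect_true("Cz" %in% spk2$interpolated)
  bp_s2 <- welch_band_powers(spk2$eeg[, "F3"], 125, spk2$mask)
  expect_equal(bp_s2$alpha, bp_c$alpha, tolerance = 0.05)
})

test_that("EOG regression attenuates blink contamination in frontal channels", {
  raw <- make_raw(n_s = 40, amp = 20, seed = 53)
  # isolate the blink component as the with/without-blink difference
  e <- synth_eeg(40, 1000, blink_rate = 20, seed = 54)
  e0 <- synth_eeg(40, 1000, blink_rate = 0, seed = 54)
  eeg <- raw$eeg + (e$eeg - e0$eeg)
  eog <- e$eog - e0$eog + raw$eog
  # blink energy in Fz = variance excess over the blink-free recording,
  # measured before vs after the correction step
  clean <- preprocess_eeg(raw$eeg, raw$eog, 1000)$eeg
  corr <- preprocess_eeg(eeg, eog, 1000)$eeg
  uncorr <- fft_decimate(eeg, 8, 1000); colnames(uncorr) <- eeg_channels()
  unclean <- fft_decimate(raw$eeg, 8, 1000)
  colnames(unclean) <- eeg_channels()
  excess_before <- var(uncorr[, "Fz"]) - var(unclean[, "Fz"])
  excess_after <- var(corr[, "Fz"]) - var(clean[, "Fz"])
  expect_gt(excess_before, 0)
  expect_lt(excess_after / excess_before, 0.2)
})

test_that("outlying channels are replaced by neighbour means", {
  raw <- make_raw(n_s = 20, amp = 10, seed = 55)
  broken <- raw$eeg
  broken[, "P3"] <- broken[, "P3"] * 100
  out <- preprocess_eeg(broken, raw$eog, 1000)
  expect_true("P3" %in% out$interpolated)
  expect_lt(var(out$eeg[, "P3"]) / median(apply(out$eeg, 2, var)), 10)
})

test_that("index formulas reproduce forced values", {
  bp <- data.frame(channel = eeg_channels(), theta = 2, alpha = 2, beta = 2)
  idx <- compute_indices(bp)
  ch <- idx$channel
  expect_equal(ch$engagement_abt, rep(0.5, 18))
  expect_equal(ch$engagement_ba, rep(1, 18))
  expect_equal(idx$scalar$valence, 0)
  expect_equal(idx$scalar$arousal, 1)

  bp2 <- bp
  bp2$alpha[bp2$channel == "F4"] <- 2; bp2$beta[bp2$channel == "F4"] <- 1
  bp2$alpha[bp2$channel == "F3"] <- 1; bp2$beta[bp2$channel == "F3"] <- 2
  idx2 <- compute_indices(bp2)
  expect_equal(idx2$scalar$valence, 2 / 1 - 1 / 2)

  bp3 <- bp
  bp3$beta[bp3$channel %in% c("F3", "F4")] <- 2
  bp3$alpha[bp3$channel %in% c("F3", "F4")] <- 1
  expect_equal(compute_indices(bp3)$scalar$arousal, 2)
})

test_that("zero denominators flag indices as missing instead of fabricating", {
  bp <- data.frame(channel = eeg_channels(), theta = 1, alpha = 1, beta = 1)
  bp$alpha[1] <- 0
  idx <- compute_indices(bp)
  expect_true(is.na(idx$channel$theta_alpha[1]))
  expect_true(is.na(idx$channel$engagement_ba[1]))
  expect_false(anyNA(idx$channel$theta_alpha[-1]))
})

test_that("ratio indices are scale invariant; engagement is monotone in beta", {
  withr::with_seed(56, {
    bp <- data.frame(channel = eeg_channels(), theta = runif(18, 1, 3),
                     alpha = runif(18, 1, 3), beta = runif(18, 1, 3))
  })
  i1 <- compute_indices(bp)
  bp_scaled <- bp; bp_scaled[c("theta", "alpha", "beta")] <-
    bp[c("theta", "alpha", "beta")] * 4.2
  i2 <- compute_indices(bp_scaled)
  expect_equal(i1$channel[-1], i2$channel[-1], tolerance = 1e-12)
  expect_equal(i1$scalar, i2$scalar, tolerance = 1e-12)
  bp_beta <- bp; bp_beta$beta <- bp$beta * 1.3
  i3 <- compute_indices(bp_beta)
  expect_true(all(i3$channel$engagement_abt > i1$channel$engagement_abt))
  expect_true(all(i3$channel$engagement_ba > i1$channel$engagement_ba))
})

test_that("baseline correction subtracts rest index values", {
  withr::with_seed(57, {
    bt <- data.frame(channel = eeg_channels(), theta = runif(18, 1, 2),
                     alpha = runif(18, 1, 2), beta = runif(18, 1, 2))
    br <- data.frame(channel = eeg_channels(), theta = runif(18, 1, 2),
                     alpha = runif(18, 1, 2), beta = runif(18, 1, 2))
  })
  idx <- compute_indices(bt, br)
  tr <- idx$channel[idx$channel$phase == "trial", ]
  re <- idx$channel[idx$channel$phase == "rest", ]
  co <- idx$channel[idx$channel$phase == "corrected", ]
  expect_equal(co$engagement_abt, tr$engagement_abt - re$engagement_abt)
  sc <- idx$scalar
  expect_equal(sc$arousal[sc$phase == "corrected"],
               sc$arousal[sc$phase == "trial"] -
                 sc$arousal[sc$phase == "rest"])
})
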