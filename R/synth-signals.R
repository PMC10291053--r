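# Synthetic physiological signal generators.
#
# Each generator is a pure function of its parameters and seed, returning
# both the waveform(s) and the ground truth needed to verify downstream
# extraction (beat times, SCR events, planted band weights, ...).

#' EEG channel montage
#'
#' The fixed 18-channel 10-20 montage used throughout the package.
#' @return character vector of 18 channel labels.
#' @export
eeg_channels <- function() {
  c("F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz", "C4", "T8",
    "P8", "P4", "Pz", "P3", "P7", "O1", "Oz", "O2")
}

# frontal weighting of the blink template (strongest at frontal sites)
.blink_topography <- function() {
  w <- c(F7 = 0.8, F3 = 1.0, Fz = 1.0, F4 = 1.0, F8 = 0.8,
         T7 = 0.25, C3 = 0.35, Cz = 0.4, C4 = 0.35, T8 = 0.25,
         P8 = 0.08, P4 = 0.1, Pz = 0.1, P3 = 0.1, P7 = 0.08,
         O1 = 0.04, Oz = 0.04, O2 = 0.04)
  w[eeg_channels()]
}

# Fixed 400 ms biphasic blink template (unit peak), sampled at `sfreq`.
.blink_template <- function(sfreq) {
  t <- seq(0, 0.4, by = 1 / sfreq)
  # positive lobe then shallow negative rebound
  y <- sin(pi * t / 0.25)^2 * (t <= 0.25) - 0.3 * sin(pi * (t - 0.25) / 0.15)^2 * (t > 0.25)
  y
}

#' Synthesize multichannel EEG
#'
#' Builds each channel as a sum of band-limited Gaussian processes in the
#' theta (4-8 Hz), alpha (8-12 Hz) and beta (12-30 Hz) bands, scaled to the
#' requested relative band powers, plus a 1/f pink background and optional
#' stereotyped blink transients that are shared (scaled up) with the EOG
#' channel. Band processes are drawn directly in the frequency domain
#' (complex Gaussian spectrum shaped by raised-cosine band masks), which is
#' distributionally identical to band-filtering white noise.
#'
#' @param duration signal duration in seconds.
#' @param sfreq sampling frequency in Hz (default 1000).
#' @param band_weights named list/vector with `theta`, `alpha`, `beta`
#'   relative band powers (>= 0).
#' @param pink_noise_level amplitude scale of the 1/f background,
#'   relative to the band processes.
#' @param total_power total background variance per channel (µV²); the
#'   combined band + pink profile is normalised to this power so
#'   amplitudes sit in a realistic scalp-EEG range.
#' @param blink_rate blinks per minute (0 disables ocular artifacts).
#' @param seed integer seed.
#' @param channel_gain optional length-18 per-channel gain.
#' @return list with `eeg` (samples x 18 matrix, µV, columns named by
#'   channel), `eog` (vector), `sfreq`, and `truth` (band weights, blink
#'   onset times).
#' @export
synth_eeg <- function(duration, sfreq = 1000,
                      band_weights = c(theta = 1, alpha = 1, beta = 1),
                      pink_noise_level = 0.3, blink_rate = 12, seed = 1,
                      channel_gain = NULL, total_power = 100) {
  .assert_scalar(duration, "duration", 0, strict_lo = TRUE)
  .assert_scalar(sfreq, "sfreq", 0, strict_lo = TRUE)
  bw <- unlist(band_weights)[c("theta", "alpha", "beta")]
  if (any(is.na(bw)) || any(bw < 0)) stop("band_weights must be named non-negative (theta, alpha, beta)")
  n <- round(duration * sfreq)
  chans <- eeg_channels()
  nch <- length(chans)
  if (is.null(channel_gain)) channel_gain <- rep(1, nch)
  bands <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))

  .with_seed(seed, {
    np <- .next_fast(n)      # draw on a fast-length grid, keep n samples
    f <- .fft_freqs(np, sfreq)
    # target amplitude spectrum: sqrt of summed band + pink power
    # profiles; the pink background is confined to the 0-62.5 Hz
    # analysis bandwidth (content above the decimation cutoff never
    # survives preprocessing)
    prof <- pink_noise_level^2 / pmax(abs(f), 0.5) *
      .fft_mask(f, NULL, min(62.5, sfreq / 2 * 0.95), roll = 2)^2
    for (b in names(bands)) {
      mask <- .fft_mask(f, bands[[b]][1], bands[[b]][2], roll = 0.25)
      width <- diff(bands[[b]])
      prof <- prof + bw[[b]] * mask^2 / width
    }
    if (sum(prof) > 0)   # normalise the realized variance to total_power
      prof <- prof * total_power / (sum(prof) / 2 * sfreq / np)
    amp <- sqrt(prof) * sqrt(np * sfreq / 2)
    pos <- which(f > 0 & amp > 0)                  # positive-freq support
    half_n <- if (np %% 2 == 0) np / 2 + 1 else NA
    draw_spectrum <- function() {
      Z <- complex(length.out = np)
      Z[pos] <- complex(real = stats::rnorm(length(pos)),
                        imaginary = stats::rnorm(length(pos))) / sqrt(2) *
        amp[pos]
      if (!is.na(half_n)) Z[half_n] <- stats::rnorm(1) * amp[half_n]
      Z[np + 2 - pos] <- Conj(Z[pos])              # Hermitian symmetry
      Z
    }
    keep <- seq_len(n)
    eeg <- matrix(0, n, nch, dimnames = list(NULL, chans))
    # two real channels per complex inverse FFT: x1 = Re, x2 = Im
    for (j in seq(1, nch, by = 2)) {
      Z1 <- draw_spectrum()
      if (j < nch) {
        w <- (stats::fft(Z1 + 1i * draw_spectrum(), inverse = TRUE) / np)[keep]
        eeg[, j] <- Re(w) * channel_gain[j]
        eeg[, j + 1] <- Im(w) * channel_gain[j + 1]
      } else {
        eeg[, j] <- Re(stats::fft(Z1, inverse = TRUE) / np)[keep] * channel_gain[j]
      }
    }
    eog <- 2 * stats::rnorm(n)                     # measurement noise only
    blink_onsets <- numeric(0)
    if (blink_rate > 0) {
      nb <- stats::rpois(1, blink_rate * duration / 60)
      if (nb > 0) {
        blink_onsets <- sort(stats::runif(nb, 0, max(duration - 0.5, 0.01)))
        tmpl <- .blink_template(sfreq) * 150       # ~150 µV at EOG
        topo <- .blink_topography()
        for (on in blink_onsets) {
          i0 <- round(on * sfreq) + 1
          ii <- i0:min(i0 + length(tmpl) - 1, n)
          tt <- tmpl[seq_along(ii)]
          eog[ii] <- eog[ii] + tt
          eeg[ii, ] <- eeg[ii, ] + outer(tt, topo * 0.4)
        }
      }
    }
    list(eeg = eeg, eog = eog, sfreq = sfreq,
         truth = list(band_weights = bw, blink_onsets = blink_onsets))
  })
}

#' Synthesize an interbeat-interval series and PPG waveform
#'
#' RR intervals follow a stationary AR(1) process,
#' `RR_i = mu + phi (RR_{i-1} - mu) + eps`, with the innovation variance
#' scaled so the stationary SD equals `sdnn_target`. The PPG is built by
#' placing a fixed unit pulse template at the cumulative beat times.
#'
#' @param duration seconds of signal to generate.
#' @param mean_rr mean interbeat interval, ms.
#' @param sdnn_target stationary SD of the RR series, ms.
#' @param phi AR(1) coefficient in `[0, 1)`.
#' @param seed integer seed.
#' @param sfreq PPG sampling frequency, Hz.
#' @return list with `ppg` (vector, a.u.), `beat_times` (s), `rr` (ms),
#'   `sfreq`.
#' @export
synth_cardiac <- function(duration, mean_rr = 800, sdnn_target = 50,
                          phi = 0.8, seed = 1, sfreq = 100) {
  .assert_scalar(duration, "duration", 0, strict_lo = TRUE)
  .assert_scalar(mean_rr, "mean_rr", 0, strict_lo = TRUE)
  .assert_scalar(sdnn_target, "sdnn_target", 0)
  .assert_scalar(phi, "phi", 0, hi = 1 - 1e-9)
  .with_seed(seed, {
    n_max <- ceiling(duration * 1000 / mean_rr * 1.5) + 20
    sd_eps <- sdnn_target * sqrt(1 - phi^2)
    rr <- numeric(n_max)
    rr[1] <- mean_rr + stats::rnorm(1, 0, sdnn_target)
    eps <- stats::rnorm(n_max, 0, sd_eps)
    for (i in 2:n_max) rr[i] <- mean_rr + phi * (rr[i - 1] - mean_rr) + eps[i]
    rr <- pmax(rr, 250)                         # physiological floor
    bt <- cumsum(rr) / 1000
    keep <- bt <= duration - 0.05
    bt <- bt[keep]
    rr <- diff(c(0, bt)) * 1000
    n <- round(duration * sfreq)
    ppg <- 0.02 * stats::rnorm(n)
    # unit pulse template, maximum exactly at the beat time
    tt <- seq(-0.15, 0.35, by = 1 / sfreq)
    tmpl <- exp(-0.5 * ((tt) / 0.07)^2) + 0.25 * exp(-0.5 * ((tt - 0.22) / 0.06)^2)
    off <- which.max(tmpl) - 1
    for (b in bt) {
      i0 <- round(b * sfreq) + 1 - off
      ii <- max(i0, 1):min(i0 + length(tmpl) - 1, n)
      ppg[ii] <- ppg[ii] + tmpl[ii - i0 + 1]
    }
    list(ppg = ppg, beat_times = bt, rr = diff(bt) * 1000, sfreq = sfreq)
  })
}

# smooth burst envelope: sum of Gaussian bumps at Poisson times
# (each bump evaluated only on its +/- 5 sd support)
.burst_envelope <- function(n, sfreq, rate_per_min, width = 0.6) {
  env <- numeric(n)
  duration <- n / sfreq
  nb <- stats::rpois(1, rate_per_min * duration / 60)
  if (nb == 0) return(list(env = env, onsets = numeric(0)))
  cent <- stats::runif(nb, 0, duration)
  half <- ceiling(5 * width * sfreq)
  for (cc in cent) {
    i0 <- round(cc * sfreq)
    ii <- max(1, i0 - half):min(n, i0 + half)
    env[ii] <- env[ii] + exp(-0.5 * ((ii / sfreq - cc) / width)^2)
  }
  list(env = env, onsets = sort(cent))
}

#' Synthesize surface EMG
#'
#' A band-limited (10-350 Hz) Gaussian noise carrier is amplitude-modulated
#' by a constant baseline envelope plus smooth Gaussian bursts at Poisson
#' times. The mean rectified amplitude grows monotonically with
#' `burst_amplitude`.
#'
#' @param duration seconds.
#' @param sfreq sampling frequency; must be at least 700 Hz so the
#'   10-350 Hz carrier band is representable.
#' @param burst_rate bursts per minute.
#' @param burst_amplitude envelope height of a burst (µV).
#' @param baseline_level constant envelope level (µV).
#' @param seed integer seed.
#' @return list with `emg` (vector, µV), `sfreq`, `truth` (burst onsets,
#'   envelope mean).
#' @export
synth_emg <- function(duration, sfreq = 1000, burst_rate = 8,
                      burst_amplitude = 4, baseline_level = 2, seed = 1) {
  .assert_scalar(duration, "duration", 0, strict_lo = TRUE)
  if (sfreq < 700) stop("`sfreq` must be >= 700 Hz to represent the 10-350 Hz band")
  .assert_scalar(burst_rate, "burst_rate", 0)
  .assert_scalar(burst_amplitude, "burst_amplitude", 0)
  .with_seed(seed, {
    n <- round(duration * sfreq)
    carrier <- fft_bandpass(stats::rnorm(n), sfreq, 10, min(350, sfreq / 2 * 0.98), roll = 2)
    carrier <- carrier / .popsd(carrier)         # unit-SD carrier
    be <- .burst_envelope(n, sfreq, burst_rate)
    env <- baseline_level + burst_amplitude * be$env
    list(emg = carrier * env, sfreq = sfreq,
         truth = list(burst_onsets = be$onsets, envelope_mean = mean(env)))
  })
}

# biexponential (Bateman) SCR kernel, unit peak time/value helpers
.bateman <- function(t, tau_r, tau_d) {
  (exp(-t / tau_d) - exp(-t / tau_r)) * (t >= 0)
}

#' Peak value of the unit Bateman kernel
#' @param tau_r,tau_d rise and decay time constants (s), `tau_r < tau_d`.
#' @return list with `t_peak` (s) and `peak` value of
#'   `exp(-t/tau_d) - exp(-t/tau_r)`.
#' @export
bateman_peak <- function(tau_r = 1, tau_d = 4) {
  if (tau_r >= tau_d) stop("`tau_r` must be < `tau_d`")
  tp <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  list(t_peak = tp, peak = .bateman(tp, tau_r, tau_d))
}

#' Synthesize an electrodermal activity trace
#'
#' A slow tonic component (level + drift + slow wander) plus skin
#' conductance responses at Poisson event times, each a Bateman kernel
#' `A (exp(-t/tau_d) - exp(-t/tau_r))`.
#'
#' @param duration seconds.
#' @param sfreq sampling frequency, Hz.
#' @param scr_rate SCR events per minute (>= 0).
#' @param scr_amplitude scale `A` of each event's kernel (µS); individual
#'   event amplitudes are jittered around this value.
#' @param tonic_drift linear drift of the tonic level, µS over the trace.
#' @param tonic_level baseline tonic conductance, µS.
#' @param tau_r,tau_d kernel rise/decay constants (s), `tau_r < tau_d`.
#' @param seed integer seed.
#' @return list with `eda` (vector, µS), `sfreq`, `truth` (event times and
#'   kernel amplitudes).
#' @export
synth_eda <- function(duration, sfreq = 20, scr_rate = 4, scr_amplitude = 0.5,
                      tonic_drift = 0.2, tonic_level = 4, tau_r = 1, tau_d = 4,
                      seed = 1) {
  .assert_scalar(duration, "duration", 0, strict_lo = TRUE)
  .assert_scalar(scr_rate, "scr_rate", 0)
  if (tau_r >= tau_d) stop("`tau_r` must be < `tau_d`")
  .with_seed(seed, {
    n <- round(duration * sfreq)
    t <- seq_len(n) / sfreq
    tonic <- tonic_level + tonic_drift * t / duration +
      0.1 * fft_bandpass(stats::rnorm(n), sfreq, NULL, 0.02, roll = 0.01) * sqrt(n)
    ne <- stats::rpois(1, scr_rate * duration / 60)
    times <- sort(stats::runif(ne, 0, max(duration - 5, 0.1)))
    amps <- scr_amplitude * exp(stats::rnorm(ne, 0, 0.2))
    eda <- tonic
    for (k in seq_len(ne)) {
      eda <- eda + amps[k] * .bateman(t - times[k], tau_r, tau_d)
    }
    eda <- eda + 0.003 * stats::rnorm(n)
    list(eda = eda, sfreq = sfreq,
         truth = list(event_times = times, event_amplitudes = amps,
                      tau_r = tau_r, tau_d = tau_d))
  })
}
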