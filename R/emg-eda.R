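# Facial EMG trial means and the electrodermal SCR amplitude-per-time
# statistic, both rest-baseline corrected.

#' Rectified facial EMG trial mean
#'
#' Zero-phase band-pass 10-350 Hz, full-wave rectification, arithmetic
#' mean over the trial; `corrected = trial mean - rest mean`.
#'
#' @param emg trial EMG waveform (µV) at `sfreq`.
#' @param sfreq sampling frequency; must be >= 800 Hz for the 350 Hz
#'   upper edge.
#' @param rest optional rest-segment waveform for baseline correction.
#' @return list with `rectified_mean` (µV), and when rest is given
#'   `rest_mean` and `corrected`.
#' @export
emg_trial_mean <- function(emg, sfreq = 1000, rest = NULL) {
  if (sfreq < 800) stop("`sfreq` too low for the 350 Hz band edge (need >= 800 Hz)")
  rect <- function(x) mean(abs(fft_bandpass(x, sfreq, 10,
                                            min(350, sfreq / 2 * 0.98),
                                            roll = 2)))
  out <- list(rectified_mean = rect(emg))
  if (!is.null(rest)) {
    out$rest_mean <- rect(rest)
    out$corrected <- out$rectified_mean - out$rest_mean
  }
  out
}

# SCR detection on a phasic residual: peaks above `min_amplitude` over
# their preceding onset (local minimum).
.scr_detect <- function(phasic, sfreq, min_amplitude = 0.01) {
  n <- length(phasic)
  pk <- which(phasic >= c(-Inf, phasic[-n]) & phasic > c(phasic[-1], -Inf))
  tr <- which(phasic <= c(Inf, phasic[-n]) & phasic < c(phasic[-1], Inf))
  amps <- numeric(0); times <- numeric(0)
  for (p in pk) {
    prev_tr <- tr[tr < p]
    base <- if (length(prev_tr)) phasic[prev_tr[length(prev_tr)]] else phasic[1]
    a <- phasic[p] - base
    if (a >= min_amplitude) {
      amps <- c(amps, a)
      times <- c(times, (p - 1) / sfreq)
    }
  }
  list(amplitudes = amps, times = times)
}

#' Skin conductance response statistic
#'
#' Estimates the tonic component with a centred moving median (8-s
#' window) and subtracts it; detects SCR peaks on the phasic residual
#' (amplitude = peak minus the preceding local-minimum onset, minimum
#' amplitude 0.01 µS); the statistic is the sum of peak amplitudes
#' divided by the epoch duration in seconds, which corrects for
#' different film lengths. With a rest segment,
#' `corrected = trial statistic - rest statistic`.
#'
#' @param eda trial skin conductance (µS) at `sfreq`.
#' @param sfreq sampling frequency, Hz.
#' @param rest optional rest-segment waveform.
#' @param tonic_window moving-median window, s.
#' @param min_amplitude minimum SCR amplitude, µS.
#' @return list with `scr_sum_per_s` (µS/s), `n_peaks`, `peak_times`,
#'   `peak_amplitudes`, and when rest is given `rest_sum_per_s` and
#'   `corrected`.
#' @export
eda_scr_statistic <- function(eda, sfreq = 20, rest = NULL,
                              tonic_window = 8, min_amplitude = 0.01) {
  if (any(!is.finite(eda))) stop("`eda` contains non-finite samples")
  one <- function(x, min_s = 30) {
    if (length(x) < min_s * sfreq)
      stop(sprintf("need at least %d s of EDA signal", min_s))
    w <- round(tonic_window * sfreq)
    if (w %% 2 == 0) w <- w + 1
    tonic <- stats::runmed(x, w, endrule = "median")
    phasic <- x - tonic
    # light smoothing so sample noise does not fragment peaks
    phasic <- fft_bandpass(phasic, sfreq, NULL, 2, roll = 0.5)
    det <- .scr_detect(phasic, sfreq, min_amplitude)
    list(stat = sum(det$amplitudes) / (length(x) / sfreq), det = det)
  }
  tr <- one(eda)
  out <- list(scr_sum_per_s = tr$stat, n_peaks = length(tr$det$amplitudes),
              peak_times = tr$det$times, peak_amplitudes = tr$det$amplitudes)
  if (!is.null(rest)) {
    rs <- one(rest, min_s = 10)   # rest baselines may be short
    out$rest_sum_per_s <- rs$stat
    out$corrected <- out$scr_sum_per_s - rs$stat
  }
  out
}
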