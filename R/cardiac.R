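# PPG beat detection, Hampel RR cleaning, and the HRV feature set.

#' Construct an RR series object
#'
#' @param beat_times strictly increasing beat times, s.
#' @param flags optional logical per-interval quality flags (TRUE =
#'   corrected/suspect).
#' @return object of class `rr_series` with `beat_times` (s), `rr` (ms),
#'   `flags`.
#' @export
rr_series <- function(beat_times, flags = NULL) {
  if (is.unsorted(beat_times, strictly = TRUE))
    stop("`beat_times` must be strictly increasing")
  rr <- diff(beat_times) * 1000
  if (any(rr <= 0)) stop("all RR intervals must be > 0")
  if (is.null(flags)) flags <- rep(FALSE, length(rr))
  stopifnot(length(flags) == length(rr))
  structure(list(beat_times = beat_times, rr = rr, flags = flags),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d intervals, mean %.0f ms, %d flagged\n",
              length(x$rr), mean(x$rr), sum(x$flags)))
  invisible(x)
}

#' Detect heart beats in a photoplethysmogram
#'
#' Beats are local maxima of the 0.5-8 Hz band-passed pulse wave that
#' exceed an adaptive threshold (centred rolling mean + k x rolling SD,
#' 2-s window); candidate peaks closer than the 300-ms refractory period
#' are resolved in favour of the larger peak.
#'
#' @param ppg numeric waveform (a.u.).
#' @param sfreq sampling frequency, Hz.
#' @param k threshold multiplier on the rolling SD.
#' @return an [rr_series()].
#' @export
detect_beats <- function(ppg, sfreq, k = 0.5) {
  if (length(ppg) < 30 * sfreq) stop("need at least 30 s of PPG signal")
  rng <- diff(range(ppg))
  bp <- fft_bandpass(ppg, sfreq, 0.5, min(8, sfreq / 2 * 0.9), roll = 0.3)
  if (rng == 0 || stats::sd(bp) < 1e-9 * rng)
    stop("no detectable pulsatility")
  w <- max(3L, round(2 * sfreq))
  kern <- rep(1 / w, w)
  mu <- stats::filter(bp, kern, sides = 2)
  mu2 <- stats::filter(bp^2, kern, sides = 2)
  sdv <- sqrt(pmax(mu2 - mu^2, 0))
  mu[is.na(mu)] <- 0; sdv[is.na(sdv)] <- stats::sd(bp)
  thr <- as.numeric(mu + k * sdv)
  n <- length(bp)
  cand <- which(bp > thr &
                  bp >= c(-Inf, bp[-n]) & bp > c(bp[-1], -Inf))
  if (length(cand) == 0 || length(cand) / (n / sfreq) < 10 / 60)
    stop("no detectable pulsatility")
  # refractory pruning: keep the larger of peaks closer than 300 ms
  refr <- 0.3 * sfreq
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] >= refr) {
      keep <- c(keep, i)
    } else if (bp[i] > bp[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  if (length(keep) / (n / sfreq) < 10 / 60) stop("no detectable pulsatility")
  rr_series((keep - 1) / sfreq)
}

#' Hampel filter for RR outlier correction
#'
#' For each interval, if it deviates from the median of its window (three
#' points on each side by default) by more than
#' `n_mad x 1.4826 x MAD(window)`, it is replaced by the window median
#' and flagged.
#'
#' @param rr an [rr_series()] (or numeric RR vector in ms).
#' @param half_window points on each side (filter size 6 = 3 each side).
#' @param n_mad rejection threshold in scaled-MAD units.
#' @return an `rr_series` with corrected intervals and updated flags
#'   (numeric input returns a numeric vector with a `flags` attribute).
#' @export
hampel_clean <- function(rr, half_window = 3, n_mad = 3) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  n <- length(x)
  if (n < 2 * half_window + 1) stop("RR series shorter than the Hampel window")
  y <- x
  flg <- rep(FALSE, n)
  for (i in (half_window + 1):(n - half_window)) {
    win <- x[(i - half_window):(i + half_window)]
    med <- stats::median(win)
    sc <- 1.4826 * stats::median(abs(win - med))
    if (abs(x[i] - med) > n_mad * sc) {
      y[i] <- med
      flg[i] <- TRUE
    }
  }
  if (inherits(rr, "rr_series")) {
    bt <- c(rr$beat_times[1], rr$beat_times[1] + cumsum(y) / 1000)
    out <- rr_series(bt, flags = flg | rr$flags)
    return(out)
  }
  attr(y, "flags") <- flg
  y
}

# the ten time-domain HRV summary statistics of a single RR segment.
# sd1 follows the uncentred convention (sd1 = rmssd / sqrt(2) exactly),
# so that sd1^2 + sd2^2 = 2 sdnn^2 also holds exactly with population
# variance.
.hrv_one <- function(rr) {
  d <- diff(rr)
  msd <- mean(d^2)
  sd1 <- sqrt(msd / 2)
  sd2sq <- 2 * .popvar(rr) - msd / 2
  sd2 <- if (sd2sq >= 0) sqrt(sd2sq) else NA_real_
  c(hr = 60000 / mean(rr),
    sdnn = .popsd(rr),
    rmssd = sqrt(msd),
    sdsd = .popsd(d),
    pnn20 = mean(abs(d) > 20),
    pnn50 = mean(abs(d) > 50),
    mad = stats::median(abs(rr - stats::median(rr))),
    sd1 = sd1,
    sd2 = sd2,
    sd1_sd2 = if (is.na(sd2) || sd2 == 0) NA_real_ else sd1 / sd2)
}

#' Heart rate and HRV features
#'
#' Computes mean heart rate and the nine time-domain HRV statistics
#' (SDNN, RMSSD, SDSD, pNN20, pNN50, MAD, Poincaré SD1, SD2, SD1/SD2)
#' from a trial RR segment, and, when a rest segment is supplied, their
#' rest-baseline-corrected versions (trial - rest). Population variance
#' (denominator N) is used so the Poincaré identities hold exactly.
#'
#' @param trial_rr an [rr_series()] or numeric RR vector (ms) with at
#'   least 10 intervals.
#' @param rest_rr optional rest-segment RR series for baseline correction.
#' @return data.frame of class `hrv_features`, one row per feature with
#'   columns `feature`, `trial`, and (if rest given) `rest`, `corrected`.
#' @export
hrv_features <- function(trial_rr, rest_rr = NULL) {
  get_rr <- function(z) if (inherits(z, "rr_series")) z$rr else as.numeric(z)
  rr_t <- get_rr(trial_rr)
  if (length(rr_t) < 10) stop("need at least 10 trial RR intervals")
  ht <- .hrv_one(rr_t)
  out <- data.frame(feature = names(ht), trial = unname(ht),
                    stringsAsFactors = FALSE)
  if (!is.null(rest_rr)) {
    rr_r <- get_rr(rest_rr)
    if (length(rr_r) < 10) stop("need at least 10 rest RR intervals")
    hr <- .hrv_one(rr_r)
    out$rest <- unname(hr)
    out$corrected <- out$trial - out$rest
  }
  class(out) <- c("hrv_features", "data.frame")
  out
}
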