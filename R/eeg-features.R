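# EEG preprocessing and band-power / engagement / arousal / valence
# extraction with rest-baseline correction.

# fixed nearest-neighbour adjacency on the 18-channel 10-20 montage,
# used for deterministic bad-channel interpolation
.eeg_adjacency <- function() {
  list(
    F7 = c("F3", "T7"), F3 = c("F7", "Fz", "C3"), Fz = c("F3", "F4", "Cz"),
    F4 = c("Fz", "F8", "C4"), F8 = c("F4", "T8"),
    T7 = c("F7", "C3", "P7"), C3 = c("F3", "T7", "Cz", "P3"),
    Cz = c("Fz", "C3", "C4", "Pz"), C4 = c("F4", "Cz", "T8", "P4"),
    T8 = c("F8", "C4", "P8"),
    P7 = c("T7", "P3", "O1"), P3 = c("C3", "P7", "Pz", "O1"),
    Pz = c("Cz", "P3", "P4", "Oz"), P4 = c("C4", "Pz", "P8", "O2"),
    P8 = c("T8", "P4", "O2"),
    O1 = c("P7", "P3", "Oz"), Oz = c("Pz", "O1", "O2"), O2 = c("P8", "P4", "Oz")
  )
}

#' Preprocess raw EEG
#'
#' The standard reduction chain: decimate 1000 Hz to 125 Hz (zero-phase
#' anti-alias filtering), band-pass 0.05-30 Hz, replace outlying channels
#' (total power more than 10x above or below the montage median) by the
#' mean of their fixed montage neighbours, attenuate ocular contamination
#' by least-squares regression of each channel on the filtered EOG, and
#' flag muscle/movement artifacts: samples where any channel's
#' within-trial z-score exceeds 10, dilated by +/- 0.5 s, are marked in
#' the rejection mask and excluded from all subsequent spectral windows.
#'
#' @param eeg samples x 18 matrix (µV) at `sfreq`, columns named with the
#'   montage labels.
#' @param eog EOG vector at the same sampling rate.
#' @param sfreq input sampling frequency (Hz), a multiple of 125.
#' @param z_thresh artifact rejection z-score threshold.
#' @return list with `eeg` (samples x 18 at 125 Hz), `eog`, `mask`
#'   (logical, TRUE = rejected), `sfreq` (125), `interpolated` (labels of
#'   replaced channels).
#' @export
preprocess_eeg <- function(eeg, eog, sfreq = 1000, z_thresh = 10) {
  if (!is.matrix(eeg) || ncol(eeg) != 18)
    stop("`eeg` must be a samples x 18 matrix")
  if (is.null(colnames(eeg))) colnames(eeg) <- eeg_channels()
  if (!setequal(colnames(eeg), eeg_channels()))
    stop("`eeg` columns must be the 18 montage channel labels")
  eeg <- eeg[, eeg_channels(), drop = FALSE]
  if (nrow(eeg) < 10 * sfreq) stop("trial shorter than 10 s")
  if (length(eog) != nrow(eeg)) stop("`eog` length must match `eeg`")
  fs_out <- 125
  if (sfreq != fs_out) {
    fac <- sfreq / fs_out
    if (fac != round(fac)) stop("`sfreq` must be a multiple of 125 Hz")
    n_trim <- (nrow(eeg) %/% fac) * fac
    eeg <- fft_decimate(eeg[seq_len(n_trim), , drop = FALSE], fac, sfreq)
    eog <- fft_decimate(eog[seq_len(n_trim)], fac, sfreq)
    colnames(eeg) <- eeg_channels()
  }
  eeg <- fft_bandpass(eeg, fs_out, lo = 0.05, hi = 30, roll = 1)
  eog_f <- fft_bandpass(eog, fs_out, lo = 0.05, hi = 30, roll = 1)
  colnames(eeg) <- eeg_channels()

  # bad-channel replacement by fixed-adjacency neighbour mean
  pw <- apply(eeg, 2, stats::var)
  med <- stats::median(pw)
  bad <- names(pw)[pw > 10 * med | pw < 0.1 * med]
  adj <- .eeg_adjacency()
  for (ch in bad) {
    nb <- setdiff(adj[[ch]], bad)
    if (length(nb) > 0) eeg[, ch] <- rowMeans(eeg[, nb, drop = FALSE])
  }

  # ocular correction: per-channel least-squares regression on the EOG
  denom <- sum(eog_f^2)
  if (denom > 0) {
    b <- drop(crossprod(eeg, eog_f)) / denom
    eeg <- eeg - outer(eog_f, b)
  }

  # artifact mask: |z| > z_thresh on any channel, dilated +/- 0.5 s
  z <- scale(eeg)
  hit <- rowSums(abs(z) > z_thresh) > 0
  mask <- hit
  if (any(hit)) {
    w <- round(0.5 * fs_out)
    idx <- which(hit)
    for (i in idx) mask[max(1, i - w):min(length(mask), i + w)] <- TRUE
  }
  list(eeg = eeg, eog = eog_f, mask = mask, sfreq = fs_out,
       interpolated = bad)
}

#' Per-channel Welch band powers
#'
#' Hann-tapered periodograms in 1-s (125-sample) windows with 50%
#' overlap; per channel and band, the median across windows of the mean
#' spectral density inside the band. Windows overlapping any masked
#' sample are dropped. Bands: theta 4-8, alpha 8-12, beta 12-30 Hz
#' (half-open intervals).
#'
#' @param eeg samples x channels matrix (or vector) at `sfreq`.
#' @param sfreq sampling frequency, Hz.
#' @param mask optional logical rejection mask (TRUE = rejected sample).
#' @param window window length in samples (default one second).
#' @return data.frame `band_power_table`: one row per channel with
#'   columns `channel`, `theta`, `alpha`, `beta` (µV²/Hz).
#' @export
welch_band_powers <- function(eeg, sfreq = 125, mask = NULL, window = 125) {
  if (!is.matrix(eeg)) eeg <- matrix(eeg, ncol = 1,
                                     dimnames = list(NULL, "ch1"))
  if (is.null(colnames(eeg))) colnames(eeg) <- paste0("ch", seq_len(ncol(eeg)))
  bands <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
  out <- lapply(colnames(eeg), function(ch) {
    ww <- .welch_windows(eeg[, ch], sfreq, window = window, overlap = 0.5)
    if (is.null(ww)) stop("fewer than 2 usable windows")
    keep <- rep(TRUE, length(ww$starts))
    if (!is.null(mask) && any(mask)) {
      bad_cum <- cumsum(mask)
      ends <- ww$starts + ww$window - 1L
      nbad <- bad_cum[ends] - c(0, bad_cum)[ww$starts]
      keep <- nbad == 0
    }
    if (sum(keep) < 2) stop("fewer than 2 usable windows")
    P <- ww$P[, keep, drop = FALSE]
    vapply(bands, function(b) {
      sel <- ww$freqs >= b[1] & ww$freqs < b[2]
      stats::median(colMeans(P[sel, , drop = FALSE]))
    }, numeric(1))
  })
  res <- as.data.frame(do.call(rbind, out))
  data.frame(channel = colnames(eeg), res, stringsAsFactors = FALSE,
             row.names = NULL)
}

# per-channel ratio/index block from a band power table
.index_block <- function(bp) {
  with(bp, data.frame(
    channel = channel,
    theta_alpha = theta / alpha,
    theta_beta = theta / beta,
    alpha_beta = alpha / beta,
    engagement_abt = beta / (alpha + theta),
    engagement_ba = beta / alpha,
    stringsAsFactors = FALSE
  ))
}

.frontal_indices <- function(bp) {
  g <- function(ch, band) bp[[band]][match(ch, bp$channel)]
  arousal <- (g("F3", "beta") + g("F4", "beta")) /
    (g("F3", "alpha") + g("F4", "alpha"))
  valence <- if (any(c(g("F4", "beta"), g("F3", "beta")) == 0)) NA_real_ else
    g("F4", "alpha") / g("F4", "beta") - g("F3", "alpha") / g("F3", "beta")
  c(arousal = arousal, valence = valence)
}

#' EEG band ratios and engagement/arousal/valence indices
#'
#' From trial and rest band-power tables, computes per channel the three
#' band ratios (theta/alpha, theta/beta, alpha/beta) and the two
#' engagement indices beta/(alpha+theta) and beta/alpha, plus the frontal
#' arousal index (beta_F3+beta_F4)/(alpha_F3+alpha_F4) and valence index
#' (alpha_F4/beta_F4) - (alpha_F3/beta_F3). Baseline correction is
#' applied to the derived index values: corrected = trial - rest.
#' Indices whose denominator band power is zero are returned as `NA`
#' rather than fabricated.
#'
#' @param trial_powers,rest_powers band-power tables from
#'   [welch_band_powers()] (rest may be `NULL` to skip correction).
#' @return list of class `eeg_index_set`: `channel` (data.frame of
#'   per-channel indices for trial, rest and corrected), `scalar`
#'   (data.frame with arousal/valence trial, rest, corrected).
#' @export
compute_indices <- function(trial_powers, rest_powers = NULL) {
  stopifnot(is.data.frame(trial_powers),
            all(c("channel", "theta", "alpha", "beta") %in% names(trial_powers)))
  tb <- .index_block(trial_powers)
  num <- vapply(tb, is.numeric, logical(1))
  tb[num] <- lapply(tb[num], function(x) ifelse(is.finite(x), x, NA_real_))
  sc_t <- .frontal_indices(trial_powers)
  out <- list(channel = data.frame(tb, phase = "trial"),
              scalar = data.frame(phase = "trial", arousal = sc_t[["arousal"]],
                                  valence = sc_t[["valence"]]))
  if (!is.null(rest_powers)) {
    rb <- .index_block(rest_powers)
    rb[num] <- lapply(rb[num], function(x) ifelse(is.finite(x), x, NA_real_))
    sc_r <- .frontal_indices(rest_powers)
    corr <- tb
    corr[names(tb)[num]] <- tb[names(tb)[num]] -
      rb[names(tb)[num]][match(tb$channel, rb$channel), ]
    out$channel <- rbind(out$channel,
                         data.frame(rb, phase = "rest"),
                         data.frame(corr, phase = "corrected"))
    out$scalar <- rbind(out$scalar,
                        data.frame(phase = "rest", arousal = sc_r[["arousal"]],
                                   valence = sc_r[["valence"]]),
                        data.frame(phase = "corrected",
                                   arousal = sc_t[["arousal"]] - sc_r[["arousal"]],
                                   valence = sc_t[["valence"]] - sc_r[["valence"]]))
  }
  class(out) <- "eeg_index_set"
  out
}
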