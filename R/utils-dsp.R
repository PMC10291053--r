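# ---- frequency-domain zero-phase filtering -------------------------------
#
# All routine filtering in this package is done by masking the discrete
# spectrum with raised-cosine band edges and inverting the FFT.  The result
# is exactly zero-phase (a real, even impulse response, i.e. a circular
# frequency-sampling FIR filter) and deterministic.

# Raised-cosine amplitude mask over FFT bin frequencies.
# Passband [lo, hi] with cosine rolloff of width `roll` Hz on each side.
# lo = NULL or hi = NULL drop that edge.
.fft_mask <- function(freqs, lo, hi, roll) {
  m <- rep(1, length(freqs))
  f <- abs(freqs)
  if (!is.null(lo) && lo > 0) {
    m[f < lo - roll] <- 0
    idx <- f >= lo - roll & f < lo
    m[idx] <- m[idx] * 0.5 * (1 - cos(pi * (f[idx] - (lo - roll)) / roll))
  }
  if (!is.null(hi)) {
    m[f > hi + roll] <- 0
    idx <- f <= hi + roll & f > hi
    m[idx] <- m[idx] * 0.5 * (1 + cos(pi * (f[idx] - hi) / roll))
  }
  m
}

# smallest 5-smooth (2^a 3^b 5^c) integer >= n that is divisible by
# `mult`; mixed-radix FFTs degrade badly on large prime factors
.next_fast <- function(n, mult = 1) {
  best <- Inf
  p5 <- 1
  while (p5 < 2 * n) {
    p35 <- p5
    while (p35 < 2 * n) {
      # smallest power of two lifting p35 to >= n
      p <- p35 * 2^max(0, ceiling(log2(n / p35)))
      while (p %% mult != 0) p <- p * 2
      if (p >= n && p < best) best <- p
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

.fft_freqs <- function(n, sfreq) {
  k <- 0:(n - 1)
  f <- k / n * sfreq
  f[f > sfreq / 2] <- f[f > sfreq / 2] - sfreq
  f
}

#' Zero-phase band-pass filter via spectrum masking
#'
#' Filters a numeric vector (or each column of a matrix) with a zero-phase
#' frequency-sampling filter: the FFT is multiplied by a raised-cosine
#' band mask and inverted. Equivalent to a linear-phase FIR applied
#' forwards and backwards, without edge transients from recursion.
#'
#' @param x numeric vector or matrix (signals in columns).
#' @param sfreq sampling frequency, Hz.
#' @param lo,hi pass-band edges in Hz; `NULL` drops the edge.
#' @param roll cosine rolloff width in Hz on each side of the band.
#' @return filtered object with the shape of `x`.
#' @export
fft_bandpass <- function(x, sfreq, lo = NULL, hi = NULL, roll = 1) {
  if (is.matrix(x)) {
    n <- nrow(x)
    np <- .next_fast(n)
    xp <- if (np > n) rbind(x, matrix(0, np - n, ncol(x))) else x
    m <- .fft_mask(.fft_freqs(np, sfreq), lo, hi, roll)
    out <- Re(stats::mvfft(stats::mvfft(xp) * m, inverse = TRUE)) / np
    return(out[seq_len(n), , drop = FALSE])
  }
  n <- length(x)
  np <- .next_fast(n)
  xp <- if (np > n) c(x, numeric(np - n)) else x
  m <- .fft_mask(.fft_freqs(np, sfreq), lo, hi, roll)
  out <- Re(stats::fft(stats::fft(xp) * m, inverse = TRUE)) / np
  out[seq_len(n)]
}

#' Anti-aliased decimation via spectrum truncation
#'
#' Low-pass filters (raised-cosine rolloff below the new Nyquist) and
#' downsamples by an integer factor in one step, by keeping only the
#' retained spectral bins and inverting a short FFT. Zero-phase.
#'
#' @param x numeric vector or matrix (columns = channels), length divisible
#'   by `factor`.
#' @param factor integer decimation factor.
#' @param sfreq original sampling frequency (Hz), used for the rolloff.
#' @param roll_frac rolloff width as a fraction of the new Nyquist.
#' @return decimated signal of length `length(x)/factor`.
#' @export
fft_decimate <- function(x, factor, sfreq, roll_frac = 0.15) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n0 <- nrow(x)
  nc <- ncol(x)
  if (n0 %% factor != 0) stop("signal length must be divisible by `factor`")
  m0 <- n0 / factor
  n <- .next_fast(n0, mult = factor)
  if (n > n0) x <- rbind(x, matrix(0, n - n0, nc))
  m <- n / factor
  nyq_new <- sfreq / factor / 2
  # pack pairs of real columns into complex FFTs (halves the transforms)
  odd <- seq(1, nc, by = 2)
  even <- odd + 1
  even <- even[even <= nc]
  C <- x[, odd, drop = FALSE] + 0i
  if (length(even) > 0)
    C[, seq_along(even)] <- C[, seq_along(even)] + 1i * x[, even, drop = FALSE]
  W <- stats::mvfft(C)
  # retained bins: 0..m/2 and the conjugate tail
  keep <- c(1:(m %/% 2 + 1), (n - (m - m %/% 2 - 1) + 1):n)
  conj_keep <- c(1, n:2)[keep]
  f <- .fft_freqs(m, sfreq / factor)
  mask <- .fft_mask(f, NULL, nyq_new * (1 - roll_frac), roll = nyq_new * roll_frac)
  # unpack the two real channels per transform on the retained bins only,
  # then re-pack pairs for the (short) inverse transforms
  Y <- matrix(0i, m, nc)
  for (p in seq_along(odd)) {
    Wk <- W[keep, p]
    Wc <- Conj(W[conj_keep, p])
    Y[, odd[p]] <- (Wk + Wc) / 2 * mask
    if (p <= length(even)) Y[, even[p]] <- (Wk - Wc) / (2i) * mask
  }
  out <- matrix(0, m, nc)
  for (p in seq_along(odd)) {
    j1 <- odd[p]
    if (p <= length(even)) {
      v <- stats::fft(Y[, j1] + 1i * Y[, even[p]], inverse = TRUE) / n
      out[, j1] <- Re(v)
      out[, even[p]] <- Im(v)
    } else {
      out[, j1] <- Re(stats::fft(Y[, j1], inverse = TRUE)) / n
    }
  }
  out <- out[seq_len(m0), , drop = FALSE]
  if (vec) drop(out) else out
}

# ---- Welch periodograms --------------------------------------------------

# Per-window one-sided Hann periodograms.
# Returns list(freqs, P) where P is [n_freq x n_windows] spectral density
# (units^2/Hz), and `starts`, the window start indices.
.welch_windows <- function(x, sfreq, window = 125, overlap = 0.5) {
  n <- length(x)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- seq(1L, n - window + 1L, by = step)
  if (length(starts) < 1) return(NULL)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))  # Hann
  idx <- outer(seq_len(window) - 1L, starts, `+`)
  seg <- matrix(x[idx], nrow = window)
  seg <- seg - rep(colMeans(seg), each = window)
  seg <- seg * w
  sp <- stats::mvfft(seg)
  nf <- window %/% 2 + 1L
  P <- (Mod(sp[seq_len(nf), , drop = FALSE])^2) / (sfreq * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when window even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (window %% 2 == 0) dbl[nf] <- 1
  P <- P * dbl
  list(freqs = (seq_len(nf) - 1) * sfreq / window, P = P, starts = starts,
       window = window)
}

#' Welch power spectral density
#'
#' Mean of Hann-tapered, mean-removed, 50%-overlapping windowed
#' periodograms (the standard Welch estimate).
#'
#' @param x numeric vector.
#' @param sfreq sampling frequency, Hz.
#' @param window window length in samples.
#' @param overlap fractional overlap between consecutive windows.
#' @return data.frame with columns `freq` (Hz) and `psd` (units^2/Hz).
#' @export
welch_psd <- function(x, sfreq, window = 125, overlap = 0.5) {
  ww <- .welch_windows(x, sfreq, window, overlap)
  if (is.null(ww)) stop("signal shorter than one window")
  data.frame(freq = ww$freqs, psd = rowMeans(ww$P))
}

# ---- seeds ---------------------------------------------------------------

# Derive a reproducible table of per-(subject, film, stream) seeds from a
# master seed: one RNG stream seeded by the master draws all sub-seeds, so
# any single trial can be regenerated in isolation from the config alone.
.seed_table <- function(master_seed, n_subjects, n_films,
                        streams = c("eeg", "eog", "ppg", "emg_zyg",
                                    "emg_corr", "eda", "latent")) {
  stopifnot(is.finite(master_seed))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(master_seed %% .Machine$integer.max))
  n <- n_subjects * n_films * length(streams)
  seeds <- sample.int(.Machine$integer.max - 1L, n + 1L)
  arr <- array(seeds[seq_len(n)], dim = c(n_subjects, n_films, length(streams)),
               dimnames = list(NULL, NULL, streams))
  list(trial = arr, cohort = seeds[n + 1L])
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  expr
}

# population variance / sd (denominator N)
.popvar <- function(x) mean((x - mean(x))^2)
.popsd <- function(x) sqrt(.popvar(x))

.assert_scalar <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lo && x <= lo) stop(sprintf("`%s` must be > %g", name, lo), call. = FALSE)
  if (!strict_lo && x < lo) stop(sprintf("`%s` must be >= %g", name, lo), call. = FALSE)
  if (x > hi) stop(sprintf("`%s` must be <= %g", name, hi), call. = FALSE)
  invisible(x)
}
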