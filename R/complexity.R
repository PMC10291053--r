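# Eleven per-channel complexity and entropy measures used as
# machine-learning features. All are deterministic, implemented from the
# defining formulas; embedding order m = 3, delay 1 throughout.
#
# Conventions fixed for internal consistency (documented in the methods
# vignette): population variance (denominator N); histogram Shannon
# entropy with ceiling(sqrt(N)) bins; ordinal-pattern ties broken by
# order of occurrence (stable ranking).

# normalized singular values of the (m = 3, delay 1) embedding matrix
.svd_sigma <- function(x, m = 3) {
  n <- length(x) - m + 1
  Y <- vapply(seq_len(m), function(k) x[k:(k + n - 1)], numeric(n))
  s <- svd(Y, nu = 0, nv = 0)$d
  s / sum(s)
}

# ordinal pattern codes for order m = 3, delay 1, stable ties
.ordinal_codes <- function(x, m = 3) {
  n <- length(x) - m + 1
  cols <- vapply(seq_len(m), function(k) x[k:(k + n - 1)], numeric(n))
  # rank of each element within its length-3 window (stable: earlier
  # occurrence wins ties)
  code <- integer(n)
  fac <- 1L
  for (a in seq_len(m)) {
    r <- rep(0L, n)
    for (b in seq_len(m)) {
      if (b < a) r <- r + (cols[, b] <= cols[, a])
      if (b > a) r <- r + (cols[, b] < cols[, a])
    }
    code <- code + r * fac
    fac <- fac * m
  }
  code
}

#' Signal complexity and entropy features
#'
#' Computes eleven complexity measures of a single-channel waveform:
#' Petrosian (`pfd`), Katz (`kfd`) and Sevcik (`sfd`) fractal dimensions;
#' normalized permutation entropy (`pen`, order 3, delay 1); histogram
#' Shannon entropy (`shanen`, bits, ceiling(sqrt(N)) bins); normalized
#' spectral entropy (`specen`, over the Welch PSD bins); singular value
#' decomposition entropy (`svden`, bits); Fisher information (`fi`);
#' Hjorth complexity (`hjorth`); relative roughness (`rr`, in `[0, 4]`);
#' and differential entropy (`de`, nats, Gaussian closed form
#' `0.5 log(2 pi e var(x))`).
#'
#' Constant input returns 1 for the fractal dimensions (by convention)
#' and `NA` for variance-based measures.
#'
#' @param x numeric waveform, length >= 64, finite.
#' @param sfreq sampling frequency (Hz), used for the spectral entropy.
#' @param welch_window Welch window length (samples) for `specen`.
#' @return named numeric vector with the 11 features.
#' @export
compute_complexity <- function(x, sfreq = 125, welch_window = 125) {
  if (any(!is.finite(x))) stop("`x` must be finite (no NA/NaN/Inf)")
  n <- length(x)
  if (n < 64) stop("`x` must have at least 64 samples")
  dx <- diff(x)
  v <- .popvar(x)
  out <- c(pfd = NA_real_, kfd = NA_real_, sfd = NA_real_, pen = NA_real_,
           shanen = NA_real_, specen = NA_real_, svden = NA_real_,
           fi = NA_real_, hjorth = NA_real_, rr = NA_real_, de = NA_real_)
  if (v == 0) {
    out[c("pfd", "kfd", "sfd")] <- 1
    out["pen"] <- 0
    return(out)
  }

  # Petrosian: sign changes of the first differences
  s_changes <- sum(dx[-length(dx)] * dx[-1] < 0)
  out["pfd"] <- log10(n) / (log10(n) + log10(n / (n + 0.4 * s_changes)))

  # Katz: total curve length vs maximal excursion from the first point
  L <- sum(abs(dx))
  d <- max(abs(x - x[1]))
  nn <- n - 1
  out["kfd"] <- if (d == 0 || L == 0) 1 else
    log10(nn) / (log10(nn) + log10(d / L))

  # Sevcik: curve length after normalizing both axes to [0, 1]
  rng <- max(x) - min(x)
  xs <- (x - min(x)) / rng
  Lstar <- sum(sqrt(diff(xs)^2 + (1 / (n - 1))^2))
  out["sfd"] <- 1 + log(Lstar) / log(2 * (n - 1))

  # permutation entropy, normalized by log(m!)
  codes <- .ordinal_codes(x)
  p <- tabulate(match(codes, unique(codes)))
  p <- p / sum(p)
  out["pen"] <- -sum(p * log(p)) / log(factorial(3))

  # histogram Shannon entropy (bits)
  nb <- ceiling(sqrt(n))
  h <- tabulate(pmin(floor((x - min(x)) / (rng / nb)) + 1, nb), nb)
  q <- h[h > 0] / n
  out["shanen"] <- -sum(q * log2(q))

  # spectral entropy over the K-bin normalized Welch PSD
  psd <- welch_psd(x, sfreq, window = min(welch_window, n))$psd
  qs <- psd / sum(psd)
  qs <- qs[qs > 0]
  out["specen"] <- -sum(qs * log2(qs)) / log2(length(psd))

  # SVD entropy and Fisher information over normalized singular values
  sg <- .svd_sigma(x)
  out["svden"] <- -sum(sg * log2(sg))
  out["fi"] <- sum(diff(sg)^2 / sg[-length(sg)])

  # Hjorth complexity: mobility of the derivative over mobility of x
  mob <- function(y) sqrt(.popvar(diff(y)) / .popvar(y))
  out["hjorth"] <- mob(dx) / mob(x)

  # relative roughness: 2 (1 - lag-1 autocorrelation)
  xm <- x - mean(x)
  g0 <- mean(xm^2)
  g1 <- mean(xm[-n] * xm[-1])
  out["rr"] <- 2 * (1 - g1 / g0)

  # differential entropy, Gaussian closed form (nats)
  out["de"] <- 0.5 * log(2 * pi * exp(1) * v)
  out
}
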