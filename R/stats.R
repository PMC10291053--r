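# Genre comparisons, trialwise feature-rating correlations with
# per-channel multiple-testing correction, and the within-subject median
# split. The test statistics themselves are delegated to the standard
# machinery (t.test, cor.test, p.adjust); this module fixes the
# conventions (paired Cohen's d = mean difference / SD of differences)
# and the grouping semantics.

#' Paired comparison with Cohen's d
#'
#' Two-tailed paired t-test between condition means `a` and `b`
#' (paired by subject), with the paired-design effect size
#' `d = mean(a - b) / SD(a - b)` (equivalently `t / sqrt(n)`).
#'
#' @param a,b equal-length numeric vectors of per-subject condition
#'   means, n >= 3.
#' @return data.frame with `t`, `df`, `p`, `d`, `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `n`.
#' @export
paired_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (anyNA(a) || anyNA(b)) {
    ok <- stats::complete.cases(a, b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3) stop("fewer than 3 complete pairs")
  }
  dd <- a - b
  if (stats::sd(dd) == 0) stop("zero variance of paired differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = mean(dd) / stats::sd(dd),
             mean_a = mean(a), mean_b = mean(b),
             sd_a = stats::sd(a), sd_b = stats::sd(b), n = length(a))
}

#' Trialwise Pearson correlation with a rating
#'
#' Pearson r between a feature (pooled across all subject x film trials)
#' and the ratings, with the two-tailed p-value from
#' `t = r sqrt(n-2) / sqrt(1-r^2)`.
#'
#' @param x feature values across trials.
#' @param y ratings (same length).
#' @param feature,channel optional identifiers echoed into the result.
#' @return data.frame with `feature`, `channel`, `r`, `n`, `p` (and `q`
#'   unset, `NA`, until [bh_adjust()]).
#' @export
correlate <- function(x, y, feature = NA_character_, channel = NA_character_) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in `x` or `y`")
  ct <- stats::cor.test(x, y)
  data.frame(feature = feature, channel = channel,
             r = unname(ct$estimate), n = length(x), p = ct$p.value,
             q = NA_real_, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment, optionally per group
#'
#' Standard step-up FDR q-values; when `group` is given (e.g. the EEG
#' channel), the correction is applied separately within each group,
#' matching a per-channel correction over that channel's feature family.
#'
#' @param p p-values in `[0, 1]`.
#' @param group optional grouping vector of the same length.
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p, group = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (is.null(group)) return(stats::p.adjust(p, method = "BH"))
  stopifnot(length(group) == length(p))
  q <- rep(NA_real_, length(p))
  for (g in unique(group)) {
    i <- which(group == g)
    q[i] <- stats::p.adjust(p[i], method = "BH")
  }
  q
}

#' Within-subject median split of film ratings
#'
#' Ranks one subject's films by rating and labels the lower half "low",
#' the upper half "high" (4/4 with eight films). Ties at the boundary are
#' broken by a seeded random draw; a constant rating vector is split by
#' the seeded draw with a warning.
#'
#' @param ratings numeric ratings of one subject across films (>= 2).
#' @param seed integer seed for boundary tie-breaking.
#' @return factor with levels `low`, `high`, same length as `ratings`.
#' @export
median_split <- function(ratings, seed = 1) {
  n <- length(ratings)
  if (n < 2) stop("need at least 2 films")
  if (length(unique(ratings)) == 1)
    warning("all ratings identical; split assigned by seeded draw")
  n_low <- n %/% 2
  # seeded tie-break: sub-resolution jitter randomizes order within ties
  # without ever reordering distinct ratings (integer scale, gaps >= 1)
  ord <- .with_seed(seed, order(ratings + stats::runif(n, 0, 0.49)))
  lab <- rep("high", n)
  lab[ord[seq_len(n_low)]] <- "low"
  factor(lab, levels = c("low", "high"))
}
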