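# paired comparisons, correlations, BH adjustment, median split

# deterministic vector with exact sample mean m and sample SD s
fixed_vec <- function(n, m, s, seed = 61) {
  z <- withr::with_seed(seed, rnorm(n))
  z <- (z - mean(z)) / sd(z)
  m + s * z
}

test_that("paired t and Cohen's d reproduce the printed study pairs", {
  n <- 21
  d1 <- fixed_vec(n, m = 3.25 / sqrt(n), s = 1)   # t = 3.25 exactly
  res1 <- paired_test(d1, rep(0, n))
  expect_equal(res1$t, 3.25, tolerance = 1e-9)
  expect_equal(res1$df, 20)
  expect_equal(round(res1$d, 2), 0.71)
  expect_equal(round(res1$p, 3), 0.004)

  d2 <- fixed_vec(n, m = 2.12 / sqrt(n), s = 1)
  res2 <- paired_test(d2, rep(0, n))
  expect_equal(round(res2$d, 2), 0.46)
  expect_equal(round(res2$p, 3), 0.047)
})

test_that("swapping conditions negates t and d but keeps p", {
  a <- fixed_vec(15, 2, 1, seed = 62)
  b <- fixed_vec(15, 1.4, 0.8, seed = 63)
  r1 <- paired_test(a, b)
  r2 <- paired_test(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$d, -r2$d)
  expect_equal(r1$p, r2$p)
  expect_equal(sign(r1$d), sign(r1$t))
  expect_error(paired_test(a, a), "zero variance")
})

test_that("correlation p-value matches the closed form at the printed n", {
  # construct x, y with cor(x, y) = 0.26 exactly at n = 168
  n <- 168
  x <- fixed_vec(n, 0, 1, seed = 64)
  e <- withr::with_seed(65, rnorm(n))
  e <- residuals(lm(e ~ x))
  e <- e / sd(e)
  r0 <- 0.26
  y <- r0 * x + sqrt(1 - r0^2) * e
  res <- correlate(x, y)
  expect_equal(res$r, 0.26, tolerance = 1e-9)
  expect_equal(round(res$p, 3), 0.001)
  expect_equal(res$n, 168)
  # perfect correlation
  expect_equal(correlate(x, x)$r, 1)
  expect_lt(correlate(x, x)$p, 1e-100)
  expect_error(correlate(rep(1, 10), rnorm(10)), "variance")
})

test_that("correlation p-values agree with a permutation oracle", {
  withr::with_seed(66, {
    x <- rnorm(40)
    y <- 0.3 * x + rnorm(40)
    p_param <- correlate(x, y)$p
    r_obs <- abs(cor(x, y))
    perm <- vapply(1:10000, function(i) abs(cor(x, sample(y))), numeric(1))
    p_perm <- mean(perm >= r_obs)
    expect_equal(p_param, p_perm, tolerance = 0.02)
  })
})

test_that("correlation p-values are uniform under the null", {
  withr::with_seed(67, {
    x <- rnorm(50)
    p <- vapply(1:2000, function(i) correlate(x, rnorm(50))$p, numeric(1))
    expect_lte(mean(p < 0.05), 0.055 + 0.01)
    expect_gt(mean(p < 0.5), 0.45)
  })
})

test_that("BH adjustment reproduces the hand step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.013), 0.013)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # shrinking any p never decreases the rejection count
  withr::with_seed(68, {
    p <- runif(30)
    for (i in 1:10) {
      j <- sample(30, 1)
      p2 <- p; p2[j] <- p[j] / 2
      expect_gte(sum(bh_adjust(p2) < 0.05), sum(bh_adjust(p) < 0.05))
    }
  })
  # grouped adjustment is independent across groups
  p <- c(0.01, 0.04, 0.3, 0.01, 0.04, 0.3)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(bh_adjust(p, g)[1:3], bh_adjust(p[1:3]))
  q <- bh_adjust(p, g)
  expect_true(all(q >= p))
})

test_that("median split labels halves correctly and respects cardinality", {
  s <- median_split(c(2, 3, 8, 9, 4, 7, 1, 10))
  expect_equal(as.character(s),
               c("low", "low", "high", "high", "low", "high", "low", "high"))
  tied <- median_split(c(5, 5, 5, 5, 2, 2, 9, 9), seed = 3)
  expect_equal(sum(tied == "low"), 4L)
  expect_equal(sum(tied == "high"), 4L)
  expect_true(all(tied[c(5, 6)] == "low"))   # the 2s are always low
  expect_true(all(tied[c(7, 8)] == "high"))  # the 9s are always high
  expect_warning(median_split(rep(4, 8)), "identical")
  # bimodal ratings always separate the modes
  for (s in 1:5) {
    r <- withr::with_seed(s, sample(c(rep(2, 4), rep(9, 4))))
    sp <- median_split(r, seed = s)
    expect_gt(mean(r[sp == "high"]), mean(r[sp == "low"]))
  }
})

test_that("type-I control of the per-channel BH-corrected correlation screen", {
  # null cohorts: ratings from a zero-effect generator; per-channel index
  # families simulated as correlated noise, 18 channels x 7 indices
  rates <- null_fp_rates()
  expect_lte(mean(rates[, "bh"]), 0.05)
})
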