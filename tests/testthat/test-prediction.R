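# outlier masking, chained imputation, feature selection,
# leave-one-film-out evaluation

toy_matrix <- function(n_sub = 10, n_film = 6, n_feat = 8, seed = 71,
                       signal = 0, feat_noise = 1.25) {
  withr::with_seed(seed, {
    grid <- expand.grid(subject_id = sprintf("s%02d", 1:n_sub),
                        film_id = paste0("f", 1:n_film),
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    lat <- rnorm(n)
    grid$rating <- pmin(pmax(round(6 + 2 * (signal * lat +
                                              sqrt(1 - signal^2) * rnorm(n))),
                             1), 10)
    X <- as.data.frame(sapply(1:n_feat, function(i)
      lat + rnorm(n) * feat_noise))
    names(X) <- paste0("feat", 1:n_feat)
    assemble_matrix(cbind(grid, X))
  })
}

test_that("matrix assembly enforces shape and uniqueness", {
  m <- toy_matrix()
  expect_equal(nrow(m), 60)
  expect_s3_class(m, "feature_matrix")
  expect_error(assemble_matrix(rbind(m, m[1, ])), "duplicated")
  small <- toy_matrix(2, 3)
  expect_equal(nrow(small), 6)
})

test_that("outlier masking removes only extreme cells", {
  m <- toy_matrix()
  m$feat1 <- c(100, rep(0, nrow(m) - 1))
  mm <- mask_outliers(m)
  expect_true(is.na(mm$feat1[1]))
  expect_equal(sum(is.na(mm$feat1)), 1)
  m$feat2 <- rep(3.3, nrow(m))
  expect_false(anyNA(mask_outliers(m)$feat2))
  # identifiers and ratings are untouched
  expect_false(anyNA(mm$rating))
})

test_that("masking matches the Gaussian tail expectation on average", {
  withr::with_seed(72, {
    counts <- vapply(1:200, function(i) {
      x <- rnorm(168)
      sum(abs(x - mean(x)) > 3 * sd(x))
    }, numeric(1))
  })
  expect_equal(mean(counts), 2 * pnorm(-3) * 168, tolerance = 0.25)
})

test_that("imputation is exact for perfectly correlated columns", {
  m <- toy_matrix(n_feat = 4)
  m$feat4 <- m$feat3
  holes <- withr::with_seed(73, sample(nrow(m), 6))
  truth <- m$feat4[holes]
  m$feat4[holes] <- NA
  out <- impute_chained(m)
  expect_equal(out$data$feat4[holes], truth, tolerance = 1e-6)
  # no-missing input returns unchanged
  m2 <- toy_matrix()
  expect_equal(impute_chained(m2)$data, m2)
})

test_that("imputation beats the column SD on MCAR Gaussian data", {
  # strongly inter-correlated features: the regime chained imputation
  # is designed for
  m <- toy_matrix(n_sub = 30, n_film = 8, n_feat = 6, seed = 74,
                  feat_noise = 0.6)
  full <- m
  withr::with_seed(75, {
    for (j in paste0("feat", 1:6)) {
      holes <- sample(nrow(m), round(0.15 * nrow(m)))
      m[[j]][holes] <- NA
    }
  })
  out <- impute_chained(m)$data
  for (j in paste0("feat", 1:6)) {
    holes <- is.na(m[[j]])
    rmse <- sqrt(mean((out[[j]][holes] - full[[j]][holes])^2))
    expect_lt(rmse, sd(full[[j]]))
  }
  m$feat1[seq_len(round(0.55 * nrow(m)))] <- NA
  expect_error(impute_chained(m), "50%")
})

test_that("a planted signal feature ranks first almost always", {
  firsts <- vapply(1:20, function(s) {
    m <- withr::with_seed(s + 400, {
      g <- expand.grid(subject_id = sprintf("s%02d", 1:10),
                       film_id = paste0("f", 1:6),
                       stringsAsFactors = FALSE)
      g$rating <- sample(1:10, 60, replace = TRUE)
      X <- as.data.frame(matrix(rnorm(60 * 10), 60))
      names(X) <- paste0("noise", 1:10)
      X$planted <- g$rating + rnorm(60, 0, 0.3)
      assemble_matrix(cbind(g, X))
    })
    select_features(m, "rating", k = 3, seed = s)$feature[1]
  }, "")
  expect_gte(mean(firsts == "planted"), 0.95)
  m <- toy_matrix(n_feat = 5)
  expect_equal(nrow(select_features(m, "rating", k = 5)), 5)
  expect_error(select_features(m, "rating", k = 99), "exceeds")
})

test_that("duplicated informative columns share their importance", {
  m <- toy_matrix(n_sub = 12, n_feat = 4, seed = 76, signal = 0.8)
  m$info <- m$rating + withr::with_seed(77, rnorm(nrow(m), 0, 0.5))
  imp_single <- select_features(m, "rating", k = 5, seed = 1)
  base <- imp_single$importance[imp_single$feature == "info"]
  m$info2 <- m$info
  imp_dup <- select_features(m, "rating", k = 6, seed = 1)
  combined <- sum(imp_dup$importance[imp_dup$feature %in% c("info", "info2")])
  expect_equal(combined, base, tolerance = 0.5 * base)
})

test_that("LOFO regression runs one fold per film with hand-checkable metrics", {
  m <- toy_matrix(n_sub = 8, n_film = 6, seed = 78, signal = 0.6)
  rep_ <- lofo_evaluate(m, "regression", k = 4, seed = 2)
  expect_equal(nrow(rep_$per_film), 6)
  expect_true(all(rep_$per_film$gbt_mape >= 0))
  expect_length(rep_$selected, 6)
  expect_true(all(vapply(rep_$selected, nrow, 1L) == 4))
  # hand arithmetic for the metric definitions
  expect_equal(cinephys:::.mape(c(5, 10), c(4, 12)), 0.2)
  expect_equal(cinephys:::.mae(c(5, 10), c(4, 12)), 1.5)
  expect_error(lofo_evaluate(m[m$film_id %in% c("f1", "f2"), ], "regression"),
               "3 films")
})

test_that("LOFO reports are bitwise reproducible for a fixed seed", {
  m <- toy_matrix(n_sub = 8, n_film = 5, seed = 79, signal = 0.5)
  r1 <- lofo_evaluate(m, "classification", models = c("logistic", "tree"),
                      k = 4, seed = 3)
  r2 <- lofo_evaluate(m, "classification", models = c("logistic", "tree"),
                      k = 4, seed = 3)
  expect_identical(r1$per_film, r2$per_film)
  expect_identical(r1$mean, r2$mean)
})

test_that("no training statistic leaks from the held-out film", {
  m <- toy_matrix(n_sub = 8, n_film = 5, seed = 80)
  folds1 <- prepare_folds(m, seed = 4)
  # corrupt the held-out film wildly; training-fold data must not move
  m2 <- m
  i <- m2$film_id == "f3"
  m2[i, paste0("feat", 1:8)] <- m2[i, paste0("feat", 1:8)] + 1e6
  folds2 <- prepare_folds(m2, seed = 4)
  expect_identical(folds1[["f3"]]$train, folds2[["f3"]]$train)
  # and fold training sets genuinely exclude the held-out film
  for (f in names(folds1))
    expect_false(f %in% folds1[[f]]$train$film_id)
})

test_that("classifiers on label-permuted data sit at chance AUC", {
  m <- latent_matrix(seed = 90, r_target = 0.5)
  res <- permuted_label_auc(m, n_perm = 30, seed = 6)
  expect_lt(abs(res$mean_auc - 0.5), 0.04)
})

test_that("planted signal lifts AUC above its permuted-label baseline", {
  seeds <- 1:20
  gap <- memo("auc_gap", {
    vapply(seeds, function(s) {
      ms <- latent_matrix(seed = 500 + s, r_target = 0.5)
      folds <- prepare_folds(ms, seed = s)
      rs <- lofo_evaluate(ms, "classification", models = "logistic",
                          k = 5, seed = s, folds = folds)
      perm <- permuted_label_auc(ms, n_perm = 5, seed = s, k = 5,
                                 folds = folds)
      mean(rs$per_film$logistic_auc, na.rm = TRUE) - perm$mean_auc
    }, numeric(1))
  })
  expect_gte(mean(gap), 0.08)
  # null cohorts: the same gap is statistically indistinguishable from 0
  gap0 <- memo("auc_gap_null", {
    vapply(seeds, function(s) {
      m0 <- latent_matrix(seed = 700 + s, r_target = 0)
      folds <- prepare_folds(m0, seed = s)
      r0 <- lofo_evaluate(m0, "classification", models = "logistic",
                          k = 5, seed = s, folds = folds)
      perm <- permuted_label_auc(m0, n_perm = 5, seed = s, k = 5,
                                 folds = folds)
      mean(r0$per_film$logistic_auc, na.rm = TRUE) - perm$mean_auc
    }, numeric(1))
  })
  expect_gt(t.test(gap0)$p.value, 0.01)
})

test_that("the mean-rating baseline hits its closed-form MAPE", {
  m <- toy_matrix(n_sub = 12, n_film = 6, seed = 81)
  # predict the training mean for every test trial, by hand
  mapes <- vapply(unique(m$film_id), function(f) {
    mu <- mean(m$rating[m$film_id != f])
    cinephys:::.mape(m$rating[m$film_id == f],
                     rep(mu, sum(m$film_id == f)))
  }, numeric(1))
  closed <- vapply(unique(m$film_id), function(f) {
    mu <- mean(m$rating[m$film_id != f])
    y <- m$rating[m$film_id == f]
    mean(abs(mu - y) / y)
  }, numeric(1))
  expect_equal(mean(mapes), mean(closed), tolerance = 0.02)
})
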