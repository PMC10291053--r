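# Leave-one-film-out rating prediction: outlier masking, chained
# imputation, top-k impurity-importance feature selection and the model
# suite, with every statistic refit inside the training fold.

#' Mask column outliers
#'
#' Per numeric feature column, values beyond mean +/- z x SD (column
#' statistics computed once on the unmasked data) are set missing.
#' Identifier and rating columns are untouched; constant columns pass
#' through.
#'
#' @param m feature matrix (data.frame).
#' @param z threshold in SD units.
#' @param stats_from optional data.frame: compute the column means/SDs
#'   from these rows instead (used to apply training-fold thresholds to
#'   held-out rows).
#' @return `m` with outlying feature cells set to `NA`; the thresholds
#'   used are attached as `attr(, "column_stats")`.
#' @export
mask_outliers <- function(m, z = 3, stats_from = NULL) {
  cols <- .feature_cols(m)
  src <- if (is.null(stats_from)) m else stats_from
  mu <- vapply(src[cols], function(x) mean(x, na.rm = TRUE), numeric(1))
  sd_ <- vapply(src[cols], function(x) stats::sd(x, na.rm = TRUE), numeric(1))
  for (j in cols) {
    if (!is.finite(sd_[j]) || sd_[j] == 0) next
    bad <- !is.na(m[[j]]) & abs(m[[j]] - mu[j]) > z * sd_[j]
    m[[j]][bad] <- NA
  }
  attr(m, "column_stats") <- data.frame(column = cols, mean = mu, sd = sd_)
  m
}

#' Chained-equation imputation
#'
#' Iterative conditional imputation in the spirit of multivariate
#' imputation by chained equations: missing cells are initialised at
#' column medians, then `n_iter` sweeps cycle through the incomplete
#' columns, each fitted by least squares on its `n_pred` most correlated
#' feature columns and its missing cells overwritten by the fit.
#' Deterministic given the data and seed. Identifier and rating columns
#' are never imputed nor used as predictors.
#'
#' @param m feature matrix with missing cells (each feature column must
#'   be at least half observed).
#' @param n_iter sweeps over the columns.
#' @param n_pred number of predictor columns per imputation model.
#' @param seed integer seed (kept for interface stability; the algorithm
#'   is deterministic).
#' @return list with `data` (completed matrix) and `models` (per-column
#'   fits, reusable on new rows via [apply_imputation()]).
#' @export
impute_chained <- function(m, n_iter = 10, n_pred = 10, seed = 1) {
  cols <- .feature_cols(m)
  X <- as.matrix(m[cols])
  if (any(colMeans(is.na(X)) > 0.5))
    stop("columns with more than 50% missing cannot be imputed: ",
         paste(cols[colMeans(is.na(X)) > 0.5], collapse = ", "))
  if (any(colSums(!is.na(X)) == 0)) stop("entirely missing column")
  miss <- is.na(X)
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  for (j in seq_along(cols)) X[miss[, j], j] <- med[j]
  models <- vector("list", length(cols))
  names(models) <- cols
  target <- which(colSums(miss) > 0)
  if (length(target) > 0) {
    for (it in seq_len(n_iter)) {
      co <- suppressWarnings(stats::cor(X))
      co[!is.finite(co)] <- 0
      for (j in target) {
        pr <- order(abs(co[j, -j]), decreasing = TRUE)[seq_len(min(n_pred, ncol(X) - 1))]
        pr <- setdiff(seq_len(ncol(X))[-j][pr], j)
        obs <- !miss[, j]
        fit <- stats::lm.fit(cbind(1, X[obs, pr, drop = FALSE]), X[obs, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        X[miss[, j], j] <- drop(cbind(1, X[miss[, j], pr, drop = FALSE]) %*% beta)
        if (it == n_iter)
          models[[j]] <- list(predictors = cols[pr], beta = beta,
                              median = med[j])
      }
    }
  }
  out <- m
  out[cols] <- as.data.frame(X)
  list(data = out, models = models, medians = med)
}

#' Apply fitted imputation models to new rows
#'
#' Initialises missing cells of `newdata` at the training medians, then
#' applies the stored per-column linear models once. Keeps held-out rows
#' strictly out of the imputation fitting.
#'
#' @param imp result of [impute_chained()].
#' @param newdata feature matrix rows to complete.
#' @return completed data.frame.
#' @export
apply_imputation <- function(imp, newdata) {
  cols <- names(imp$medians)
  X <- as.matrix(newdata[cols])
  miss <- is.na(X)
  for (j in seq_along(cols)) X[miss[, j], j] <- imp$medians[j]
  for (j in which(colSums(miss) > 0)) {
    mdl <- imp$models[[cols[j]]]
    if (is.null(mdl)) next
    X[miss[, j], j] <- drop(cbind(1, X[miss[, j], mdl$predictors, drop = FALSE]) %*% mdl$beta)
  }
  newdata[cols] <- as.data.frame(X)
  newdata
}

#' Select the most important features
#'
#' Fits a random-forest ensemble on the training rows and ranks features
#' by mean impurity reduction (Gini importance for classification,
#' variance reduction for regression); returns the top `k`.
#'
#' @param train complete training feature matrix.
#' @param target `"rating"` for regression or `"label"` for binary
#'   classification (column must be present).
#' @param k number of features to keep.
#' @param seed integer seed for the ensemble.
#' @param num_trees ensemble size.
#' @return data.frame `feature`, `importance`, ordered decreasing,
#'   `k` rows.
#' @export
select_features <- function(train, target = c("rating", "label"), k = 15,
                            seed = 1, num_trees = 300) {
  target <- match.arg(target)
  cols <- .feature_cols(train)
  if (k > length(cols)) stop("`k` exceeds the number of feature columns")
  y <- train[[target]]
  if (target == "label") y <- factor(y, levels = c("low", "high"))
  X <- train[cols]
  fit <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  data.frame(feature = names(imp)[seq_len(k)],
             importance = unname(imp)[seq_len(k)],
             stringsAsFactors = FALSE)
}

# ---- model suite ---------------------------------------------------------

# continuous-score predictions on a common interface; `task` is "reg" or
# "clf". For classifiers the score is P(high) or a signed decision value.
.fit_predict <- function(model, train, test, feats, seed) {
  Xtr <- as.matrix(train[feats]); Xte <- as.matrix(test[feats])
  if (model %in% c("gbt_reg", "gbt_clf")) {
    y <- if (model == "gbt_reg") train$rating else
      as.numeric(train$label == "high")
    prm <- list(max_depth = 3, eta = 0.1, nthread = 1,
                objective = if (model == "gbt_reg") "reg:squarederror"
                else "binary:logistic")
    dtr <- xgboost::xgb.DMatrix(Xtr, label = y)
    fit <- xgboost::xgb.train(params = prm, data = dtr, nrounds = 150,
                              verbose = 0)
    return(as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(Xte))))
  }
  if (model == "svr") {
    fit <- e1071::svm(Xtr, train$rating, type = "eps-regression",
                      kernel = "radial")
    return(as.numeric(stats::predict(fit, Xte)))
  }
  if (model == "logistic") {
    df <- data.frame(y = as.numeric(train$label == "high"), Xtr)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    return(as.numeric(suppressWarnings(
      stats::predict(fit, data.frame(Xte), type = "response"))))
  }
  if (model == "knn") {
    k_ <- max(3L, min(15L, round(sqrt(nrow(Xtr)))))
    mu <- colMeans(Xtr)
    s <- apply(Xtr, 2, stats::sd)
    s[s == 0] <- 1
    pr <- class::knn(scale(Xtr, mu, s), scale(Xte, mu, s),
                     cl = train$label, k = k_, prob = TRUE)
    p_win <- attr(pr, "prob")
    return(ifelse(pr == "high", p_win, 1 - p_win))
  }
  if (model == "tree") {
    df <- data.frame(label = train$label, Xtr)
    fit <- rpart::rpart(label ~ ., data = df,
                        method = "class",
                        control = rpart::rpart.control(cp = 0.01,
                                                       minsplit = 10))
    return(as.numeric(stats::predict(fit, data.frame(Xte))[, "high"]))
  }
  if (model == "svc") {
    fit <- e1071::svm(Xtr, train$label, type = "C-classification",
                      kernel = "radial")
    dv <- attr(stats::predict(fit, Xte, decision.values = TRUE),
               "decision.values")
    sign_ <- if (grepl("^high", colnames(dv)[1])) 1 else -1
    return(sign_ * as.numeric(dv[, 1]))
  }
  stop("unknown model: ", model)
}

.mape <- function(y, yhat) mean(abs(yhat - y) / y)
.mae <- function(y, yhat) mean(abs(yhat - y))

.f1 <- function(y, yhat, positive = "high") {
  tp <- sum(yhat == positive & y == positive)
  fp <- sum(yhat == positive & y != positive)
  fn <- sum(yhat != positive & y == positive)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

.auc <- function(y, score) {
  if (length(unique(y)) < 2 || length(unique(score)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c("low", "high"),
                                 direction = "<", quiet = TRUE)))
}

#' Attach within-subject median-split labels
#'
#' @param m feature matrix with `subject_id` and `rating`.
#' @param seed tie-break seed passed to [median_split()].
#' @return `m` with a `label` factor column (`low`/`high`).
#' @export
add_split_labels <- function(m, seed = 1) {
  m$label <- factor(NA_character_, levels = c("low", "high"))
  for (s in unique(m$subject_id)) {
    i <- m$subject_id == s
    m$label[i] <- suppressWarnings(median_split(m$rating[i], seed = seed))
  }
  m
}

#' Leave-one-film-out evaluation
#'
#' For each film, all trials of the remaining films form the training
#' fold: outlier thresholds, imputation models, feature selection and
#' model fits are computed inside the fold, then applied to the held-out
#' film's trials. Regression reports per-film MAPE
#' (`mean(|yhat-y|/y)`) and MAE; classification reports accuracy, F1
#' (positive class = high) and AUC from continuous scores.
#'
#' Binary labels come from the within-subject median split computed over
#' ALL films (the study's convention; the held-out film's rating thus
#' participates in defining its own label). Set
#' `fold_safe_labels = TRUE` to recompute test labels from the training
#' films only.
#'
#' @param m assembled [assemble_matrix()] feature matrix (with ratings).
#' @param task `"regression"` or `"classification"`.
#' @param models subset of `c("gbt", "svr")` (regression) or
#'   `c("logistic", "gbt", "knn", "tree", "svc")` (classification).
#' @param k number of selected features per fold.
#' @param seed pipeline seed (selection, models, label tie-breaks).
#' @param global_selection select the 15 features once on the full
#'   matrix before cross-validation instead of per fold (reproduces the
#'   ambiguous global variant; leaks the held-out film into selection).
#' @param fold_safe_labels see above.
#' @param labels optional precomputed label factor (overrides the median
#'   split; used for permutation analyses).
#' @param folds optional precomputed fold data (from [prepare_folds()]).
#' @return list of class `prediction_report`: `task`, `per_film`
#'   (data.frame of per-film metrics per model), `mean` (across-film
#'   means), `selected` (per-fold feature lists), `settings`.
#' @export
lofo_evaluate <- function(m, task = c("regression", "classification"),
                          models = NULL, k = 15, seed = 1,
                          global_selection = FALSE,
                          fold_safe_labels = FALSE, labels = NULL,
                          folds = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(m, "data.frame"), "rating" %in% names(m))
  films <- unique(m$film_id)
  if (length(films) < 3) stop("need at least 3 films")
  if (any(m$rating == 0)) stop("ratings of 0 make MAPE undefined")
  if (is.null(models))
    models <- if (task == "regression") c("gbt", "svr") else
      c("logistic", "gbt", "knn", "tree", "svc")
  if (task == "classification") {
    if (!is.null(labels)) {
      m$label <- factor(labels, levels = c("low", "high"))
    } else if (!fold_safe_labels) {
      m <- add_split_labels(m, seed = seed)
    }
  }
  if (is.null(folds)) folds <- prepare_folds(m, seed = seed)

  sel_global <- NULL
  if (global_selection) {
    full <- impute_chained(mask_outliers(m), seed = seed)$data
    if (task == "classification" && is.null(full$label))
      full <- add_split_labels(full, seed = seed)
    sel_global <- select_features(full,
                                  target = if (task == "regression") "rating"
                                  else "label", k = k, seed = seed)
  }

  per_film <- list()
  selected <- list()
  for (f in films) {
    fd <- folds[[f]]
    train <- fd$train; test <- fd$test
    if (task == "classification") {
      train$label <- m$label[fd$train_idx]
      if (fold_safe_labels) {
        # recompute all labels from training films only
        lab <- rep(NA_character_, nrow(m))
        for (s in unique(m$subject_id)) {
          i_tr <- which(m$subject_id == s & m$film_id != f)
          spl <- suppressWarnings(median_split(m$rating[i_tr], seed = seed))
          lab[i_tr] <- as.character(spl)
          # held-out trial labelled against the training median
          i_te <- which(m$subject_id == s & m$film_id == f)
          lab[i_te] <- ifelse(m$rating[i_te] >=
                                stats::median(m$rating[i_tr]), "high", "low")
        }
        train$label <- factor(lab[fd$train_idx], levels = c("low", "high"))
        test_label <- factor(lab[fd$test_idx], levels = c("low", "high"))
      } else {
        test_label <- m$label[fd$test_idx]
      }
    }
    sel <- if (global_selection) sel_global else
      select_features(train, target = if (task == "regression") "rating"
                      else "label", k = k, seed = seed)
    selected[[f]] <- sel
    y <- test$rating
    row <- list(film = f, observed = mean(y))
    for (mod in models) {
      key <- switch(mod, gbt = if (task == "regression") "gbt_reg" else "gbt_clf",
                    mod)
      score <- .fit_predict(key, train, test, sel$feature, seed)
      if (task == "regression") {
        row[[paste0(mod, "_mape")]] <- .mape(y, score)
        row[[paste0(mod, "_mae")]] <- .mae(y, score)
        row[[paste0(mod, "_predicted")]] <- mean(score)
      } else {
        thr <- if (mod == "svc") 0 else 0.5   # svc scores are signed margins
        yhat <- ifelse(score >= thr, "high", "low")
        row[[paste0(mod, "_accuracy")]] <- mean(yhat == as.character(test_label))
        row[[paste0(mod, "_f1")]] <- .f1(as.character(test_label), yhat)
        row[[paste0(mod, "_auc")]] <- .auc(as.character(test_label), score)
      }
    }
    per_film[[f]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  per_film <- do.call(rbind, per_film)
  means <- colMeans(per_film[setdiff(names(per_film), "film")], na.rm = TRUE)
  structure(list(task = task, per_film = per_film, mean = means,
                 selected = selected,
                 settings = list(models = models, k = k, seed = seed,
                                 global_selection = global_selection,
                                 fold_safe_labels = fold_safe_labels)),
            class = "prediction_report")
}

#' Precompute leave-one-film-out folds
#'
#' For each film, masks outliers and fits the imputation with training
#' rows only, then completes the held-out rows with the training models.
#' Separated out so label-permutation analyses can reuse the fold data
#' (masking and imputation are label-free).
#'
#' @param m feature matrix.
#' @param z outlier threshold in SDs.
#' @param seed seed forwarded to the imputation.
#' @return named list per film: `train`, `test` (completed data.frames),
#'   `train_idx`, `test_idx` (row indices into `m`).
#' @export
prepare_folds <- function(m, z = 3, seed = 1) {
  folds <- list()
  for (f in unique(m$film_id)) {
    tr_i <- which(m$film_id != f)
    te_i <- which(m$film_id == f)
    tr <- mask_outliers(m[tr_i, , drop = FALSE], z = z)
    te <- mask_outliers(m[te_i, , drop = FALSE], z = z,
                        stats_from = m[tr_i, , drop = FALSE])
    imp <- impute_chained(tr, seed = seed)
    folds[[f]] <- list(train = imp$data, test = apply_imputation(imp, te),
                       train_idx = tr_i, test_idx = te_i)
  }
  folds
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Leave-one-film-out %s report (%d films)\n", x$task,
              nrow(x$per_film)))
  print(x$per_film, digits = 3)
  cat("Across-film means:\n")
  print(round(x$mean, 3))
  invisible(x)
}

#' Mean AUC under label permutation
#'
#' Replaces the within-subject binary labels by seeded random
#' permutations (within each subject) and evaluates the leave-one-film-out
#' classifier, averaging the across-film mean AUC over `n_perm`
#' permutations. The expected value under label exchangeability is 0.5.
#'
#' @param m feature matrix with ratings.
#' @param n_perm number of permutations.
#' @param models classifier subset (default logistic regression only).
#' @param seed base seed; permutation `p` uses `seed + p`.
#' @param k selected features per fold.
#' @param folds optional precomputed [prepare_folds()] result.
#' @return list with `mean_auc`, `per_perm` (vector), `n_perm`.
#' @export
permuted_label_auc <- function(m, n_perm = 100, models = "logistic",
                               seed = 1, k = 15, folds = NULL) {
  m0 <- add_split_labels(m, seed = seed)
  if (is.null(folds)) folds <- prepare_folds(m, seed = seed)
  aucs <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    lab <- .with_seed(seed + p, {
      out <- as.character(m0$label)
      for (s in unique(m0$subject_id)) {
        i <- which(m0$subject_id == s)
        out[i] <- out[sample(i)]
      }
      out
    })
    rep_p <- lofo_evaluate(m, task = "classification", models = models,
                           k = k, seed = seed, labels = lab, folds = folds)
    aucs[p] <- mean(rep_p$per_film[[paste0(models[1], "_auc")]], na.rm = TRUE)
  }
  list(mean_auc = mean(aucs), per_perm = aucs, n_perm = n_perm)
}
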