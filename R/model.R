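auc_value <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

stratified_folds <- function(labels, nfolds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

#' Fit the gradient-boosted phenotype probability model
#'
#' Trains a gradient-boosted decision-tree classifier (binary logistic
#' objective) on the screened feature matrix of the gold-standard cohort,
#' with early stopping on a stratified validation split, and reports the
#' fold-wise AUC from seeded stratified tenfold cross-validation plus
#' gain-based variable importance (normalized to sum to 1).  All
#' randomness is governed by `seed`; fits run single-threaded so results
#' are bit-for-bit reproducible.
#'
#' @param x numeric (sparse) feature matrix, patients in rows, feature
#'   names as colnames, patient ids as rownames.
#' @param labels 0/1 case indicator aligned with `x`'s rows.
#' @param seed integer seed.
#' @param nrounds maximum boosting rounds (default 500).
#' @param max_depth tree depth (default 4).
#' @param eta learning rate (default 0.05).
#' @param min_child_weight minimum hessian mass per leaf.  Kept near zero
#'   (default 1e-3): with a rare phenotype the logistic hessians of a
#'   small, nearly pure code group sum to far less than xgboost's default
#'   of 1, which would forbid exactly the splits that matter.
#' @param early_stopping_rounds stop after this many rounds without
#'   validation improvement (default 25).
#' @param val_fraction fraction held out (stratified) for early stopping
#'   (default 0.1).
#' @param nfolds cross-validation folds (default 10).
#' @param cv set `FALSE` to skip cross-validation (fits faster; `cv_auc`
#'   is then empty).
#' @param nthread threads for xgboost (keep 1 for reproducibility).
#' @return object of class `phenotype_model`: the booster, the feature
#'   names, per-fold CV AUC, normalized gain importance, hyperparameters
#'   and seed.
#' @seealso [predict.phenotype_model()], [score_patients()]
#' @export
phenotype_model <- function(x, labels, seed = 1L, nrounds = 500,
                            max_depth = 4, eta = 0.05, min_child_weight = 1e-3,
                            early_stopping_rounds = 25, val_fraction = 0.1,
                            nfolds = 10, cv = TRUE, nthread = 1L) {
  labels <- as.numeric(labels)
  stopifnot(nrow(x) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L) {
    stop("training error: need at least two patients of each class",
         call. = FALSE)
  }
  set.seed(seed)
  params <- list(objective = "binary:logistic", eval_metric = "logloss",
                 max_depth = max_depth, eta = eta,
                 min_child_weight = min_child_weight, nthread = nthread,
                 subsample = 1, colsample_bytree = 1)

  # stratified early-stopping split
  val <- unlist(lapply(split(seq_along(labels), labels), function(idx)
    sample(idx, max(1L, round(val_fraction * length(idx))))))
  tr <- setdiff(seq_along(labels), val)
  dtrain <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = labels[tr])
  dval <- xgboost::xgb.DMatrix(x[val, , drop = FALSE], label = labels[val])
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds,
                                evals = list(val = dval),
                                early_stopping_rounds = early_stopping_rounds,
                                verbose = 0)
  es <- attributes(booster)$early_stop
  best_iter <- if (!is.null(es$best_iteration)) es$best_iteration
               else xgboost::xgb.get.num.boosted.rounds(booster)

  cv_auc <- numeric(0)
  if (cv) {
    fold <- stratified_folds(labels, nfolds)
    cv_auc <- vapply(seq_len(nfolds), function(f) {
      dtr <- xgboost::xgb.DMatrix(x[fold != f, , drop = FALSE],
                                  label = labels[fold != f])
      m <- xgboost::xgb.train(params = params, data = dtr,
                              nrounds = best_iter, verbose = 0)
      p <- predict(m, xgboost::xgb.DMatrix(x[fold == f, , drop = FALSE]))
      auc_value(labels[fold == f], p)
    }, 0)
  }

  imp <- xgboost::xgb.importance(model = booster)
  importance <- data.frame(feature = imp$Feature, importance = imp$Gain)

  structure(list(booster = booster, feature_names = colnames(x),
                 cv_auc = cv_auc, importance = importance,
                 best_iteration = best_iter,
                 params = params, seed = seed,
                 n = nrow(x), n_cases = sum(labels)),
            class = "phenotype_model")
}

align_features <- function(x, feature_names) {
  have <- intersect(colnames(x), feature_names)
  if (length(have) == 0L) {
    stop("scoring error: no overlap between model features and input columns",
         call. = FALSE)
  }
  extra <- setdiff(colnames(x), feature_names)
  if (length(extra)) {
    warning(length(extra), " input column(s) unknown to the model dropped",
            call. = FALSE)
  }
  out <- Matrix::Matrix(0, nrow(x), length(feature_names), sparse = TRUE,
                        dimnames = list(rownames(x), feature_names))
  out[, have] <- x[, have]
  out
}

#' Predict case probabilities from a phenotype model
#'
#' Columns are aligned to the training features: columns the model never
#' saw are dropped with a warning, training columns absent from `newdata`
#' are filled with 0.
#'
#' @param object a [phenotype_model()].
#' @param newdata feature matrix with colnames.
#' @param ... unused.
#' @return numeric vector of case probabilities, named by rownames of
#'   `newdata`.
#' @export
predict.phenotype_model <- function(object, newdata, ...) {
  xa <- align_features(newdata, object$feature_names)
  p <- predict(object$booster, xgboost::xgb.DMatrix(xa))
  names(p) <- rownames(newdata)
  p
}

#' Score patients with a phenotype model
#'
#' @param model a [phenotype_model()].
#' @param x feature matrix with patient ids as rownames.
#' @return a `patient_scores` data.frame (`patient_id`, `p_case`,
#'   `p_not_case`).
#' @export
score_patients <- function(model, x) {
  p <- predict(model, x)
  patient_scores(rownames(x), p)
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf("phenotype_model: %d patients (%d cases), %d features, %d boosting rounds\n",
              x$n, x$n_cases, length(x$feature_names), x$best_iteration))
  if (length(x$cv_auc)) {
    cat(sprintf("  %d-fold CV AUC: %.3f (folds %.3f-%.3f)\n",
                length(x$cv_auc), mean(x$cv_auc), min(x$cv_auc), max(x$cv_auc)))
  }
  invisible(x)
}

#' @export
summary.phenotype_model <- function(object, n_top = 10, ...) {
  print(object)
  cat("\nTop variable importance (normalized gain):\n")
  print(utils::head(object$importance, n_top), row.names = FALSE)
  invisible(object)
}

#' Plot variable importance of a phenotype model
#'
#' @param x a [phenotype_model()].
#' @param n_top number of features shown.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.phenotype_model <- function(x, n_top = 10, ...) {
  imp <- utils::head(x$importance, n_top)
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(imp$importance), names.arg = rev(imp$feature),
                    horiz = TRUE, las = 1, xlab = "normalized gain",
                    main = "phenotype model importance", ...)
  invisible(x)
}

#' Reliability (calibration) check of predicted probabilities
#'
#' Bins patients by predicted probability and regresses the observed event
#' rate on the mean prediction per bin (weighted by bin size).  A slope
#' near 1 indicates usable calibration; the probabilistic confusion matrix
#' assumes it.
#'
#' @param p_case predicted probabilities.
#' @param outcome 0/1 true status.
#' @param bins number of quantile bins (default 10).
#' @param tolerance acceptable slope band around 1 (default `c(0.8, 1.2)`).
#' @return list with `slope`, `ok`, and the per-bin table.
#' @export
calibration_check <- function(p_case, outcome, bins = 10,
                              tolerance = c(0.8, 1.2)) {
  outcome <- as.numeric(outcome)
  stopifnot(length(p_case) == length(outcome))
  br <- unique(stats::quantile(p_case, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(p_case, breaks = br, include.lowest = TRUE)
  tab <- data.frame(
    mean_pred = tapply(p_case, bin, mean),
    obs_rate = tapply(outcome, bin, mean),
    n = as.integer(table(bin)))
  tab <- tab[tab$n > 0, , drop = FALSE]
  slope <- if (nrow(tab) >= 2) {
    unname(coef(lm(obs_rate ~ mean_pred, data = tab, weights = tab$n))[2])
  } else {
    NA_real_
  }
  list(slope = slope,
       ok = is.finite(slope) && slope >= tolerance[1] && slope <= tolerance[2],
       table = tab)
}
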