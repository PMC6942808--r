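#' Stratified train/test split
#'
#' Splits a cohort into disjoint train and test sets, stratified by the
#' diagnosis label so both parts keep the overall prevalence to within
#' rounding.
#'
#' @param dataset a [clinical_dataset].
#' @param test_fraction fraction assigned to the test set, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test`, both [clinical_dataset]s.
#' @export
split_train_test <- function(dataset, test_fraction = 0.3, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  y <- label_vector(dataset)
  with_seed(seed, {
    test_idx <- unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      n_test <- round(test_fraction * length(idx))
      if (n_test < 1L || n_test >= length(idx)) {
        stop("split leaves a class empty in train or test", call. = FALSE)
      }
      sample(idx, n_test)
    }))
    test_idx <- sort(test_idx)
    syms <- symptom_names(dataset)
    df <- as.data.frame(dataset, check.names = FALSE)
    list(train = clinical_dataset(df[-test_idx, , drop = FALSE], syms),
         test = clinical_dataset(df[test_idx, , drop = FALSE], syms))
  })
}

#' Published-optimum boosting parameters
#'
#' The grid-search optimum reported for this diagnostic task
#' (nrounds 60, eta 0.2, gamma 0.5, max_depth 4, min_child_weight 1,
#' subsample 0.55, colsample_bytree 1), used as the default fit
#' configuration.
#'
#' @return named list of parameters including `nrounds`.
#' @export
default_model_params <- function() {
  list(nrounds = 60L, eta = 0.2, gamma = 0.5, max_depth = 4L,
       min_child_weight = 1, subsample = 0.55, colsample_bytree = 1)
}

#' Default parameter grid for tuning
#'
#' Candidate values spanning (and containing) [default_model_params()].
#' The exhaustive product is large; pass a trimmed grid for quick runs.
#'
#' @return named list of candidate value vectors.
#' @export
default_param_grid <- function() {
  list(nrounds = c(20L, 40L, 60L, 80L, 100L),
       eta = c(0.1, 0.2, 0.3),
       gamma = c(0, 0.5, 1),
       max_depth = c(3L, 4L, 5L, 6L),
       min_child_weight = c(1, 3, 5),
       subsample = c(0.55, 0.75, 1.0),
       colsample_bytree = c(0.55, 0.75, 1.0))
}

#' Compact tuning grid
#'
#' A 64-combination subset of [default_param_grid()] (same candidate
#' values, trimmed ranges) that keeps a per-seed 5-fold grid search to a
#' few seconds; used by the simulation benchmarks.
#'
#' @return named list of candidate value vectors.
#' @export
fast_param_grid <- function() {
  list(nrounds = c(60L, 100L),
       eta = c(0.1, 0.2),
       gamma = c(0.5, 1),
       max_depth = c(3L, 4L),
       min_child_weight = c(1, 5),
       subsample = c(0.55, 0.75),
       colsample_bytree = 1)
}

validate_param_grid <- function(grid) {
  need <- names(default_param_grid())
  miss <- setdiff(need, names(grid))
  if (length(miss)) {
    stop("grid is missing parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(grid$eta <= 0 | grid$eta > 1)) stop("eta must be in (0, 1]", call. = FALSE)
  if (any(grid$subsample <= 0 | grid$subsample > 1) ||
      any(grid$colsample_bytree <= 0 | grid$colsample_bytree > 1)) {
    stop("subsample/colsample_bytree must be in (0, 1]", call. = FALSE)
  }
  if (any(grid$nrounds < 1) || any(grid$nrounds != round(grid$nrounds)) ||
      any(grid$max_depth < 1) || any(grid$max_depth != round(grid$max_depth))) {
    stop("nrounds and max_depth must be positive integers", call. = FALSE)
  }
  invisible(grid)
}

xgb_booster <- function(X, y, params, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = params$eta,
                  gamma = params$gamma, max_depth = params$max_depth,
                  min_child_weight = params$min_child_weight,
                  subsample = params$subsample,
                  colsample_bytree = params$colsample_bytree,
                  base_score = 0.5, tree_method = "exact",
                  nthread = 1L, seed = as.integer(seed)),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
}

#' Fit the boosted-tree diagnostic model
#'
#' Trains a gradient-boosted-tree classifier (binary logistic objective,
#' exact tree construction, single thread for reproducibility) on the
#' symptom indicators.  The decision threshold stored on the model
#' defaults to 0.5 until [optimal_threshold()] is applied.
#'
#' @param train a [clinical_dataset].
#' @param params named list of boosting parameters including `nrounds`;
#'   defaults to [default_model_params()].
#' @param seed integer seed for the booster's row/column subsampling.
#' @param threshold initial decision threshold.
#' @return an object of class `fitted_model`: list with `booster`,
#'   `params`, `features`, `threshold`, `seed`.
#' @export
fit_diagnostic_model <- function(train, params = default_model_params(),
                                 seed = 1L, threshold = 0.5) {
  X <- symptom_matrix(train)
  y <- label_vector(train)
  booster <- with_seed(seed, xgb_booster(X, y, params, seed))
  structure(list(booster = booster, params = params,
                 features = colnames(X), threshold = threshold,
                 seed = as.integer(seed)),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("Boosted-tree diagnostic model: %d features, nrounds = %d, threshold = %.2f\n",
              length(x$features), x$params$nrounds, x$threshold))
  invisible(x)
}

#' Predicted positive-class probabilities
#'
#' @param object a `fitted_model`.
#' @param newdata a [clinical_dataset] or numeric matrix over the training
#'   feature names.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "clinical_dataset")) {
    symptom_matrix(newdata)
  } else {
    as.matrix(newdata)
  }
  miss <- setdiff(object$features, colnames(X))
  if (length(miss)) {
    stop("newdata is missing feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- X[, object$features, drop = FALSE]
  stats::predict(object$booster, xgboost::xgb.DMatrix(X))
}

#' Exhaustive cross-validated grid search
#'
#' Evaluates every combination of the candidate grid by label-stratified
#' k-fold cross validation on the training set, scoring each combination
#' by mean held-out accuracy at threshold 0.5.  Ties are broken toward
#' fewer boosting rounds, then shallower trees, then grid order.
#'
#' @param train a [clinical_dataset].
#' @param grid named list of candidate value vectors (see
#'   [default_param_grid()]).
#' @param k number of folds (default 5).
#' @param seed integer seed (folds and booster subsampling).
#' @return list with `best_params`, `cv_accuracy` and `results` (one row
#'   per combination, in evaluation order).
#' @export
grid_search <- function(train, grid = default_param_grid(), k = 5L,
                        seed = 1L) {
  validate_param_grid(grid)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (!nrow(combos)) stop("empty parameter grid", call. = FALSE)
  X <- symptom_matrix(train)
  y <- label_vector(train)
  folds <- stratified_folds(y, k, derive_seed(seed, "cvfolds"))
  acc <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pars <- as.list(combos[i, ])
    fold_acc <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      booster <- with_seed(derive_seed(seed, paste0("fit", i, "_", f)),
                           xgb_booster(X[tr, , drop = FALSE], y[tr], pars, seed))
      p <- stats::predict(booster,
                          xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
      mean((p >= 0.5) == (y[!tr] == 1L))
    }, numeric(1))
    acc[i] <- mean(fold_acc)
  }
  ord <- order(-acc, combos$nrounds, combos$max_depth, seq_len(nrow(combos)))
  best <- ord[1L]
  list(best_params = as.list(combos[best, ]), cv_accuracy = acc[best],
       results = cbind(combos, cv_accuracy = acc))
}

#' Error-minimizing probability threshold
#'
#' Scans the probability grid 0.01, 0.02, ..., 0.99 and returns the
#' threshold minimizing the misclassification error of the model on the
#' given data.  Ties are broken toward the threshold closest to 0.5, then
#' toward the smaller value.
#'
#' @param model a `fitted_model`.
#' @param data a [clinical_dataset] (normally the training set).
#' @return the chosen threshold (numeric scalar).
#' @export
optimal_threshold <- function(model, data) {
  threshold_from_scores(label_vector(data), predict(model, data))
}

threshold_from_scores <- function(y, p) {
  grid <- (1:99) / 100   # exact hundredths; seq() drifts in floating point
  err <- vapply(grid, function(t) mean((p >= t) != (y == 1L)), numeric(1))
  cand <- grid[err <= min(err) + 1e-12]
  cand[order(abs(cand - 0.5), cand)][1L]
}

#' Gain-based feature importance
#'
#' Sums each feature's split-criterion improvement (gain) over every tree
#' of the fitted ensemble and normalizes to shares summing to one,
#' reported in descending order — the conventional reading of which
#' symptoms drive the model.
#'
#' @param model a `fitted_model`.
#' @return data frame of class `gain_table` with columns `feature` and
#'   `gain_share`, descending.
#' @export
gain_importance <- function(model) {
  if (!inherits(model, "fitted_model")) {
    stop("a fitted model is required", call. = FALSE)
  }
  imp <- xgboost::xgb.importance(model = model$booster)
  out <- data.frame(feature = imp$Feature,
                    gain_share = imp$Gain / sum(imp$Gain),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gain_share), ]
  rownames(out) <- NULL
  class(out) <- c("gain_table", "data.frame")
  out
}

#' Evaluate a fitted model on a cohort
#'
#' @param model a `fitted_model` (its stored threshold is used unless
#'   overridden).
#' @param data a [clinical_dataset].
#' @param threshold optional override of the decision threshold.
#' @return a [classification_metrics()] report.
#' @export
evaluate_model <- function(model, data, threshold = NULL) {
  classification_metrics(label_vector(data), predict(model, data),
                         threshold %||% model$threshold)
}
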