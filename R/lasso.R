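#' Fit the L1-penalized logistic coefficient path
#'
#' Core-symptom selection starts from the Lasso path of a logistic model
#' of diagnosis on the binary symptom indicators.  Fitting is delegated to
#' \pkg{glmnet}; the default lambda grid is built here analytically: 100
#' log-spaced values from `lambda_max = max_j |x_j' (y - mean(y))| / n`
#' (the smallest penalty at which every coefficient is exactly zero, by
#' the KKT conditions) down to `lambda_max * 1e-3`.  Binary predictors
#' share a scale already, so no standardization is applied by default; a
#' flag is provided because some toolchains standardize silently.  The
#' intercept is never penalized.
#'
#' @param dataset a [clinical_dataset] with both classes present.
#' @param lambda_grid optional decreasing penalty grid; built as above
#'   when `NULL`.
#' @param standardize standardize predictors inside the solver? Default
#'   `FALSE`.
#' @param nlambda,lambda_min_ratio grid size and ratio of smallest to
#'   largest lambda for the default grid.
#' @return an object of class `coefficient_path`: list with `lambda`
#'   (decreasing grid), `coefficients` (symptoms x lambda matrix),
#'   `intercepts`, `symptoms` and `standardize`.
#' @export
fit_lasso_path <- function(dataset, lambda_grid = NULL, standardize = FALSE,
                           nlambda = 100L, lambda_min_ratio = 1e-3) {
  X <- symptom_matrix(dataset)
  y <- label_vector(dataset)
  if (length(unique(y)) < 2L) {
    stop("both diagnosis classes must be present", call. = FALSE)
  }
  if (min(table(y)) < 2L) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  if (is.null(lambda_grid)) {
    lambda_max <- max(abs(crossprod(X, y - mean(y)))) / length(y)
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                           length.out = nlambda))
  }
  if (is.unsorted(rev(lambda_grid), strictly = TRUE)) {
    stop("lambda grid must be strictly decreasing", call. = FALSE)
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lambda_grid, standardize = standardize,
                        thresh = 1e-10)
  beta <- as.matrix(fit$beta)
  beta[abs(beta) < 1e-12] <- 0   # clamp solver noise to exact zeros
  rownames(beta) <- colnames(X)
  structure(list(lambda = fit$lambda, coefficients = beta,
                 intercepts = fit$a0, symptoms = colnames(X),
                 standardize = standardize),
            class = "coefficient_path")
}

#' @export
print.coefficient_path <- function(x, ...) {
  cat(sprintf("Lasso path: %d symptoms, %d lambda values (%.4g .. %.4g)\n",
              length(x$symptoms), length(x$lambda),
              max(x$lambda), min(x$lambda)))
  invisible(x)
}

# Stratified fold assignment: shuffle within class, deal round-robin.
# A class with a single member would vanish from one training fold and
# break the binomial fit, so that case is refused; with k <= min class
# count every held-out fold also contains both classes.
stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < 2L) {
    stop("stratified folding impossible: a class with fewer than 2 ",
         "subjects would vanish from a training fold", call. = FALSE)
  }
  with_seed(seed, {
    folds <- integer(length(y))
    nxt <- 0L
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      # continue the fold counter across classes so no fold is left empty
      folds[idx] <- (seq_along(idx) + nxt - 1L) %% k + 1L
      nxt <- nxt + length(idx)
    }
    folds
  })
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * (y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-validated binomial deviance along the Lasso path
#'
#' Label-stratified k-fold cross validation of the penalized logistic
#' model: each fold is held out once, the path is refit on the remaining
#' folds over the same lambda grid, and the held-out binomial deviance is
#' recorded per lambda.  The curve reports the mean and standard error
#' across folds, the deviance-minimizing `lambda_min`, and `lambda_1se` —
#' the largest (sparsest) lambda whose mean deviance stays within one
#' standard error of the minimum, the conventional parsimony rule for
#' selecting core features.
#'
#' @param dataset a [clinical_dataset].
#' @param path a `coefficient_path` from [fit_lasso_path()].
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return an object of class `cv_curve`: list with `lambda`,
#'   `mean_deviance`, `se_deviance`, `lambda_min`, `lambda_1se`, `folds`.
#' @export
cross_validate_deviance <- function(dataset, path, k = 10L, seed = 1L) {
  stopifnot(inherits(path, "coefficient_path"))
  X <- symptom_matrix(dataset)
  y <- label_vector(dataset)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (nrow(X) < k) stop("more folds than subjects", call. = FALSE)
  folds <- stratified_folds(y, k, seed)
  lambda <- path$lambda
  fold_dev <- matrix(NA_real_, nrow = k, ncol = length(lambda))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 1, lambda = lambda,
                          standardize = path$standardize, thresh = 1e-10)
    p <- stats::predict(fit, X[!tr, , drop = FALSE], s = lambda,
                        type = "response", exact = FALSE)
    fold_dev[f, ] <- colMeans(binomial_deviance(y[!tr], p))
  }
  mean_dev <- colMeans(fold_dev)
  se_dev <- apply(fold_dev, 2L, stats::sd) / sqrt(k)
  i_min <- which.min(mean_dev)
  within <- mean_dev <= mean_dev[i_min] + se_dev[i_min]
  i_1se <- which(within)[1L]  # grid is decreasing: first hit = largest lambda
  structure(list(lambda = lambda, mean_deviance = mean_dev,
                 se_deviance = se_dev,
                 lambda_min = lambda[i_min], lambda_1se = lambda[i_1se],
                 folds = folds, k = k),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("%d-fold CV deviance curve: lambda_min = %.5g, lambda_1se = %.5g\n",
              x$k, x$lambda_min, x$lambda_1se))
  invisible(x)
}

#' Extract the core symptoms selected at lambda.1se
#'
#' The symptoms with nonzero coefficients at the one-standard-error lambda
#' of the cross-validation curve are the selected core features.
#'
#' @param path a `coefficient_path`.
#' @param curve a `cv_curve` computed on the same lambda grid.
#' @return an object of class `selected_features`: data frame with columns
#'   `symptom` and `coefficient`, plus attribute `lambda` (the selection
#'   penalty).
#' @export
extract_core_symptoms <- function(path, curve) {
  stopifnot(inherits(path, "coefficient_path"), inherits(curve, "cv_curve"))
  i <- which(abs(path$lambda - curve$lambda_1se) <
               1e-12 + 1e-8 * curve$lambda_1se)
  if (length(i) != 1L) {
    stop("lambda_1se is not on the coefficient path grid", call. = FALSE)
  }
  beta <- path$coefficients[, i]
  sel <- beta != 0
  out <- data.frame(symptom = path$symptoms[sel],
                    coefficient = unname(beta[sel]),
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- curve$lambda_1se
  class(out) <- c("selected_features", "data.frame")
  out
}

#' One-call core-symptom selection
#'
#' Convenience wrapper running [fit_lasso_path()],
#' [cross_validate_deviance()] and [extract_core_symptoms()].
#'
#' @inheritParams cross_validate_deviance
#' @inheritParams fit_lasso_path
#' @return list with `path`, `curve` and `selected`.
#' @export
select_core_symptoms <- function(dataset, k = 10L, seed = 1L,
                                 standardize = FALSE) {
  path <- fit_lasso_path(dataset, standardize = standardize)
  curve <- cross_validate_deviance(dataset, path, k = k, seed = seed)
  list(path = path, curve = curve,
       selected = extract_core_symptoms(path, curve))
}
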