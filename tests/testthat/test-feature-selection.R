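kkt_gradients <- function(dataset, path, i) {
  X <- symptom_matrix(dataset)
  y <- label_vector(dataset)
  eta <- path$intercepts[i] + drop(X %*% path$coefficients[, i])
  drop(crossprod(X, y - stats::plogis(eta))) / nrow(X)
}

test_that("the path is fully shrunk at lambda_max and satisfies KKT", {
  sim <- generate_clinical_cohort(n = 200, seed = 21)
  path <- fit_lasso_path(sim$cohort)
  # analytic lambda_max: all symptom coefficients exactly zero there
  expect_true(all(path$coefficients[, 1] == 0))
  X <- symptom_matrix(sim$cohort)
  y <- label_vector(sim$cohort)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / length(y)
  expect_equal(path$lambda[1], lmax, tolerance = 1e-12)

  # KKT screening along the path: inactive features have |gradient| <= lambda
  for (i in seq(1, length(path$lambda), by = 10)) {
    g <- kkt_gradients(sim$cohort, path, i)
    inactive <- path$coefficients[, i] == 0
    expect_true(all(abs(g[inactive]) <= path$lambda[i] + 1e-6))
    active <- !inactive
    if (any(active)) {
      expect_true(all(abs(abs(g[active]) - path$lambda[i]) < 1e-4))
    }
  }
})

test_that("the unpenalized limit recovers the logistic MLE", {
  set.seed(31)
  n <- 400
  df <- data.frame(
    subject_id = sprintf("S%03d", 1:n),
    gender = sample(c("male", "female"), n, TRUE),
    age_group = sample(c("3-6", "7-14"), n, TRUE),
    x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.4), x3 = rbinom(n, 1, 0.6))
  eta <- -0.5 + 1.2 * df$x1 - 0.8 * df$x2
  df$label <- ifelse(rbinom(n, 1, plogis(eta)) == 1, "positive", "negative")
  d <- clinical_dataset(df, c("x1", "x2", "x3"))
  X <- symptom_matrix(d); y <- label_vector(d)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / n
  grid <- exp(seq(log(lmax), log(1e-8), length.out = 80))
  path <- fit_lasso_path(d, lambda_grid = grid)
  mle <- stats::glm(y ~ X, family = stats::binomial())
  expect_equal(unname(path$coefficients[, length(grid)]),
               unname(stats::coef(mle)[-1]), tolerance = 1e-4)
  expect_equal(unname(path$intercepts[length(grid)]),
               unname(stats::coef(mle)[1]), tolerance = 1e-4)
})

test_that("the strongest planted symptom enters the path first", {
  hits <- vapply(1:20, function(s) {
    truth <- synthetic_truth("Halitosis", 3, age_effect = 0)
    sim <- generate_clinical_cohort(
      n = 400, symptoms = c("Halitosis", "Belching", "Vomiting", "Epistaxis"),
      truth = truth, seed = s)
    path <- fit_lasso_path(sim$cohort)
    first_active <- apply(path$coefficients != 0, 1, function(r) {
      w <- which(r); if (length(w)) w[1] else Inf
    })
    names(which.min(first_active)) == "Halitosis"
  }, logical(1))
  expect_true(all(hits))
})

test_that("leave-one-out deviance equals brute-force enumeration", {
  df <- data.frame(
    subject_id = sprintf("S%02d", 1:10),
    gender = rep("male", 10),
    age_group = rep("3-6", 10),
    label = rep(c("positive", "negative"), each = 5),
    x1 = c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L),
    x2 = c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L))
  d <- clinical_dataset(df, c("x1", "x2"))
  # glmnet warns about the deliberately tiny class sizes; that is the point
  path <- suppressWarnings(fit_lasso_path(d, nlambda = 20))
  curve <- suppressWarnings(cross_validate_deviance(d, path, k = 10, seed = 1))

  # brute-force oracle: refit without each subject directly with glmnet
  X <- symptom_matrix(d); y <- label_vector(d)
  dev <- sapply(seq_len(10), function(i) {
    fit <- suppressWarnings(
      glmnet::glmnet(X[-i, ], y[-i], family = "binomial", alpha = 1,
                     lambda = path$lambda, standardize = FALSE,
                     thresh = 1e-10))
    p <- drop(stats::predict(fit, X[i, , drop = FALSE], s = path$lambda,
                             type = "response"))
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -2 * (y[i] * log(p) + (1 - y[i]) * log(1 - p))
  })
  expect_equal(curve$mean_deviance, unname(rowMeans(dev)), tolerance = 1e-8)
})

test_that("cross-validation is deterministic and honors the 1-SE contract", {
  sim <- generate_clinical_cohort(n = 300, seed = 8)
  path <- fit_lasso_path(sim$cohort)
  c1 <- cross_validate_deviance(sim$cohort, path, seed = 99)
  c2 <- cross_validate_deviance(sim$cohort, path, seed = 99)
  expect_identical(c1$folds, c2$folds)
  expect_identical(c1$mean_deviance, c2$mean_deviance)
  expect_gte(c1$lambda_1se, c1$lambda_min)
  i_min <- which.min(c1$mean_deviance)
  i_1se <- which(abs(c1$lambda - c1$lambda_1se) < 1e-12)
  expect_lte(c1$mean_deviance[i_1se],
             c1$mean_deviance[i_min] + c1$se_deviance[i_min])
  # the 1-SE lambda is the largest qualifying one
  if (i_1se > 1) {
    expect_gt(c1$mean_deviance[i_1se - 1],
              c1$mean_deviance[i_min] + c1$se_deviance[i_min])
  }
})

test_that("lambda.1se agrees with the reference cross-validator's scale", {
  sim <- generate_clinical_cohort(n = 660, seed = 17)
  sel <- select_core_symptoms(sim$cohort, seed = 17)
  X <- symptom_matrix(sim$cohort); y <- label_vector(sim$cohort)
  set.seed(17)
  ref <- glmnet::cv.glmnet(X, y, family = "binomial", nfolds = 10,
                           standardize = FALSE, lambda = sel$path$lambda)
  # fold randomization differs; the chosen penalties agree to within a
  # couple of grid steps on the log scale
  expect_lt(abs(log(sel$curve$lambda_1se) - log(ref$lambda.1se)), 0.7)
})

test_that("selection handles degenerate and duplicate designs", {
  sim <- generate_clinical_cohort(n = 300, seed = 5)
  path <- fit_lasso_path(sim$cohort)
  curve <- cross_validate_deviance(sim$cohort, path, seed = 5)
  # forged all-zero selection: empty set, not an error
  flat <- path
  flat$coefficients[] <- 0
  expect_equal(nrow(extract_core_symptoms(flat, curve)), 0)
  # off-grid lambda refused
  bad <- curve; bad$lambda_1se <- curve$lambda_1se * 1.5
  expect_error(extract_core_symptoms(path, bad), "not on the coefficient path")

  # exact duplicate column: the L1 penalty only constrains the pair's sum,
  # so the solver may keep both active, but never with opposing signs
  df <- as.data.frame(sim$cohort, check.names = FALSE)
  df$dup_of_first <- df[[symptom_names(sim$cohort)[1]]]
  d2 <- clinical_dataset(df, c(symptom_names(sim$cohort), "dup_of_first"))
  path2 <- fit_lasso_path(d2)
  b_orig <- path2$coefficients[symptom_names(sim$cohort)[1], ]
  b_dup <- path2$coefficients["dup_of_first", ]
  expect_true(all(b_orig * b_dup >= 0))

  # single-class labels refused
  df1 <- as.data.frame(sim$cohort, check.names = FALSE)
  df1$label <- "positive"
  expect_error(fit_lasso_path(clinical_dataset(df1)), "both")
})
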