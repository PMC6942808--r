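#' ROC curve and AUC
#'
#' Sweeps every unique score as a decision threshold (score >= threshold
#' is called positive), records the (false positive rate, true positive
#' rate) points, and integrates by the trapezoid rule.  With ties handled
#' this way the area equals the Mann-Whitney concordance probability:
#' P(score of a random positive > score of a random negative) + 1/2
#' P(equal).
#'
#' @param labels binary labels: 0/1, logical, or a factor/character with
#'   `"positive"`/`"negative"`.
#' @param scores numeric scores, higher = more likely positive.
#' @return list with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  stopifnot(length(y) == length(scores))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / n_neg, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- as.character(labels)
    if (all(lv %in% c("positive", "negative"))) {
      return(as.integer(lv == "positive"))
    }
  }
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) {
    stop("labels must be 0/1 or positive/negative", call. = FALSE)
  }
  y
}

#' The five diagnostic rates and AUC at a decision threshold
#'
#' Confusion counts with `score >= threshold` called positive, and the
#' five indicators conventional in diagnostic-model reports: accuracy,
#' sensitivity (true positive rate), omission rate (false negative rate),
#' specificity (true negative rate) and mistake rate (false positive
#' rate).  The complementary identities sensitivity + omission = 1 and
#' specificity + mistake = 1 hold exactly.  AUC is computed from the full
#' score vector via [roc_auc()].  With single-class labels the
#' class-conditional rates (and AUC) are undefined and returned as `NA`
#' with a warning.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold in \[0, 1\].
#' @return an object of class `metrics_report`: list with `accuracy`,
#'   `sensitivity`, `omission_rate`, `specificity`, `mistake_rate`,
#'   `auc`, `threshold` and `confusion` (named counts tp, fn, tn, fp).
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores), threshold >= 0, threshold <= 1)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  single <- length(unique(y)) < 2L
  if (single) {
    warning("single-class labels: class-conditional rates undefined")
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = sens,
    omission_rate = if (is.na(sens)) NA_real_ else 1 - sens,
    specificity = spec,
    mistake_rate = if (is.na(spec)) NA_real_ else 1 - spec,
    auc = if (single) NA_real_ else roc_auc(y, scores)$auc,
    threshold = threshold,
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("Diagnostic performance at threshold %.2f:\n",
                     "  accuracy %.4f | sensitivity %.4f | omission %.4f\n",
                     "  specificity %.4f | mistake %.4f | AUC %.4f\n"),
              x$threshold, x$accuracy, x$sensitivity, x$omission_rate,
              x$specificity, x$mistake_rate, x$auc))
  invisible(x)
}
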