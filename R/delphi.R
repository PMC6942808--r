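#' Per-item Delphi consensus statistics
#'
#' For each item of an expert Likert score matrix, computes the three
#' indices used to judge consensus importance: the mean expert score, the
#' full-mark rate (percentage of experts awarding the maximum score of 4)
#' and the variable coefficient (coefficient of variation: per-item score
#' standard deviation divided by the mean).  Standard deviations use the
#' sample (n - 1) convention throughout.
#'
#' An item whose mean is 0 has an undefined variable coefficient; it is
#' reported as `NA` rather than a silent division by zero (such an item is
#' always removed by the low-mean rule anyway).
#'
#' @param scores an [expert_scores] object or a bare experts x items
#'   matrix of integers in 0..4.
#' @return a data frame of class `item_stats` with columns `item`,
#'   `mean_score`, `variable_coefficient` and `full_mark_rate` (percent).
#' @examples
#' m <- rbind(c(4, 2), c(4, 4))
#' colnames(m) <- c("halitosis", "cough")
#' item_statistics(m)
#' @export
item_statistics <- function(scores) {
  m <- score_matrix(scores)
  if (nrow(m) < 2L) stop("need at least 2 experts per item", call. = FALSE)
  mean_score <- colMeans(m)
  sds <- apply(m, 2L, stats::sd)
  cv <- ifelse(mean_score == 0, NA_real_, sds / mean_score)
  full <- 100 * colMeans(m == 4L)
  out <- data.frame(item = colnames(m),
                    mean_score = unname(mean_score),
                    variable_coefficient = unname(cv),
                    full_mark_rate = unname(full),
                    stringsAsFactors = FALSE)
  class(out) <- c("item_stats", "data.frame")
  out
}

#' Delphi deletion thresholds
#'
#' Derives the three item-deletion cutoffs from the across-item
#' distribution of the consensus statistics:
#' minimum acceptable mean = mean(means) - sd(means);
#' maximum acceptable variable coefficient = mean(CVs) + sd(CVs);
#' minimum acceptable full-mark rate = mean(rates) - sd(rates).
#' All three are computed at full floating precision; round only when
#' reporting.  Items with an undefined CV are excluded from the CV
#' summary.
#'
#' @param stats an `item_stats` table from [item_statistics()].
#' @return an object of class `threshold_set` with elements `score_min`,
#'   `cv_max`, `fullmark_min`.
#' @export
deletion_thresholds <- function(stats) {
  stopifnot(inherits(stats, "data.frame"))
  if (nrow(stats) < 2L) {
    stop("at least 2 items are needed to derive thresholds (sd undefined)",
         call. = FALSE)
  }
  cv <- stats$variable_coefficient[!is.na(stats$variable_coefficient)]
  structure(list(
    score_min = mean(stats$mean_score) - stats::sd(stats$mean_score),
    cv_max = mean(cv) + stats::sd(cv),
    fullmark_min = mean(stats$full_mark_rate) - stats::sd(stats$full_mark_rate)),
    class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("Deletion thresholds: mean score < %.2f | CV > %.2f | full-mark rate < %.2f\n",
              x$score_min, x$cv_max, x$fullmark_min))
  invisible(x)
}

#' Apply the Delphi item-deletion rules
#'
#' An item is deleted if it meets any one of three conditions (strict
#' inequalities): mean score strictly below `score_min`, full-mark rate
#' strictly below `fullmark_min`, or variable coefficient strictly above
#' `cv_max`.  Items with an undefined CV (mean 0) skip the CV rule; they
#' are caught by the low-mean rule whenever `score_min > 0`.
#'
#' @param stats an `item_stats` table.
#' @param thresholds a `threshold_set`, typically from
#'   [deletion_thresholds()]; printed/published thresholds may be supplied
#'   directly for reproduction work.
#' @return an object of class `screening_result`: list with `retained`
#'   (character) and `deleted` (data frame with columns `item` and
#'   `rules`, the comma-joined rule tags `low_mean`, `low_fullmark`,
#'   `high_cv`).
#' @examples
#' fx <- load_reference_fixtures()
#' res <- apply_deletion_rules(fx$delphi_items, fx$delphi_thresholds)
#' length(res$retained)   # 37
#' res$deleted$item       # the 10 removed symptoms
#' @export
apply_deletion_rules <- function(stats, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  need <- c("item", "mean_score", "variable_coefficient", "full_mark_rate")
  if (!all(need %in% names(stats))) {
    stop("item statistics table is missing columns", call. = FALSE)
  }
  if (anyNA(stats$mean_score) || anyNA(stats$full_mark_rate)) {
    stop("every item needs a mean score and full-mark rate", call. = FALSE)
  }
  low_mean <- stats$mean_score < thresholds$score_min
  low_full <- stats$full_mark_rate < thresholds$fullmark_min
  high_cv <- !is.na(stats$variable_coefficient) &
    stats$variable_coefficient > thresholds$cv_max
  hit <- low_mean | low_full | high_cv
  rules <- vapply(seq_len(nrow(stats)), function(i) {
    paste(c("low_mean", "low_fullmark", "high_cv")[
      c(low_mean[i], low_full[i], high_cv[i])], collapse = ",")
  }, character(1))
  structure(list(
    retained = stats$item[!hit],
    deleted = data.frame(item = stats$item[hit], rules = rules[hit],
                         stringsAsFactors = FALSE),
    thresholds = thresholds),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Delphi screening: %d retained, %d deleted\n",
              length(x$retained), nrow(x$deleted)))
  if (nrow(x$deleted)) {
    cat(paste0("  - ", x$deleted$item, " [", x$deleted$rules, "]",
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Cronbach's alpha of an expert score matrix
#'
#' Internal-consistency reliability of the item battery:
#' `alpha = k/(k - 1) * (1 - sum(item variances) / variance(rater totals))`,
#' with k the number of items and all variances on the sample (n - 1)
#' denominator.  A matrix whose rater totals do not vary has no defined
#' alpha; `NA` is returned with a warning.
#'
#' @param scores an [expert_scores] object or bare matrix (raters x items).
#' @return an object of class `reliability_result`: list with `alpha`,
#'   `k`, `item_variances`, `total_variance`.
#' @export
cronbach_alpha <- function(scores) {
  m <- score_matrix(scores)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 raters and 2 items", call. = FALSE)
  }
  k <- ncol(m)
  item_var <- apply(m, 2L, stats::var)
  total_var <- stats::var(rowSums(m))
  alpha <- if (total_var == 0) {
    warning("rater totals have zero variance; alpha undefined")
    NA_real_
  } else {
    k / (k - 1) * (1 - sum(item_var) / total_var)
  }
  structure(list(alpha = alpha, k = k, item_variances = item_var,
                 total_variance = total_var),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (k = %d items)\n", x$alpha, x$k))
  invisible(x)
}
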