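#' Cross-tabulate a cohort covariate against the diagnosis label
#'
#' Builds the 2x2 contingency table of a two-level covariate (gender or
#' age group) by diagnosis group, with rows `positive`, `negative`.
#'
#' @param dataset a [clinical_dataset].
#' @param covariate `"gender"` or `"age_group"` (or any two-level column).
#' @return an object of class `contingency_table`: an integer matrix with
#'   a `percent` attribute holding within-group percentages.
#' @export
crosstab <- function(dataset, covariate = c("gender", "age_group")) {
  covariate <- covariate[1L]
  if (!covariate %in% names(dataset)) {
    stop("covariate not found: ", covariate, call. = FALSE)
  }
  if (nrow(dataset) == 0L) stop("empty dataset", call. = FALSE)
  v <- droplevels(factor(dataset[[covariate]]))
  if (nlevels(v) != 2L) {
    stop("covariate must have exactly two observed levels", call. = FALSE)
  }
  tab <- table(group = factor(dataset$label, levels = c("positive", "negative")),
               level = v)
  m <- matrix(as.integer(tab), nrow = 2L,
              dimnames = list(group = rownames(tab), level = colnames(tab)))
  attr(m, "percent") <- round(100 * m / rowSums(m), 2)
  class(m) <- c("contingency_table", class(m))
  m
}

#' Pearson chi-square test on a 2x2 table
#'
#' The classical uncorrected Pearson statistic
#' `sum((observed - expected)^2 / expected)` with 1 degree of freedom,
#' matching the convention of most clinical group comparisons.  The Yates
#' continuity correction is available behind a flag but off by default.
#'
#' @param table 2x2 numeric matrix (e.g. from [crosstab()]).
#' @param correct apply the Yates continuity correction? Default `FALSE`.
#' @return an object of class `chi_square_result`: list with `statistic`,
#'   `df`, `p_value`, `expected`.
#' @examples
#' m <- matrix(c(250, 66, 203, 141), nrow = 2, byrow = FALSE)
#' pearson_chi_square(m)$statistic  # 30.918
#' @export
pearson_chi_square <- function(table, correct = FALSE) {
  m <- unclass(table)
  attr(m, "percent") <- NULL
  if (!is.matrix(m) || any(dim(m) != 2L)) {
    stop("a 2x2 table is required", call. = FALSE)
  }
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  dev <- abs(m - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1L, lower.tail = FALSE),
                 expected = expected),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Describe a cohort the way clinical papers tabulate it
#'
#' One row per covariate: the 2x2 counts with within-group percentages and
#' the uncorrected Pearson chi-square comparison of the diagnosis groups.
#'
#' @param dataset a [clinical_dataset].
#' @param covariates covariates to tabulate.
#' @return data frame with one row per covariate level and the chi-square
#'   statistic and p-value attached to the first level of each covariate.
#' @export
describe_cohort <- function(dataset, covariates = c("gender", "age_group")) {
  rows <- lapply(covariates, function(cv) {
    tab <- crosstab(dataset, cv)
    chi <- pearson_chi_square(tab)
    pc <- attr(tab, "percent")
    data.frame(covariate = cv, level = colnames(tab),
               positive = tab["positive", ],
               positive_pct = pc["positive", ],
               negative = tab["negative", ],
               negative_pct = pc["negative", ],
               chi_square = c(chi$statistic, NA),
               p_value = c(chi$p_value, NA),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
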