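#' Packaged reference tables from the motivating GHRS study
#'
#' Loads the plain-text reference tables shipped with the package, drawn
#' from the published characterization of gastrointestinal heat retention
#' syndrome (GHRS) in children that this pipeline operationalizes:
#'
#' * `delphi_items`: the 47 second-round Delphi items with their printed
#'   average score, variable coefficient (coefficient of variation) and
#'   full-mark rate (percent of experts awarding the maximum score);
#' * `delphi_thresholds`: the printed deletion thresholds as a
#'   [deletion_thresholds()] object (minimum mean 2.07, maximum variable
#'   coefficient 0.44, minimum full-mark rate 2.94);
#' * `symptom_term_map`: the 19 core symptoms and their phenotype-ontology
#'   terms, 7 of which map to no term (tongue, fur and pulse signs have no
#'   ontology counterpart);
#' * `cohort_counts`: the published 2x2 gender and age-group counts for the
#'   positive (n = 453) and negative (n = 207) diagnosis groups.
#'
#' @return a list with the four components above.
#' @examples
#' fx <- load_reference_fixtures()
#' nrow(fx$delphi_items)      # 47
#' lengths(fx$symptom_term_map)
#' @export
load_reference_fixtures <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "ghrskit")
    if (!nzchar(p) || !file.exists(p)) {
      stop("packaged fixture not found: ", f, call. = FALSE)
    }
    p
  }
  items <- utils::read.csv(path("delphi_item_indices.csv"),
                           stringsAsFactors = FALSE)
  need <- c("item", "average_score", "variable_coefficient", "full_mark_rate")
  if (!all(need %in% names(items)) || nrow(items) != 47L) {
    stop("delphi item fixture is corrupt", call. = FALSE)
  }
  stats <- data.frame(item = items$item,
                      mean_score = items$average_score,
                      variable_coefficient = items$variable_coefficient,
                      full_mark_rate = items$full_mark_rate,
                      stringsAsFactors = FALSE)
  class(stats) <- c("item_stats", "data.frame")

  thresholds <- structure(
    list(score_min = 2.07, cv_max = 0.44, fullmark_min = 2.94),
    class = "threshold_set")

  stm <- read_symptom_term_map(path("core_symptom_hpo_terms.tsv"))

  counts <- utils::read.csv(path("cohort_characteristics.csv"),
                            stringsAsFactors = FALSE)
  tabs <- lapply(split(counts, counts$covariate), function(d) {
    m <- t(as.matrix(d[, c("positive", "negative")]))
    dimnames(m) <- list(group = c("positive", "negative"), level = d$level)
    m
  })

  list(delphi_items = stats,
       delphi_thresholds = thresholds,
       symptom_term_map = stm,
       cohort_counts = tabs)
}
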