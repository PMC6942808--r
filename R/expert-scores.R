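#' Expert Likert score matrix
#'
#' Container for one round of a Delphi consensus survey: a matrix of ordinal
#' scores on a 5-point Likert scale (0 = unimportant ... 4 = very important),
#' with experts (raters) in rows and candidate items in columns.
#'
#' @param scores integer matrix, experts x items, every entry in 0..4.
#'   Column names are the item labels; row names identify the raters
#'   (generated as `E1`, `E2`, ... when absent).
#' @param round_id integer survey round identifier.
#' @return an object of class `expert_scores`.
#' @export
expert_scores <- function(scores, round_id = 1L) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L || ncol(scores) < 2L) {
    stop("an expert score matrix needs at least 2 experts and 2 items",
         call. = FALSE)
  }
  if (anyNA(scores) || !all(scores == round(scores)) ||
      any(scores < 0) || any(scores > 4)) {
    stop("scores must be integers in 0..4 (5-point Likert scale)",
         call. = FALSE)
  }
  storage.mode(scores) <- "integer"
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("item", seq_len(ncol(scores)))
  }
  if (anyDuplicated(colnames(scores))) {
    stop("item labels must be unique", call. = FALSE)
  }
  if (is.null(rownames(scores))) {
    rownames(scores) <- paste0("E", seq_len(nrow(scores)))
  }
  structure(list(round_id = as.integer(round_id), scores = scores),
            class = "expert_scores")
}

#' @export
print.expert_scores <- function(x, ...) {
  cat(sprintf("Expert Likert scores (round %d): %d experts x %d items\n",
              x$round_id, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

# Accept either an `expert_scores` object or a bare matrix.
score_matrix <- function(x) {
  if (inherits(x, "expert_scores")) x$scores else expert_scores(x)$scores
}

#' Simulate a Delphi expert scoring round
#'
#' Draws ordinal scores for each item from a bounded integer mixture: with
#' weight `kappa / (1 + kappa)` a Binomial(4, p) component whose p is solved
#' so that the mixture mean equals the requested item mean `mu`, and with
#' the complementary weight a uniform component over 0..4 that injects
#' rater disagreement.  Large `kappa` concentrates scores around the target
#' mean; small `kappa` inflates the coefficient of variation.  Items flagged
#' `planted_weak` are forced to a low mean and high dispersion so that the
#' standard Delphi deletion rules remove them — useful as known negatives
#' in screening tests.
#'
#' @param n_experts number of raters (>= 2).
#' @param items data frame with columns `item` (label, optional), `mu`
#'   (target mean in \[0, 4\]), and optionally `kappa` (concentration > 0,
#'   default 9) and `planted_weak` (logical, default FALSE).
#' @param seed integer seed; identical inputs give identical matrices.
#' @param round_id survey round identifier stored on the result.
#' @return an [expert_scores] object with one column per item.
#' @examples
#' items <- data.frame(item = c("halitosis", "cough"),
#'                     mu = c(3.7, 1.9), planted_weak = c(FALSE, TRUE))
#' m <- generate_expert_scores(54, items, seed = 1)
#' colMeans(m$scores)
#' @export
generate_expert_scores <- function(n_experts, items, seed, round_id = 2L) {
  if (n_experts < 2) stop("need at least 2 experts", call. = FALSE)
  items <- as.data.frame(items)
  if (!"mu" %in% names(items)) stop("`items` needs a `mu` column", call. = FALSE)
  if (is.null(items$item)) items$item <- paste0("item", seq_len(nrow(items)))
  if (is.null(items$kappa)) items$kappa <- 9
  if (is.null(items$planted_weak)) items$planted_weak <- FALSE
  if (any(!is.finite(items$mu)) || any(items$mu < 0) || any(items$mu > 4)) {
    stop("item means `mu` must lie in [0, 4]", call. = FALSE)
  }
  if (any(items$kappa <= 0)) stop("`kappa` must be positive", call. = FALSE)

  mu <- ifelse(items$planted_weak, pmin(items$mu, 1.6), items$mu)
  kappa <- ifelse(items$planted_weak, pmin(items$kappa, 1), items$kappa)
  w <- ifelse(is.infinite(kappa), 1, kappa / (1 + kappa))
  # solve the binomial p so the mixture keeps the target mean
  p <- (mu - 2 * (1 - w)) / (4 * w)
  if (any(p < -1e-12 | p > 1 + 1e-12)) {
    bad <- items$item[p < -1e-12 | p > 1 + 1e-12]
    stop("mean/concentration combination unreachable for item(s): ",
         paste(bad, collapse = ", "),
         " (increase kappa or move mu toward 2)", call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)

  with_seed(seed, {
    cols <- lapply(seq_len(nrow(items)), function(j) {
      from_binom <- stats::runif(n_experts) < w[j]
      out <- integer(n_experts)
      out[from_binom] <- stats::rbinom(sum(from_binom), 4L, p[j])
      out[!from_binom] <- sample(0:4, sum(!from_binom), replace = TRUE)
      out
    })
    m <- do.call(cbind, cols)
    colnames(m) <- items$item
    expert_scores(m, round_id = round_id)
  })
}
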