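N_CATEGORIES <- 5L

#' Validate a five-category probability vector
#'
#' @param probs Numeric vector of five non-negative probabilities over
#'   the ordered acute toxicity categories 1..5, summing to 1 within
#'   `tol`.
#' @param tol Sum tolerance (default 1e-9).
#' @return The probabilities as a plain numeric vector, invisibly
#'   normalized names `cat1..cat5`.
#' @export
category_distribution <- function(probs, tol = 1e-9) {
  if (!is.numeric(probs) || length(probs) != N_CATEGORIES || anyNA(probs)) {
    stop("a category distribution is five non-missing probabilities",
         call. = FALSE)
  }
  if (any(probs < 0)) stop("category probabilities must be non-negative",
                           call. = FALSE)
  if (abs(sum(probs) - 1) > tol) {
    stop(sprintf("category probabilities must sum to 1 (got %.12f)",
                 sum(probs)), call. = FALSE)
  }
  stats::setNames(as.numeric(probs), paste0("cat", 1:5))
}

#' Five-category counts with totals
#'
#' @param counts Five non-negative integer counts over categories 1..5.
#' @return Named integer vector with attribute `total`.
#' @export
category_counts <- function(counts) {
  if (length(counts) != N_CATEGORIES || anyNA(counts)) {
    stop("category counts are five non-missing values", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("category counts must be non-negative integers", call. = FALSE)
  }
  out <- stats::setNames(as.integer(round(counts)), paste0("cat", 1:5))
  attr(out, "total") <- sum(out)
  out
}

#' Prevalence-scale raw category counts
#'
#' Corrects a subgroup's raw category frequencies for the imbalance of
#' the reference dataset: each category's raw share is divided by that
#' category's prevalence share, and the resulting enrichment ratios are
#' renormalized to sum to one. Exact counts are used throughout;
#' rounding to percentages happens only at the reporting boundary.
#'
#' @param raw Subgroup counts over categories 1..5 ([category_counts()]
#'   or plain numeric).
#' @param prevalence Reference dataset counts over categories 1..5.
#' @return A [category_distribution()].
#' @examples
#' # Cramer Class III subgroup against the 8186-compound reference set
#' round(100 * scale_distribution(c(219, 629, 1385, 3003, 1861),
#'                                c(219, 638, 1452, 3326, 2551)), 1)
#' @export
scale_distribution <- function(raw, prevalence) {
  raw <- category_counts(raw)
  prevalence <- category_counts(prevalence)
  if (attr(raw, "total") <= 0 || attr(prevalence, "total") <= 0) {
    stop("both count totals must be positive", call. = FALSE)
  }
  undefined <- prevalence == 0 & raw > 0
  if (any(undefined)) {
    stop("undefined enrichment ratio: zero prevalence with non-zero raw count in category ",
         paste(which(undefined), collapse = ", "), call. = FALSE)
  }
  ratio <- numeric(N_CATEGORIES)
  nz <- prevalence > 0
  ratio[nz] <- (raw[nz] / attr(raw, "total")) /
    (prevalence[nz] / attr(prevalence, "total"))
  category_distribution(ratio / sum(ratio))
}

#' Exclusionary category attribution
#'
#' Discards every category whose probability falls strictly below the
#' threshold and assigns the most hazardous (lowest-numbered) surviving
#' category. A probability exactly at the threshold survives. With
#' thresholds at or below 0.2 at least one category always survives,
#' since the maximum of five probabilities is at least 0.2.
#'
#' @param dist A [category_distribution()] (or five probabilities).
#' @param threshold Exclusion threshold as a fraction in (0, 0.2].
#' @return The assigned category, an integer in 1..5.
#' @examples
#' assign_category_exclusionary(c(0.08, 0.55, 0.30, 0.04, 0.03), 0.10) # 2
#' assign_category_exclusionary(c(0.08, 0.55, 0.30, 0.04, 0.03), 0.05) # 1
#' @export
assign_category_exclusionary <- function(dist, threshold) {
  dist <- category_distribution(dist)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold > 0.2) {
    stop("`threshold` must be a single fraction in (0, 0.2]", call. = FALSE)
  }
  surviving <- which(dist >= threshold)
  if (!length(surviving)) {
    stop("all categories excluded; no assignment possible", call. = FALSE)
  }
  as.integer(min(surviving))
}

#' Probability-weighted mean category
#'
#' Scalar severity summary of a category distribution: the expected
#' value of the category index 1..5 (1 = most toxic).
#'
#' @param dist A [category_distribution()].
#' @return Numeric scalar in \[1, 5\].
#' @export
expected_severity <- function(dist) {
  dist <- category_distribution(dist)
  sum(dist * seq_len(N_CATEGORIES))
}

#' Additive log-ratio encoding of a category distribution
#'
#' Floors all five probabilities at `floor`, renormalizes, and returns
#' log(p_k / p_5) for k = 1..4. Used to carry a tier's distribution
#' into the next tier's regression design as a four-column block.
#'
#' @param dist A [category_distribution()].
#' @param floor Positive probability floor applied before the ratio.
#' @return Numeric vector of four log ratios.
#' @export
log_ratio_encode <- function(dist, floor = 1e-6) {
  dist <- category_distribution(dist)
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    stop("`floor` must be a single positive fraction", call. = FALSE)
  }
  p <- pmax(dist, floor)
  p <- p / sum(p)
  stats::setNames(log(p[1:4] / p[5]), paste0("logratio_", 1:4))
}

#' Format a category distribution as percentages
#'
#' Reporting-boundary helper: percentages to one decimal place with
#' half-up rounding (so 19.75 prints as 19.8, not banker's 19.7 vs
#' base R `round`).
#'
#' @param dist A [category_distribution()].
#' @return Numeric vector of five percentages with one decimal.
#' @export
format_percent <- function(dist) {
  dist <- category_distribution(dist)
  # half-up rounding at one decimal on the percent scale
  floor(dist * 1000 + 0.5) / 10
}
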