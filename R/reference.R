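#' Reference category prevalence of the rat acute oral LD50 collation
#'
#' Category counts of the 8186-compound curated rat acute oral LD50
#' dataset (NICEATM/US-EPA collation as refined by Gadaleta and
#' colleagues) that the shipped Tier-0 and alert distributions were
#' derived from: 219 / 638 / 1452 / 3326 / 2551 compounds in categories
#' 1-5 (2.7 / 7.8 / 17.7 / 40.6 / 31.2 percent).
#'
#' @return A [category_counts()] vector (total 8186).
#' @export
reference_prevalence <- function() {
  category_counts(c(219, 638, 1452, 3326, 2551))
}

#' Raw category counts of Cramer Class III reference compounds
#'
#' Of the 7097 reference compounds assigned Cramer Class III, 219 fell
#' in category 1, 629 in category 2, 1385 in category 3, 3003 in
#' category 4 and 1861 in category 5.
#'
#' @return A [category_counts()] vector (total 7097).
#' @export
cramer_class3_counts <- function() {
  category_counts(c(219, 629, 1385, 3003, 1861))
}

#' Prevalence-scaled Cramer class category distributions (Tier 0)
#'
#' The scaled category-probability distributions associated with the
#' three Cramer structural classes in the 8186-compound reference set,
#' together with each class's dataset coverage. The Class III row is
#' recomputed from its raw counts through [scale_distribution()]; the
#' Class I and II rows are the published scaled percentages (their raw
#' counts are not public at full precision).
#'
#' @return A list with elements `I`, `II`, `III` (each a
#'   [category_distribution()]) and attribute `coverage` (named percent
#'   vector).
#' @export
cramer_reference <- function() {
  # published Class I/II rows are printed to 1 d.p. (sums 99.9);
  # renormalize to exact unit mass
  row_i <- c(0.0, 2.6, 10.2, 22.3, 64.8)
  row_ii <- c(0.0, 7.6, 13.3, 25.2, 53.8)
  out <- list(
    I   = category_distribution(row_i / sum(row_i)),
    II  = category_distribution(row_ii / sum(row_ii)),
    III = scale_distribution(cramer_class3_counts(), reference_prevalence())
  )
  attr(out, "coverage") <- c(I = 11.4, II = 1.9, III = 86.7)
  out
}

#' Tier-0 category distribution for a Cramer class
#'
#' @param cramer_class Character vector of classes ("I", "II", "III").
#' @param reference Output of [cramer_reference()] (or a compatible
#'   list, e.g. derived from a labelled reference table).
#' @return A matrix (length(cramer_class) x 5) of category
#'   probabilities, one row per input.
#' @export
tier0_distribution <- function(cramer_class, reference = cramer_reference()) {
  cls <- toupper(trimws(as.character(cramer_class)))
  bad <- !cls %in% names(reference)
  if (any(bad)) {
    stop("no Tier-0 distribution for Cramer class: ",
         paste(unique(cls[bad]), collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(cls, function(k) reference[[k]]))
  rownames(out) <- NULL
  colnames(out) <- paste0("cat", 1:5)
  out
}

#' Derive scaled class distributions from a labelled reference table
#'
#' Tabulates experimental categories within each class of a labelled
#' compound set and prevalence-scales each class's counts against the
#' whole set, reproducing the Tier-0 derivation on user data.
#'
#' @param class_labels Character vector of group labels (e.g. Cramer
#'   classes), one per compound; `NA`/empty labels are dropped from the
#'   per-class counts but retained in the prevalence.
#' @param categories Integer vector of experimental categories 1..5.
#' @return Named list of [category_distribution()]s, one per class
#'   present, with attributes `counts` (class x category matrix) and
#'   `coverage` (percent of labelled compounds per class). Classes with
#'   zero members are omitted with a warning.
#' @export
derive_class_distributions <- function(class_labels, categories) {
  if (length(class_labels) != length(categories)) {
    stop("label and category vectors must have equal length", call. = FALSE)
  }
  if (anyNA(categories) || !all(categories %in% 1:5)) {
    stop("categories must all be in 1..5", call. = FALSE)
  }
  prevalence <- category_counts(tabulate(categories, nbins = 5))
  cls <- as.character(class_labels)
  keep <- !is.na(cls) & nzchar(cls)
  lv <- if (is.factor(class_labels)) levels(class_labels) else sort(unique(cls[keep]))
  counts <- t(vapply(lv, function(k) {
    tabulate(categories[keep & cls == k], nbins = 5)
  }, numeric(5)))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("omitting class(es) with zero members: ",
            paste(lv[empty], collapse = ", "), call. = FALSE)
    counts <- counts[!empty, , drop = FALSE]
    lv <- lv[!empty]
  }
  out <- lapply(seq_along(lv), function(i) {
    scale_distribution(counts[i, ], prevalence)
  })
  names(out) <- lv
  colnames(counts) <- paste0("cat", 1:5)
  attr(out, "counts") <- counts
  attr(out, "coverage") <- 100 * rowSums(counts) / length(categories)
  out
}

#' Class-given-category conditionals implied by the reference tables
#'
#' Inverts the shipped prevalence-scaled Cramer rows back to the raw
#' class-by-category composition: a class's raw count in category k is
#' proportional to its scaled probability times the category's
#' prevalence count, scaled to the class's coverage. Normalizing each
#' category column gives P(class | category), the conditional the
#' synthetic-data generator draws Cramer classes from.
#'
#' @return A 3 x 5 matrix (rows I, II, III; columns cat1..cat5) of
#'   conditional probabilities; columns sum to 1.
#' @export
cramer_class_given_category <- function() {
  ref <- cramer_reference()
  cov <- attr(ref, "coverage")
  prev <- reference_prevalence()
  n_total <- attr(prev, "total")
  raw <- t(vapply(names(ref), function(k) {
    w <- ref[[k]] * as.numeric(prev)
    w / sum(w) * (cov[[k]] / 100 * n_total)
  }, numeric(5)))
  cond <- sweep(raw, 2, colSums(raw), "/")
  rownames(cond) <- names(ref)
  colnames(cond) <- paste0("cat", 1:5)
  cond
}
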