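#' Build a tier evaluation report
#'
#' Confusion matrix (rows experimental, columns predicted) with
#' correct/over/under-prediction tallies and a deviation histogram.
#' Overprediction means the predicted category is numerically smaller
#' (more toxic) than the experimental one — the framework's deliberate
#' conservative direction; deviation is experimental minus predicted,
#' so positive deviations are overpredictions.
#'
#' @param experimental,predicted Equal-length integer vectors of
#'   categories 1..5.
#' @return A list of class `tier_eval`: `confusion` (5 x 5),
#'   `n_correct`, `n_over`, `n_under`, `deviation_histogram` (named
#'   counts for deviations -4..+4).
#' @export
build_report <- function(experimental, predicted) {
  if (length(experimental) != length(predicted)) {
    stop("experimental and predicted vectors must have equal length",
         call. = FALSE)
  }
  experimental <- as.integer(experimental)
  predicted <- as.integer(predicted)
  if (anyNA(experimental) || anyNA(predicted) ||
      !all(experimental %in% 1:5) || !all(predicted %in% 1:5)) {
    stop("categories must all lie in 1..5", call. = FALSE)
  }
  confusion <- table(factor(experimental, levels = 1:5),
                     factor(predicted, levels = 1:5))
  confusion <- matrix(as.integer(confusion), 5, 5,
                      dimnames = list(experimental = paste0("exp", 1:5),
                                      predicted = paste0("pred", 1:5)))
  deviation <- experimental - predicted
  hist <- table(factor(deviation, levels = -4:4))
  structure(list(
    confusion = confusion,
    n_correct = sum(predicted == experimental),
    n_over = sum(predicted < experimental),
    n_under = sum(predicted > experimental),
    deviation_histogram = stats::setNames(as.integer(hist), names(hist))
  ), class = "tier_eval")
}

#' Count overpredictions in a confusion matrix
#'
#' With experimental categories on rows and predicted on columns,
#' overpredictions (predicted more toxic than observed) are the
#' entries below the diagonal: column index smaller than row index.
#'
#' @param confusion 5 x 5 non-negative matrix.
#' @return Integer count.
#' @export
count_overpredictions <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == 5, ncol(confusion) == 5, all(confusion >= 0))
  sum(confusion[col(confusion) < row(confusion)])
}

#' Count underpredictions in a confusion matrix
#'
#' @param confusion 5 x 5 non-negative matrix (experimental rows,
#'   predicted columns).
#' @return Integer count of entries above the diagonal (predicted less
#'   toxic than observed).
#' @export
count_underpredictions <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == 5, ncol(confusion) == 5, all(confusion >= 0))
  sum(confusion[col(confusion) > row(confusion)])
}

#' LD50-variability category-switch analysis
#'
#' Experimental LD50 values are medians of a replicate distribution;
#' this analysis shifts each LD50 by plus or minus `delta` log10 units
#' (the replicate 95 percent confidence half-width, 0.31 by default),
#' re-categorizes, and reports the percentage of compounds whose
#' category changes in each direction.
#'
#' @param records A `compound_records` data frame (or anything with an
#'   `ld50_mg_kg` column).
#' @param delta Non-negative shift in log10(mg/kg).
#' @param bounds [category_bounds()].
#' @return A list: `pct_changed_up` (after adding `delta`),
#'   `pct_changed_down` (after subtracting), `n` compounds considered.
#' @export
ld50_variability_switch <- function(records, delta = 0.31,
                                    bounds = category_bounds()) {
  if (delta < 0) stop("`delta` must be non-negative", call. = FALSE)
  ld50 <- records$ld50_mg_kg
  ld50 <- ld50[!is.na(ld50)]
  if (!length(ld50)) stop("no records carry an LD50 value", call. = FALSE)
  base <- categorize(ld50, bounds)
  up <- categorize(ld50 * 10^delta, bounds)
  down <- categorize(ld50 * 10^(-delta), bounds)
  list(pct_changed_up = 100 * mean(up != base),
       pct_changed_down = 100 * mean(down != base),
       n = length(ld50))
}

#' @export
print.tier_eval <- function(x, ...) {
  n <- sum(x$confusion)
  cat(sprintf("Category assignment evaluation (n = %d)\n", n))
  cat(sprintf("  correct: %d  overpredicted: %d  underpredicted: %d\n",
              x$n_correct, x$n_over, x$n_under))
  cat("  confusion matrix (rows experimental, columns predicted):\n")
  print(x$confusion)
  cat("  deviation histogram (experimental - predicted; positive = overpredicted):\n")
  print(x$deviation_histogram)
  invisible(x)
}

#' Write an evaluation report to delimited files
#'
#' @param report A `tier_eval`.
#' @param path CSV path for the confusion matrix; a `*_summary.txt`
#'   sibling receives the tallies.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "tier_eval"))
  utils::write.csv(as.data.frame(report$confusion), path, row.names = TRUE)
  summary_path <- sub("\\.csv$", "_summary.txt", path)
  lines <- c(
    sprintf("n=%d", sum(report$confusion)),
    sprintf("correct=%d", report$n_correct),
    sprintf("overpredicted=%d", report$n_over),
    sprintf("underpredicted=%d", report$n_under),
    paste0("deviation_histogram=",
           paste(sprintf("%s:%d", names(report$deviation_histogram),
                         report$deviation_histogram), collapse = ","))
  )
  writeLines(lines, summary_path)
  invisible(path)
}
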