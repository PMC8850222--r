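#' Assemble a modelling feature matrix from structures
#'
#' Builds the random-forest input block: binary substructure-key
#' fingerprints (OpenBabel MACCS-type keys by default) filtered by
#' prevalence, concatenated with a numeric physicochemical descriptor
#' block. The published model used a commercial descriptor package;
#' here an open descriptor set from the OpenBabel backend is the
#' default, and any user-supplied numeric descriptor table is accepted
#' in its place.
#'
#' @param smiles Character vector of parseable SMILES.
#' @param fingerprint Fingerprint name passed to the backend
#'   ("MACCS", "FP2", "FP4").
#' @param descriptors Optional numeric matrix/data frame of descriptors
#'   (rows in `smiles` order); `NULL` computes the backend defaults.
#' @param min_prev,max_prev Fingerprint-bit prevalence bounds (bits
#'   outside are dropped; see [filter_fingerprint_bits()]).
#' @return A list of class `feature_matrix`: `compound_ids`,
#'   `fingerprint_block` (binary matrix), `descriptor_block` (numeric
#'   matrix), `matrix` (the concatenation), `column_names`.
#' @export
build_feature_matrix <- function(smiles, fingerprint = "MACCS",
                                 descriptors = NULL,
                                 min_prev = 0.05, max_prev = 0.95) {
  ok <- smiles_parseable(smiles)
  if (!all(ok)) {
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(!ok), 5), collapse = ", "), call. = FALSE)
  }
  ids <- if (!is.null(names(smiles))) names(smiles) else sprintf("c%06d", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids)))
  fpset <- ChemmineR::fingerprintOB(sdf, fingerprint)
  fp <- ChemmineR::as.matrix(fpset)
  storage.mode(fp) <- "integer"
  colnames(fp) <- sprintf("%s_bit%03d", tolower(fingerprint), seq_len(ncol(fp)))
  fp <- filter_fingerprint_bits(fp, min_prev, max_prev)

  if (is.null(descriptors)) {
    pr <- ChemmineR::propOB(sdf)
    keep <- vapply(pr, is.numeric, logical(1))
    descriptors <- as.matrix(pr[, keep, drop = FALSE])
  } else {
    descriptors <- as.matrix(descriptors)
    if (nrow(descriptors) != length(smiles)) {
      stop("descriptor rows must match the number of structures", call. = FALSE)
    }
  }
  # drop all-constant descriptor columns (uninformative for trees)
  vary <- apply(descriptors, 2, function(x) length(unique(x[!is.na(x)])) > 1L)
  descriptors <- descriptors[, vary, drop = FALSE]
  rownames(fp) <- rownames(descriptors) <- ids
  structure(list(
    compound_ids = ids,
    fingerprint_block = fp,
    descriptor_block = descriptors,
    matrix = cbind(fp, descriptors),
    column_names = c(colnames(fp), colnames(descriptors))
  ), class = "feature_matrix")
}

#' Filter fingerprint bits by prevalence
#'
#' Bits set in fewer than `min_prev` or more than `max_prev` of the
#' compounds are excluded; the bounds themselves are retained, since
#' exclusion is phrased strictly ("fewer than 5 percent", "greater
#' than 95 percent").
#'
#' @param bits Binary matrix (compounds x bits).
#' @param min_prev,max_prev Prevalence bounds as fractions,
#'   `0 <= min_prev < max_prev <= 1`.
#' @return The matrix restricted to retained columns.
#' @export
filter_fingerprint_bits <- function(bits, min_prev = 0.05, max_prev = 0.95) {
  bits <- as.matrix(bits)
  if (!(min_prev >= 0 && min_prev < max_prev && max_prev <= 1)) {
    stop("require 0 <= min_prev < max_prev <= 1", call. = FALSE)
  }
  if (nrow(bits) == 0L || ncol(bits) == 0L) {
    return(bits[, integer(0), drop = FALSE])
  }
  prev <- colMeans(bits != 0)
  bits[, prev >= min_prev & prev <= max_prev, drop = FALSE]
}

#' Random forest LD50 model with out-of-fold predictions
#'
#' Fits a 500-tree random forest regression of log LD50 on the feature
#' matrix under seeded k-fold cross-validation: every compound's
#' reported prediction comes from the forest whose training fold
#' excluded it. A final forest fitted on all data is returned as the
#' deployable model handle.
#'
#' @param features A `feature_matrix` (or plain numeric matrix).
#' @param target Numeric response (log LD50), one per row.
#' @param n_trees Trees per forest (default 500).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment and forests.
#' @return List of class `rf_oof_fit`: `oof_pred`, `folds`, `model`
#'   (the full-data forest), `r_squared` (out-of-fold), `n_trees`,
#'   `n_folds`, `seed`.
#' @export
train_rf_oof <- function(features, target, n_trees = 500L, n_folds = 10L,
                         seed = 1L) {
  X <- if (inherits(features, "feature_matrix")) features$matrix else as.matrix(features)
  y <- as.numeric(target)
  if (nrow(X) != length(y)) stop("feature rows must match target length", call. = FALSE)
  if (anyNA(y)) stop("target contains missing values", call. = FALSE)
  n <- nrow(X)
  if (n < n_folds) {
    stop(sprintf("need at least %d labelled compounds for %d-fold CV (got %d)",
                 n_folds, n_folds, n), call. = FALSE)
  }
  set.seed(seed)
  folds <- sample(rep_len(seq_len(n_folds), n))
  oof <- rep(NA_real_, n)
  for (f in seq_len(n_folds)) {
    hold <- folds == f
    fit <- randomForest::randomForest(X[!hold, , drop = FALSE], y[!hold],
                                      ntree = n_trees)
    oof[hold] <- stats::predict(fit, X[hold, , drop = FALSE])
  }
  model <- randomForest::randomForest(X, y, ntree = n_trees)
  r2 <- stats::cor(oof, y)^2
  structure(list(oof_pred = oof, folds = folds, model = model,
                 r_squared = r2, n_trees = n_trees, n_folds = n_folds,
                 seed = seed),
            class = "rf_oof_fit")
}

#' @export
print.rf_oof_fit <- function(x, ...) {
  cat(sprintf("Random forest LD50 model: %d trees, %d-fold CV (seed %d)\n",
              x$n_trees, x$n_folds, x$seed))
  cat(sprintf("  out-of-fold r-squared: %.3f on %d compounds\n",
              x$r_squared, length(x$oof_pred)))
  invisible(x)
}

#' Ingest an external QSAR prediction column
#'
#' Populates a prediction field on the records from a table column,
#' counting (and reporting) compounds with no available prediction;
#' the count feeds the eligibility filter for the balanced evaluation
#' set.
#'
#' @param records A `compound_records` data frame.
#' @param values Numeric vector (or character; empty/NA = missing) of
#'   predictions in record order.
#' @param field Record field to populate (`"test_pred"` or
#'   `"rf_pred"`).
#' @return The records with the field populated and attribute
#'   `n_missing_<field>` recorded.
#' @export
ingest_external_predictions <- function(records, values, field = "test_pred") {
  stopifnot(field %in% c("test_pred", "rf_pred"))
  if (length(values) != nrow(records)) {
    stop("prediction vector length must match record count", call. = FALSE)
  }
  if (!is.numeric(values)) {
    ch <- trimws(as.character(values))
    parsed <- suppressWarnings(as.numeric(ch))
    bad <- which(!is.na(ch) & nzchar(ch) & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("non-numeric prediction '%s' for compound %s (row %d)",
                   ch[bad[1]], records$compound_id[bad[1]], bad[1]),
           call. = FALSE)
    }
    values <- parsed
  }
  records[[field]] <- as.numeric(values)
  n_missing <- sum(is.na(values))
  attr(records, paste0("n_missing_", field)) <- n_missing
  if (n_missing) {
    message(sprintf("ingest_external_predictions: %d compound(s) lack a %s value",
                    n_missing, field))
  }
  records
}
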