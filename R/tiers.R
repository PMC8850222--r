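#' Assemble the regression design for a tier
#'
#' The Tier-0 category distribution is carried into the regression as
#' a four-column additive log-ratio block ([log_ratio_encode()]), so
#' the prior evidence enters the proportional-odds model as ordinary
#' covariates. Tier 1 appends the standardized external-QSAR and
#' random-forest log-LD50 predictions, a four-column log-ratio block
#' for the matched-alert distribution (rows without an alert carry the
#' dataset-prevalence encoding) and an alert-present indicator. Tier 2
#' appends the standardized AC50 with a censoring indicator; compounds
#' without a quantifiable AC50 are imputed at the censor bound rather
#' than dropped. Continuous columns are standardized to zero mean and
#' unit variance with the transform recorded.
#'
#' @param records A `compound_records` data frame.
#' @param tier_id 0, 1 or 2.
#' @param tier0_dists Matrix (n x 5) of Tier-0 distributions; computed
#'   from the Cramer classes when `NULL`.
#' @param alerts An `alert_table` providing alert distributions.
#' @param floor Probability floor for the log-ratio encodings.
#' @param reference Cramer reference distributions for the Tier-0
#'   lookup.
#' @return A list of class `tier_design`: `tier_id`, `design_matrix`,
#'   `column_roles`, `standardization` (per-column mean/sd), `records`.
#' @export
build_tier_design <- function(records, tier_id, tier0_dists = NULL,
                              alerts = default_alerts(), floor = 1e-6,
                              reference = cramer_reference()) {
  stopifnot(tier_id %in% 0:2)
  n <- nrow(records)
  if (is.null(tier0_dists)) {
    tier0_dists <- tier0_distribution(records$cramer_class, reference)
  }
  if (nrow(tier0_dists) != n) {
    stop("Tier-0 distributions must cover every record", call. = FALSE)
  }
  carrier <- t(apply(tier0_dists, 1, log_ratio_encode, floor = floor))
  colnames(carrier) <- paste0("tier0_logratio_", 1:4)
  X <- carrier
  roles <- colnames(carrier)
  std <- list()

  standardize <- function(x, name) {
    m <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s < .Machine$double.eps) s <- 1
    std[[name]] <<- c(mean = m, sd = s)
    (x - m) / s
  }

  if (tier_id >= 1L) {
    need <- c("test_pred", "rf_pred")
    missing_rows <- !stats::complete.cases(records[, need])
    if (any(missing_rows)) {
      stop("records lack mandatory Tier-1 predictors (test_pred/rf_pred): ",
           paste(utils::head(records$compound_id[missing_rows], 5), collapse = ", "),
           if (sum(missing_rows) > 5) " ...", call. = FALSE)
    }
    prevalence_dist <- category_distribution(
      as.numeric(reference_prevalence()) / attr(reference_prevalence(), "total"))
    alert_block <- t(vapply(seq_len(n), function(i) {
      d <- alert_contribution(records$alert_names[[i]], alerts)
      if (is.null(d)) d <- prevalence_dist
      log_ratio_encode(d, floor = floor)
    }, numeric(4)))
    colnames(alert_block) <- paste0("alert_logratio_", 1:4)
    alert_present <- as.numeric(lengths(records$alert_names) > 0)
    X <- cbind(X,
               test_pred = standardize(records$test_pred, "test_pred"),
               rf_pred = standardize(records$rf_pred, "rf_pred"),
               alert_block,
               alert_present = alert_present)
    roles <- colnames(X)
  }

  if (tier_id >= 2L) {
    ac50 <- records$ac50_log
    censored <- records$ac50_censored
    censored[is.na(censored)] <- FALSE
    bound <- suppressWarnings(max(ac50, na.rm = TRUE))
    if (!is.finite(bound)) {
      stop("Tier 2 requested but no record carries an AC50 value", call. = FALSE)
    }
    missing_ac50 <- is.na(ac50)
    ac50[missing_ac50] <- bound
    censored <- censored | missing_ac50
    X <- cbind(X,
               ac50 = standardize(ac50, "ac50"),
               ac50_censored = as.numeric(censored))
    roles <- colnames(X)
  }

  rownames(X) <- records$compound_id
  structure(list(tier_id = as.integer(tier_id), design_matrix = X,
                 column_roles = roles, standardization = std,
                 records = records),
            class = "tier_design")
}

#' Run the tiered assessment
#'
#' Tier 0 assigns each compound the prevalence-scaled category
#' distribution of its Cramer class (a lookup; no model is fitted).
#' Tiers 1 and 2 refit the Bayesian proportional-odds model on their
#' expanding designs, carrying the Tier-0 distribution forward as a
#' covariate block, and emit each compound's posterior-predictive
#' category distribution. Every tier also reports the exclusionary
#' category assignment at each configured threshold.
#'
#' @param records A `compound_records` data frame carrying Cramer
#'   classes, the Tier-1 predictors, the AC50 column (for Tier 2) and
#'   experimental categories (the fitted outcome).
#' @param thresholds Exclusion thresholds (fractions in (0, 0.2]).
#' @param config A [polr_config()] for the Tier-1/2 fits.
#' @param alerts Alert table used for the alert covariate block.
#' @param max_tier Highest tier to run (default 2).
#' @param floor Log-ratio probability floor.
#' @param reference Cramer reference distributions.
#' @return A list of class `tier_run` with one element per tier, each
#'   holding `dist` (n x 5 matrix), `assigned` (n x thresholds integer
#'   matrix) and, for Tiers 1-2, `fit` (the `polr_fit`).
#' @export
run_tiers <- function(records, thresholds = c(0.05, 0.10),
                      config = polr_config(), alerts = default_alerts(),
                      max_tier = 2L, floor = 1e-6,
                      reference = cramer_reference()) {
  stopifnot(max_tier %in% 0:2)
  if (any(thresholds <= 0 | thresholds > 0.2)) {
    stop("exclusion thresholds must lie in (0, 0.2]", call. = FALSE)
  }
  bad_class <- !records$cramer_class %in% names(reference)
  if (any(bad_class)) {
    stop("records without a usable Cramer class: ",
         paste(utils::head(records$compound_id[bad_class], 5), collapse = ", "),
         call. = FALSE)
  }
  assign_all <- function(dist) {
    out <- vapply(thresholds, function(t)
      apply(dist, 1, assign_category_exclusionary, threshold = t),
      integer(nrow(dist)))
    out <- matrix(as.integer(out), nrow = nrow(dist))
    dimnames(out) <- list(records$compound_id,
                          sprintf("assigned_%gpct", 100 * thresholds))
    out
  }

  tier0_dists <- tier0_distribution(records$cramer_class, reference)
  rownames(tier0_dists) <- records$compound_id
  out <- list(tier0 = list(dist = tier0_dists, assigned = assign_all(tier0_dists)))

  if (max_tier >= 1L) {
    y <- records$experimental_category
    if (anyNA(y)) {
      stop("tier models require experimental categories for every record",
           call. = FALSE)
    }
    for (tid in seq_len(max_tier)) {
      design <- build_tier_design(records, tid, tier0_dists = tier0_dists,
                                  alerts = alerts, floor = floor,
                                  reference = reference)
      cfg <- config
      cfg$seed <- config$seed + tid  # distinct chains per tier
      fit <- fit_polr(design, y, cfg)
      out[[paste0("tier", tid)]] <- list(dist = fit$per_compound,
                                         assigned = assign_all(fit$per_compound),
                                         fit = fit)
    }
  }
  structure(c(out, list(thresholds = thresholds)), class = "tier_run")
}

#' Write per-compound tier outputs as a delimited table
#'
#' @param run A `tier_run`.
#' @param tier Tier name ("tier0", "tier1", "tier2").
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tier_table <- function(run, tier, path) {
  stopifnot(inherits(run, "tier_run"), tier %in% setdiff(names(run), "thresholds"))
  el <- run[[tier]]
  out <- data.frame(id = rownames(el$dist),
                    round(100 * el$dist, 1),
                    el$assigned, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
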