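#' Configuration for the synthetic compound-data generator
#'
#' Defaults encode the statistical landscape of the 8186-compound rat
#' acute oral LD50 reference collation: category prevalence from the
#' reference counts (2.7 / 7.8 / 17.7 / 40.6 / 31.2 percent),
#' Cramer-class conditionals implied by the shipped Tier-0 tables,
#' replicate-LD50 noise with a 95 percent half-width of 0.31 log10
#' units, and predictor noise solved analytically so the TEST-like,
#' RF-like and cytotoxicity-like surrogates hit r-squared targets of
#' 0.739, 0.602 and 0.0877 against the observed log LD50.
#'
#' @param n Number of compounds.
#' @param seed Integer seed.
#' @param category_prevalence Five fractions summing to 1.
#' @param r2_targets Named list/vector with `test`, `rf`, `cytotox`
#'   targets in (0, 1).
#' @param replicate_ci_halfwidth 95 percent confidence half-width of
#'   replicate LD50 noise, log10 units (implies the noise SD).
#' @param alert_fraction Share of category-1/2 compounds carrying an
#'   alert-bearing template structure.
#' @param log_ld50_min Lower cap of the Category-1 band, log10 mg/kg.
#' @param log_ld50_max Upper cap of the open Category-5 band, log10
#'   mg/kg (default 4.7, i.e. about 50 g/kg).
#' @param ac50_intercept,ac50_slope Affine map from the latent
#'   cytotoxicity scale to log10 molar AC50.
#' @param ac50_censor_log Assay ceiling on log10 molar AC50; weaker
#'   (larger) values are censored at this bound.
#' @param bounds [category_bounds()] defining the LD50 bands.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n = 1000L, seed = 1L,
                         category_prevalence = as.numeric(reference_prevalence()) /
                           attr(reference_prevalence(), "total"),
                         r2_targets = c(test = 0.739, rf = 0.602, cytotox = 0.0877),
                         replicate_ci_halfwidth = 0.31,
                         alert_fraction = 0.30,
                         log_ld50_min = -1, log_ld50_max = 4.7,
                         ac50_intercept = -5.5, ac50_slope = 0.4,
                         ac50_censor_log = -4.0,
                         bounds = category_bounds()) {
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  if (abs(sum(category_prevalence) - 1) > 1e-9 || any(category_prevalence < 0)) {
    stop("category prevalences must be non-negative and sum to 1", call. = FALSE)
  }
  r2 <- unlist(r2_targets)[c("test", "rf", "cytotox")]
  if (anyNA(r2) || any(r2 <= 0) || any(r2 >= 1)) {
    stop("r-squared targets must be named test/rf/cytotox, each in (0, 1)",
         call. = FALSE)
  }
  stopifnot(replicate_ci_halfwidth > 0, alert_fraction >= 0, alert_fraction <= 1,
            log_ld50_min < log10(bounds$lower_edges[1]),
            log_ld50_max > log10(bounds$lower_edges[4]))
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    category_prevalence = category_prevalence, r2_targets = r2,
    replicate_sd = replicate_ci_halfwidth / stats::qnorm(0.975),
    replicate_ci_halfwidth = replicate_ci_halfwidth,
    alert_fraction = alert_fraction,
    log_ld50_min = log_ld50_min, log_ld50_max = log_ld50_max,
    ac50_intercept = ac50_intercept, ac50_slope = ac50_slope,
    ac50_censor_log = ac50_censor_log, bounds = bounds
  ), class = "synth_config")
}

# log10 band edges of the five categories, including the configured caps
synth_band_edges <- function(config) {
  e <- log10(config$bounds$lower_edges)
  cbind(lower = c(config$log_ld50_min, e),
        upper = c(e, config$log_ld50_max))
}

#' Analytic variance of observed log LD50 under a synthetic config
#'
#' The observed log10 LD50 is uniform within each category band, with
#' bands mixed by the configured prevalence; mean and variance follow
#' in closed form. Used for the analytic predictor-noise calibration.
#'
#' @param config A [synth_config()].
#' @return Named numeric vector `mean`, `var`.
#' @export
synth_log_ld50_moments <- function(config) {
  edges <- synth_band_edges(config)
  p <- config$category_prevalence
  mid <- rowMeans(edges)
  w <- edges[, "upper"] - edges[, "lower"]
  m <- sum(p * mid)
  v <- sum(p * (mid^2 + w^2 / 12)) - m^2
  c(mean = m, var = v)
}

# noise SD such that cor(true + noise, observed)^2 == r2, given that
# true = observed - replicate noise (all noise terms independent)
synth_predictor_sd <- function(config, r2) {
  v_obs <- synth_log_ld50_moments(config)[["var"]]
  v_eps <- config$replicate_sd^2
  tau2 <- v_obs * (1 - r2) / r2 - v_eps
  if (tau2 < 0) {
    stop(sprintf("infeasible r-squared target %.3f given the configured bands and replicate noise",
                 r2), call. = FALSE)
  }
  sqrt(tau2)
}

# template structures assigned to synthetic compounds; alert-bearing
# templates are real exemplars of the alert chemistry, benign templates
# are simple organics matching none of the shipped alerts
synth_templates <- function() {
  data.frame(
    name = c("paraoxon", "carbaryl", "warfarin", "tcdd", "fenazaflor",
             "pindone",
             "ethanol", "butan1ol", "octane", "toluene", "isopropanol",
             "glycerol", "phenol", "acetic_acid", "aniline", "diethyl_ether",
             "ethyl_benzoate", "cyclohexane"),
    smiles = c(
      "O=P(OCC)(OCC)Oc1ccc(cc1)[N+](=O)[O-]",
      "CNC(=O)Oc1cccc2ccccc12",
      "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
      "Clc1cc2Oc3cc(Cl)c(Cl)cc3Oc2cc1Cl",
      "FC(F)(F)c1nc2cc(Cl)c(Cl)cc2n1C(=O)OC1CCCCC1",
      "CC(C)(C)C(=O)C1C(=O)c2ccccc2C1=O",
      "CCO", "CCCCO", "CCCCCCCC", "Cc1ccccc1", "CC(C)O",
      "OCC(O)CO", "Oc1ccccc1", "CC(O)=O", "Nc1ccccc1", "CCOCC",
      "CCOC(=O)c1ccccc1", "C1CCCCC1"),
    has_alert = c(rep(TRUE, 6), rep(FALSE, 12)),
    stringsAsFactors = FALSE
  )
}

#' Generate a calibrated synthetic compound dataset
#'
#' Draws a dataset with the statistical structure the tiered framework
#' assumes, so that every pipeline stage is exercisable without the
#' reference data. Per compound: an acute toxicity category from the
#' configured prevalence; an observed log10 LD50 uniform within that
#' category's band (so labels match [categorize()] exactly); a "true"
#' log LD50 equal to the observed value minus replicate noise of the
#' configured half-width; a Cramer class from the class-given-category
#' conditionals; TEST-like and RF-like predictions equal to the true
#' value plus analytic noise hitting the configured r-squared; a
#' cytotoxicity AC50 on its own scale at its (deliberately weak)
#' r-squared, censored at the assay ceiling; and a template structure,
#' with alert-bearing templates attached to a seeded share of
#' category-1/2 compounds so the substructure-matching path runs.
#'
#' @param config A [synth_config()].
#' @param alerts Alert table used to label the templates' alerts.
#' @return A list of class `synth_dataset`: `records` (a
#'   `compound_records` data frame) and `truth` (per-compound true log
#'   LD50, uncensored AC50 latent, template, drawn category) plus the
#'   calibration constants as attributes.
#' @export
synth_generate <- function(config = synth_config(), alerts = default_alerts()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n
  templates <- synth_templates()
  template_mw <- backend_mol_weight(templates$smiles)
  template_alerts <- match_alerts(templates$smiles, alerts)

  if (n == 0L) {
    rec <- as_compound_records(data.frame(compound_id = character(0),
                                          smiles = character(0)))
    truth <- data.frame(compound_id = character(0), category = integer(0),
                        true_log_ld50 = numeric(0), ac50_latent = numeric(0),
                        template = character(0))
    return(structure(list(records = rec, truth = truth, config = config),
                     class = "synth_dataset"))
  }

  set.seed(config$seed)
  category <- sample.int(5L, n, replace = TRUE, prob = config$category_prevalence)
  edges <- synth_band_edges(config)
  log_obs <- stats::runif(n, edges[category, "lower"], edges[category, "upper"])
  ld50 <- 10^log_obs
  true_log <- log_obs - stats::rnorm(n, 0, config$replicate_sd)

  cond <- cramer_class_given_category()
  cramer <- vapply(category, function(k) {
    sample(rownames(cond), 1L, prob = cond[, k])
  }, character(1))

  tau_test <- synth_predictor_sd(config, config$r2_targets[["test"]])
  tau_rf <- synth_predictor_sd(config, config$r2_targets[["rf"]])
  tau_cyt <- synth_predictor_sd(config, config$r2_targets[["cytotox"]])
  test_pred <- true_log + stats::rnorm(n, 0, tau_test)
  rf_pred <- true_log + stats::rnorm(n, 0, tau_rf)

  mom <- synth_log_ld50_moments(config)
  ac50_latent <- config$ac50_intercept +
    config$ac50_slope * (true_log + stats::rnorm(n, 0, tau_cyt) - mom[["mean"]])
  ac50_censored <- ac50_latent > config$ac50_censor_log
  ac50_log <- ifelse(ac50_censored, config$ac50_censor_log, ac50_latent)

  # template assignment: alert-bearing templates to a share of the two
  # most toxic categories, benign templates elsewhere
  benign <- which(!templates$has_alert)
  alerty <- which(templates$has_alert)
  template_idx <- sample(benign, n, replace = TRUE)
  toxic <- which(category <= 2L)
  n_alert <- round(config$alert_fraction * length(toxic))
  if (n_alert > 0) {
    chosen <- sample(toxic, n_alert)
    template_idx[chosen] <- sample(alerty, n_alert, replace = TRUE)
  }

  rec <- data.frame(
    compound_id = sprintf("SYN%06d", seq_len(n)),
    smiles = templates$smiles[template_idx],
    casrn = NA_character_,
    mol_weight = template_mw[template_idx],
    ld50_mg_kg = ld50,
    cramer_class = cramer,
    test_pred = test_pred,
    rf_pred = rf_pred,
    ac50_log = ac50_log,
    stringsAsFactors = FALSE
  )
  rec$ac50_censored <- ac50_censored
  rec$alert_names <- template_alerts[template_idx]
  rec <- as_compound_records(rec, bounds = config$bounds)

  truth <- data.frame(
    compound_id = rec$compound_id,
    category = category,
    true_log_ld50 = true_log,
    ac50_latent = ac50_latent,
    template = templates$name[template_idx],
    stringsAsFactors = FALSE
  )
  structure(list(records = rec, truth = truth, config = config,
                 calibration = list(tau_test = tau_test, tau_rf = tau_rf,
                                    tau_cytotox = tau_cyt,
                                    log_ld50_moments = mom)),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("Synthetic compound dataset: n = %d (seed %d)\n",
              nrow(x$records), x$config$seed))
  if (nrow(x$records)) {
    tab <- table(factor(x$records$experimental_category, levels = 1:5))
    cat("  category counts:", paste(tab, collapse = " / "), "\n")
    cat(sprintf("  alerts attached: %d compound(s)\n",
                sum(lengths(x$records$alert_names) > 0)))
  }
  invisible(x)
}

#' Draw a balanced evaluation subset
#'
#' Selects `n_per_category` eligible compounds per acute toxicity
#' category. Eligibility requires a usable Cramer class, both log-LD50
#' predictions, and an AC50 value (censored counts as present). A
#' shortfall in a category cascades to the next (less toxic) category,
#' mirroring the reference procedure in which only six eligible
#' Category-1 substances forced four extra Category-2 draws.
#'
#' @param records A `compound_records` data frame.
#' @param n_per_category Target draws per category (default 10).
#' @param seed Integer seed for the draw.
#' @return The selected records, with attribute `selection_counts`.
#' @export
make_balanced_eval_set <- function(records, n_per_category = 10L, seed = 1L) {
  eligible <- records$cramer_class %in% c("I", "II", "III") &
    !is.na(records$test_pred) & !is.na(records$rf_pred) &
    !is.na(records$ac50_log) & !is.na(records$experimental_category)
  pool <- records[eligible, , drop = FALSE]
  target_total <- 5L * as.integer(n_per_category)
  if (nrow(pool) < target_total) {
    stop(sprintf("only %d eligible compounds for a %d-compound balanced set",
                 nrow(pool), target_total), call. = FALSE)
  }
  set.seed(seed)
  take <- integer(0)
  counts <- integer(5)
  carry <- 0L
  for (k in 1:5) {
    want <- as.integer(n_per_category) + carry
    idx <- which(pool$experimental_category == k)
    got <- min(length(idx), want)
    if (got > 0) take <- c(take, sample(idx, got))
    counts[k] <- got
    carry <- want - got
  }
  if (carry > 0L) {
    stop(sprintf("shortfall of %d compound(s) remains after cascading through Category 5",
                 carry), call. = FALSE)
  }
  out <- pool[sort(take), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "selection_counts") <- stats::setNames(counts, paste0("cat", 1:5))
  out
}

#' Write a synthetic dataset to compound + truth tables
#'
#' @param dataset A `synth_dataset`.
#' @param compound_path,truth_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_synth_dataset <- function(dataset, compound_path, truth_path) {
  stopifnot(inherits(dataset, "synth_dataset"))
  write_compound_table(dataset$records, compound_path)
  utils::write.csv(dataset$truth, truth_path, row.names = FALSE)
  invisible(c(compound_path, truth_path))
}
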