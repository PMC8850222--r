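#' Manually estimated distribution for rare structural alerts
#'
#' Alerts occurring in fewer than ten reference compounds carry a
#' manually estimated category distribution instead of a calculated
#' one: 90 percent in Category 1, 10 percent in Category 4, zero
#' elsewhere.
#'
#' @return A [category_distribution()] of (0.9, 0, 0, 0.1, 0).
#' @export
rare_alert_distribution <- function() {
  category_distribution(c(0.90, 0, 0, 0.10, 0))
}

#' Minimum coverage for the calculated alert-distribution route
#' @keywords internal
ALERT_MIN_COVERAGE <- 10L

#' Prevalence-scaled distribution for a structural alert
#'
#' For alerts with sufficient coverage (at least ten matching
#' compounds), the category distribution is calculated by
#' prevalence-scaling the raw match counts exactly as for the Tier-0
#' class distributions.
#'
#' @param matches [category_counts()] of alert-matching compounds by
#'   experimental category.
#' @param prevalence Reference-set [category_counts()].
#' @return A [category_distribution()].
#' @export
derive_alert_distribution <- function(matches, prevalence = reference_prevalence()) {
  matches <- category_counts(matches)
  if (attr(matches, "total") < ALERT_MIN_COVERAGE) {
    stop(sprintf("alert coverage %d is below %d; use rare_alert_distribution()",
                 attr(matches, "total"), ALERT_MIN_COVERAGE), call. = FALSE)
  }
  scale_distribution(matches, prevalence)
}

#' Default structural alert table
#'
#' The thirteen shipped alerts flag substructures over-represented in
#' the two most toxic categories: acetylcholinesterase-inhibiting
#' organophosphates and carbamates, fenazaflor-like fluoromethyl
#' benzimidazoles (oxidative-phosphorylation uncouplers), warfarin-like
#' 4-hydroxycoumarin vitamin-K antagonists and dibenzodioxins carry
#' calculated, prevalence-scaled distributions derived from the
#' 8186-compound reference set; the eight sparse alerts (aflatoxin,
#' ochratoxin, saxitoxin, strychnine, trichothecene, vitamin-D
#' secosteroid, bromethalin-like and indandione scaffolds, each present
#' in fewer than ten reference compounds) carry the manually estimated
#' [rare_alert_distribution()].
#'
#' The published alert set depicts its fragments graphically without
#' machine-readable patterns; the SMARTS shipped here are authored
#' approximations of those fragments and are fully overridable through
#' [read_alert_table()].
#'
#' @return A data frame of class `alert_table` with columns `name`,
#'   `smarts`, `cat1..cat5` (fractions), `coverage` (NA where the
#'   exact count is not published), `is_estimated`.
#' @export
default_alerts <- function() {
  calc <- data.frame(
    name = c("organophosphate", "carbamate", "fluoromethyl_benzimidazole",
             "vitamin_k_antagonist", "dibenzodioxin"),
    smarts = c(
      "[PX4](=[OX1])([OX2])([OX2])[OX2]",
      "[NX3][CX3](=[OX1])[OX2]",
      "FC(F)c1nc2ccccc2n1",
      "[OX2H]c1cc(=O)oc2ccccc12",
      "c1ccc2c(c1)Oc1ccccc1O2"),
    stringsAsFactors = FALSE
  )
  calc_dist <- rbind(
    c(41.8, 33.9, 16.7, 4.6, 3.1),
    c(31.5, 40.0, 16.4, 8.3, 4.2),
    c(51.6, 41.3, 7.0, 0.0, 0.0),
    c(84.4, 5.8, 7.6, 2.2, 0.0),
    c(96.3, 3.7, 0.0, 0.0, 0.0)) / 100
  calc_cov <- c(730L, 327L, 128L, 11L, 10L)

  rare <- data.frame(
    name = c("aflatoxin", "ochratoxin", "saxitoxin", "strychnine",
             "trichothecene", "vitamin_d_secosteroid", "bromethalin_like",
             "indandione"),
    smarts = c(
      "C1=CC2OC3Oc4ccccc4C3C2O1",
      "O=C1OC(C)Cc2ccccc12",
      "NC1=NC2NC(=N)NC2C1",
      "O=C1CC2OCC=C3CN4CCC5(c6ccccc6N1C25)C34",
      "CC1CC2(CO2)C(C1)O",
      "C(=C)C1CCCC(C1)O",
      "CN(c1ccccc1)c1ccccc1",
      "O=C1c2ccccc2C(=O)C1"),
    stringsAsFactors = FALSE
  )
  rd <- rare_alert_distribution()
  dist <- rbind(calc_dist, matrix(rep(rd, nrow(rare)), ncol = 5, byrow = TRUE))
  out <- rbind(calc, rare)
  colnames(dist) <- paste0("cat", 1:5)
  out <- cbind(out, as.data.frame(dist))
  out$coverage <- c(calc_cov, rep(NA_integer_, nrow(rare)))
  out$is_estimated <- c(rep(FALSE, nrow(calc)), rep(TRUE, nrow(rare)))
  validate_alert_table(out)
}

validate_alert_table <- function(tab) {
  need <- c("name", "smarts", paste0("cat", 1:5), "coverage", "is_estimated")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("alert table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$name)) stop("duplicated alert names", call. = FALSE)
  probs <- as.matrix(tab[, paste0("cat", 1:5)])
  rd <- rare_alert_distribution()
  for (i in seq_len(nrow(tab))) {
    # published rows are printed to 1 d.p. and can sum slightly off 100;
    # renormalize within a 2% slack, reject anything further out
    s <- sum(probs[i, ])
    if (abs(s - 1) > 0.02) {
      stop(sprintf("alert '%s' probabilities sum to %.4f", tab$name[i], s),
           call. = FALSE)
    }
    tab[i, paste0("cat", 1:5)] <- probs[i, ] / s
    d <- category_distribution(probs[i, ] / s)
    if (isTRUE(tab$is_estimated[i]) && any(abs(d - rd) > 1e-9)) {
      stop(sprintf("alert '%s' flagged estimated but its distribution is not the rare-alert rule",
                   tab$name[i]), call. = FALSE)
    }
    if (!isTRUE(tab$is_estimated[i])) {
      cov <- tab$coverage[i]
      if (is.na(cov) || cov < ALERT_MIN_COVERAGE) {
        stop(sprintf("alert '%s' uses the calculated route but coverage is below %d",
                     tab$name[i], ALERT_MIN_COVERAGE), call. = FALSE)
      }
    }
  }
  class(tab) <- unique(c("alert_table", class(tab)))
  tab
}

#' Read an alert-definition table
#'
#' Comma-delimited with header columns `name`, `smarts`,
#' `cat1..cat5` (percent), `coverage`, `is_estimated`.
#'
#' @param path File path.
#' @return An `alert_table` data frame (probabilities as fractions).
#' @export
read_alert_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (k in paste0("cat", 1:5)) tab[[k]] <- tab[[k]] / 100
  tab$is_estimated <- as.logical(tab$is_estimated)
  tab$coverage <- suppressWarnings(as.integer(tab$coverage))
  validate_alert_table(tab)
}

#' Match structural alerts against SMILES
#'
#' Substructure matching is delegated to the OpenBabel SMARTS backend.
#' Unparseable structures are flagged (attribute `failed`) and return
#' no matches.
#'
#' @param smiles Character vector of SMILES strings.
#' @param alerts An `alert_table` (default [default_alerts()]).
#' @return A list (one element per input) of character vectors of
#'   matching alert names, with attribute `failed` marking inputs whose
#'   structure did not parse.
#' @export
match_alerts <- function(smiles, alerts = default_alerts()) {
  alerts <- validate_alert_table(as.data.frame(alerts))
  n <- length(smiles)
  out <- rep(list(character(0)), n)
  ok <- smiles_parseable(smiles)
  if (any(ok)) {
    sdf <- suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(smiles[ok], sprintf("q%06d", which(ok))))
    )
    hit <- matrix(FALSE, sum(ok), nrow(alerts))
    for (j in seq_len(nrow(alerts))) {
      counts <- tryCatch(
        as.numeric(ChemmineR::smartsSearchOB(sdf, alerts$smarts[j])),
        error = function(e) stop(sprintf("SMARTS for alert '%s' failed: %s",
                                         alerts$name[j], conditionMessage(e)),
                                 call. = FALSE)
      )
      hit[, j] <- counts > 0
    }
    idx <- which(ok)
    for (i in seq_along(idx)) {
      out[[idx[i]]] <- alerts$name[hit[i, ]]
    }
  }
  attr(out, "failed") <- !ok
  out
}

#' Category distribution contributed by a compound's matched alerts
#'
#' A compound matching several alerts contributes the distribution of
#' the alert with the lowest [expected_severity()] — the most
#' conservative choice, in keeping with the framework's deliberate
#' protective bias.
#'
#' @param alert_names Character vector of matched alert names (possibly
#'   empty).
#' @param alerts An `alert_table`.
#' @return A [category_distribution()], or `NULL` if no alert matched.
#' @export
alert_contribution <- function(alert_names, alerts = default_alerts()) {
  if (!length(alert_names)) return(NULL)
  idx <- match(alert_names, alerts$name)
  if (anyNA(idx)) {
    stop("unknown alert name(s): ",
         paste(alert_names[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  dists <- lapply(idx, function(i)
    category_distribution(as.numeric(alerts[i, paste0("cat", 1:5)]), tol = 1e-6))
  sev <- vapply(dists, expected_severity, numeric(1))
  d <- dists[[which.min(sev)]]
  category_distribution(d / sum(d))
}
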