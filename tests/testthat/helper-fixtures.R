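# shared fixtures built in code at test time

# minimal record table (valid structures, no chemistry needed beyond parsing)
make_record_df <- function(n = 5, smiles = "CCO") {
  data.frame(
    compound_id = sprintf("CMP%03d", seq_len(n)),
    smiles = rep_len(smiles, n),
    mol_weight = rep(46.07, n),
    ld50_mg_kg = seq(10, 10 * n, by = 10),
    cramer_class = rep_len(c("I", "II", "III"), n),
    stringsAsFactors = FALSE
  )
}

# records with every predictor populated, for design/eligibility tests
make_full_records <- function(n = 20, seed = 1) {
  set.seed(seed)
  df <- make_record_df(n)
  df$ld50_mg_kg <- 10^stats::runif(n, -0.5, 4)
  df$test_pred <- log10(df$ld50_mg_kg) + stats::rnorm(n, 0, 0.4)
  df$rf_pred <- log10(df$ld50_mg_kg) + stats::rnorm(n, 0, 0.6)
  df$ac50_log <- -5 + 0.3 * scale(log10(df$ld50_mg_kg))[, 1] + stats::rnorm(n, 0, 1)
  df$ac50_censored <- FALSE
  as_compound_records(df)
}

# independent arithmetic for the prevalence-scaling rule, used as the
# oracle against scale_distribution
oracle_scale <- function(raw, prev) {
  r <- (raw / sum(raw)) / (prev / sum(prev))
  r[raw == 0] <- 0
  r / sum(r)
}

# independent arithmetic for the proportional-odds category
# probabilities (plain logistic evaluation, no package code)
oracle_polr_probs <- function(eta, cuts) {
  cum <- 1 / (1 + exp(-(cuts - eta)))
  c(cum[1], diff(cum), 1 - cum[4])
}

# brute-force oracle for the exclusionary rule: smallest index whose
# probability clears the threshold
oracle_exclusionary <- function(p, t) {
  min(which(p >= t))
}

quiet_fit <- function(...) {
  withCallingHandlers(fit_polr(...),
                      warning = function(w) invokeRestart("muffleWarning"))
}
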