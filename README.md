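# toxtiers

Tiered Bayesian prediction of rat acute oral toxicity categories from
chemical structure and surrogate (non-animal) data.

Regulatory acute toxicity classification bins the rat oral LD50 into
five ordered bands (EU CLP categories, extended with a low-concern
Category 5 for LD50 ≥ 2000 mg/kg; Category 1, LD50 < 5 mg/kg, is the
most severe). `toxtiers` is for toxicologists and risk assessors who
want a *probabilistic* category call assembled from cheap evidence in
stages, with the animal test kept only as a hypothetical last resort:

* **Tier 0 — structural class prior.** A compound's Cramer class is
  converted into a five-category probability distribution by
  *prevalence scaling* against an 8186-compound reference collation:
  the class's raw category share is divided by the dataset-wide share
  of that category and renormalized, correcting for the reference
  set's strong imbalance.
* **Tier 1 — in silico update.** A Bayesian proportional-odds
  logistic regression (POLR) updates the Tier-0 distribution with an
  external QSAR LD50 prediction, an in-package random-forest LD50
  prediction, and matched structural alerts (13 shipped SMARTS
  patterns with prevalence-scaled or manually estimated category
  distributions). The model: latent severity η_i = X_i β with
  P(y ≤ k) = logistic(c_k − η_i), ordered cut-points c_1 < … < c_4,
  Laplace(μ, σ) priors on β (hyperparameters estimated), Normal(0, 20)
  priors on cut-points.
* **Tier 2 — in vitro update.** The design is expanded with a
  cytotoxicity AC50 column (censored at the assay ceiling) and the
  model refitted.
* **Attribution.** Each tier's per-compound distribution becomes a
  single category by the *exclusionary method*: discard categories
  below a 5% or 10% probability threshold and assign the most
  hazardous survivor — a deliberately conservative rule.

A calibrated synthetic-data generator reproduces the statistical
landscape the framework assumes (category prevalences, Cramer
conditionals, predictor correlations r² = 0.739 / 0.602 / 0.0877,
replicate-LD50 noise of ±0.31 log10 units), so the whole pipeline is
testable without any external dataset.

## Worked example

```r
library(toxtiers)

# Tier-0 prior for a Cramer Class III compound, attributed at 10%
ref <- cramer_reference()
round(100 * ref$III, 1)
#> cat1 cat2 cat3 cat4 cat5
#> 21.9 21.6 20.9 19.7 16.0
assign_category_exclusionary(ref$III, 0.10)
#> [1] 1
```

Every probability in the flat Class III row clears the 10% threshold,
so the most hazardous surviving category — Category 1 — is assigned:
the Tier-0 prior is conservative by design.

```r
# a calibrated synthetic dataset and a balanced 50-compound subset
ds  <- synth_generate(synth_config(n = 2000, seed = 42))
bal <- make_balanced_eval_set(ds$records, n_per_category = 10, seed = 7)
run <- run_tiers(bal, config = polr_config(seed = 3))

for (tier in c("tier0", "tier1", "tier2")) {
  r <- build_report(bal$experimental_category, run[[tier]]$assigned[, 2])
  cat(sprintf("%s: %2d correct, %2d over, %2d under\n",
              tier, r$n_correct, r$n_over, r$n_under))
}
#> tier0: 11 correct, 39 over,  0 under
#> tier1: 19 correct, 29 over,  2 under
#> tier2: 22 correct, 28 over,  0 under
```

At the 10% threshold, Tier 0 assigns almost everything to Category 1
(39 of 50 compounds overpredicted). Folding in the in-silico evidence
nearly doubles the correct assignments and cuts the overprediction
count by a quarter, while the weakly informative cytotoxicity tier
shifts the picture only slightly — the qualitative pattern
the tiered design is meant to show. Each tier also exposes the full
per-compound posterior distributions (`run$tier1$dist`) and sampler
diagnostics (`run$tier1$fit$diagnostics`).

A thin command-line interface wraps the same functions:

```sh
inst/cli/toxtiers synth --n 500 --seed 7 --out-dir data/
inst/cli/toxtiers run --compounds data/synthetic_compounds.csv --out-dir out/
```

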