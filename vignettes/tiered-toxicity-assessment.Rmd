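---
title: "Tiered Bayesian assessment of acute oral toxicity categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered Bayesian assessment of acute oral toxicity categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`toxtiers` implements a probabilistic, tiered strategy for assigning rat
acute oral toxicity categories from non-animal evidence. This vignette
is the package's own account of the underlying model, the choices that
were genuinely open, and what the shipped synthetic data can and cannot
establish.

## The categorical scheme

Acute oral toxicity is expressed as an ordinal category 1–5 derived
from the rat LD50 (mg/kg body weight), mirroring the EU CLP bands with
an appended low-concern Category 5:

| Category | LD50 (mg/kg bw) |
|---|---|
| 1 | < 5 |
| 2 | 5–49 |
| 3 | 50–299 |
| 4 | 300–1999 |
| 5 | ≥ 2000 |

Category 1 is the most toxic. The printed integer band ends are
implemented as half-open intervals `[5, 50)`, `[50, 300)`,
`[300, 2000)`: a non-integer LD50 of 49.7 mg/kg then falls in exactly
one band, and an LD50 exactly at a cut belongs to the less toxic side
(`categorize(50)` is 3). All "more severe" comparisons in the package
mean *numerically smaller* category.

## Tier 0: prevalence-scaled Cramer class distributions

The Cramer scheme sorts structures into three classes of escalating
structural concern. Within a large reference collation (8186 curated
rat LD50 records), each class has an observed category composition;
raw shares are however dominated by the dataset's strong imbalance
(40.6% of all compounds sit in Category 4, 2.7% in Category 1). The
Tier-0 prior therefore uses *prevalence scaling*: each class's raw
category share is divided by the dataset-wide share of that category,

$$ r_k = \frac{\text{raw}_k/\sum_j \text{raw}_j}
              {\text{prev}_k/\sum_j \text{prev}_j}, $$

and the enrichment ratios $r_k$ are renormalized to sum to one. Two
numerical choices matter:

* **Exact counts, not printed percentages.** Scaling the rounded
  percentages shifts third digits (Class III / Category 1 becomes
  21.8% instead of 21.9%); `scale_distribution()` therefore takes
  count vectors.
* **Renormalization.** The enrichment ratios do not naturally sum to
  one; renormalizing reproduces the published class rows and keeps
  `CategoryDistribution` a proper probability vector.

The shipped Class III row is recomputed from its public raw counts;
the Class I and II rows are stored as published (their raw counts are
not public at full precision) and renormalized from the 1-d.p. print,
which can move a cell by up to 0.1 percentage point.

## Exclusionary category attribution

A category distribution is turned into a single decision by excluding
every category whose probability falls below a threshold (5% or 10%)
and assigning the *most hazardous surviving* category. The rule is
deliberately conservative: overprediction of hazard is preferred to
underprediction in a risk-assessment setting.

A probability exactly at the threshold **survives**. The published
worked examples never exercise exact equality, but the Class I row
(Category 3 at 10.2%) must survive a 10% threshold while 9.0% must
not; `p >= t` is the only convention consistent with both, and it
keeps thresholds in `(0, 0.2]` guaranteed to leave a survivor (five
probabilities cannot all be below 0.2).

## Structural alerts

Thirteen alerts flag chemistry over-represented in Categories 1–2:
organophosphates and carbamates (acetylcholinesterase inhibition),
fenazaflor-like fluoromethyl-benzimidazoles, warfarin-like
4-hydroxycoumarins, dibenzodioxins, and eight sparse classes
(aflatoxins, ochratoxins, saxitoxins, strychnine, trichothecenes,
vitamin-D secosteroids, bromethalin-like compounds, indandiones).
Alerts seen in at least ten reference compounds carry a distribution
calculated by the same prevalence scaling as Tier 0 (exactly ten uses
the calculated route); sparser alerts carry the manual estimate
90/0/0/10/0 over Categories 1–5.

The reference alert set depicts its fragments graphically. The SMARTS
patterns shipped in `default_alerts()` are **authored
approximations** of that chemistry, validated against exemplar
molecules (paraoxon, carbaryl, warfarin, TCDD, fenazaflor, pindone)
and fully overridable through `read_alert_table()`. A compound
matching several alerts contributes the distribution of the alert
with the lowest expected severity — the most conservative choice; the
source procedure is silent on ties, and conservatism is the
framework's stated direction.

## The Bayesian proportional-odds engine

Tiers 1 and 2 update the Tier-0 picture through a proportional-odds
logistic regression (POLR). Each compound has a latent severity
$\eta_i = X_i\beta$; ordered cut-points $c_1 < \dots < c_4$ partition
it into the five categories via

$$ P(y_i \le k) = \mathrm{logit}^{-1}(c_k - \eta_i). $$

**Orientation.** Larger $\eta$ means *less* toxic (mass toward higher
categories), so log-LD50-scale predictors are expected to enter with
positive coefficients. The source fixes no convention; this one makes
every predictor's expected sign positive.

**Priors.** Coefficients are exchangeable Laplace$(\mu, \sigma)$
(parameterized by mean and *standard deviation*, so the scale is
$\sigma/\sqrt2$), inducing sparsity-friendly shrinkage; cut-points are
Normal(0, 20). The hyperprior forms are not reproduced in the source;
the package uses $\mu \sim$ Normal(0, 1) and $\sigma \sim$
half-Normal(0, 1), both configurable in `polr_config()`.

**Tier chaining.** The Tier-0 distribution is carried into the design
as a 4-column additive log-ratio block, $\log(p_k/p_5)$ after
flooring at $10^{-6}$ and renormalizing. This preserves the full
distribution, keeps every tier a single POLR fit, and makes Tier
designs strictly nested: Tier 1 appends standardized external-QSAR
and random-forest log-LD50 predictions, a matched-alert log-ratio
block (rows without an alert carry the dataset-prevalence encoding
and an indicator 0), and Tier 2 appends standardized AC50 with a
censoring indicator. Whether the source refits a joint model at Tier
2 or sequentially updates the Tier-1 posterior is not stated;
*refitting with an expanded design* was chosen as the reproducible
reading, and it makes the tier designs literally nested. Compounds
without a quantifiable AC50 (assay inactive) are imputed at the
censor bound with the indicator set, rather than dropped — the
eligibility filter has already run, and within-model censoring
retains the remaining information.

**Sampling.** The posterior is explored by a componentwise
stepping-out slice sampler (compiled; deterministic given the seed,
chain $c$ seeded at `seed*1000 + c`). Two geometric refinements
matter because the carrier blocks are collinear by construction (a
4-column log-ratio block over three distinct Cramer rows has rank at
most 3):

1. every sweep also slices along the SVD-whitened axes of the
   column-centered design, each with a compensating $c_1$ component
   (adding a constant to every $\eta$ trades off exactly against the
   cut-points);
2. a short pilot run estimates the posterior covariance in the
   unconstrained parameterization, and its scaled eigen-directions
   are added to the direction set before any kept draw — this lets
   sweeps traverse the coefficient-magnitude/cut-point-spread ridge
   that appears under quasi-separation.

Cut-point ordering is enforced by an ordered parameterization
($c_1$ plus log-increments), not rejection. Every fit records
split-$\hat R$ for all parameters and is rejected above 1.01 (a
classed error by default; demotable to a warning). Slice sampling has
no divergence mechanism, so the divergence count in the diagnostics
is identically zero. The default *test profile* runs 4 chains of
2,000 kept draws after 1,000 warmup sweeps — enough to clear the 1.01
bound on the collinear tier designs in a few seconds per fit; the
*full profile* (`profile = "full"`) runs 4 × 10,000 for final
inference. Posterior-predictive category distributions are the exact
average of the closed-form probabilities over the kept draws.

## The synthetic study design

`synth_generate()` emulates the statistical landscape the framework
assumes, so the whole pipeline is testable without the reference
data:

* **Categories** are drawn from the reference prevalence
  (2.7/7.8/17.7/40.6/31.2%).
* **Observed log LD50** is uniform within the drawn category's log
  band; the open bands are capped at 0.1 mg/kg below and
  $10^{4.7}$ mg/kg (≈50 g/kg) above — a plausible physical ceiling,
  configurable. The generator draws the *observed* value inside the
  band and derives the "true" value by subtracting replicate noise,
  rather than the reverse: with noise added on top of a
  band-uniform true value, boundary crossings would drain roughly
  three percentage points out of Category 4 and the label shares
  could not match the reference prevalence. With this construction
  the label equals `categorize(observed)` exactly *and* the shares
  match by construction.
* **Replicate noise** is Normal with a 95% half-width of 0.31 log10
  units (SD 0.158), matching the reported replicate variability of
  the underlying LD50 data.
* **Surrogate predictors** equal the true log LD50 plus Normal noise
  whose variance is solved analytically from the target squared
  correlation: with $v$ the analytic variance of observed log LD50
  (a mixture of uniforms; `synth_log_ld50_moments()`) and $v_\epsilon$
  the replicate-noise variance,
  $\tau^2 = v(1-r^2)/r^2 - v_\epsilon$. Targets default to the
  reported $r^2$ of 0.739 (external QSAR), 0.602 (random forest) and
  0.0877 (cytotoxicity). Infeasible targets raise a configuration
  error rather than silently truncating. Predictions are emitted on
  the same log10 mg/kg scale as the observed LD50 so the calibration
  is exact; the tier designs standardize columns, so this affine
  choice cannot affect the model.
* **AC50** is an affine map of the cytotoxicity-calibrated latent to
  the log10 molar scale, censored at an assay ceiling of $10^{-4}$ M;
  censored records keep the bound plus a flag, and the uncensored
  latent is stored in the truth table (calibration is checked against
  the latent, since censoring would bias the measured correlation).
* **Cramer classes** are drawn from class-given-category conditionals
  obtained by inverting the shipped scaled class rows against the
  prevalence counts; the public Class III raw counts confirm the
  inversion.
* **Structures** are a small panel of template molecules: six real
  alert exemplars attached to a configurable share (default 30%) of
  Category-1/2 compounds, and twelve benign organics elsewhere. They
  exist so the substructure-matching and fingerprint code paths
  genuinely execute.

What the generator does **not** emulate: real chemical-space
topology, descriptor covariance, assay-specific noise structure, or
any relationship between a template structure and its LD50. Passing
tests on synthetic data therefore demonstrate that the machinery is
correct and that the tier logic behaves as designed *under the
assumed statistical conditions* — not that the framework attains any
particular accuracy on new chemistry.

The balanced evaluation subset mirrors the reference procedure: ten
eligible compounds per category (eligibility = usable Cramer class,
both LD50 predictions, an AC50 value), with any shortfall in a
category cascading to the next less toxic one — exactly the published
situation of six Category-1 compounds topped up by four extra
Category-2 draws. A shortfall remaining after Category 5 is an error.

## Evaluation conventions

Confusion matrices put experimental categories on rows and predicted
on columns. *Overprediction* means predicted more toxic (column index
below row index); deviation is experimental − predicted, so positive
deviations are overpredictions. The LD50-variability switch analysis
multiplies each LD50 by $10^{\pm\delta}$ (default $\delta = 0.31$)
and reports the percentage of compounds whose category changes in
each direction; percentages print as integers there and to one
decimal elsewhere.

## Random forest LD50 model

The in-package surrogate QSAR is a 500-tree random forest over binary
substructure-key fingerprints (bits present in fewer than 5% or more
than 95% of compounds are excluded; the bounds themselves are
retained) concatenated with a numeric descriptor block. The reference
model used a commercial descriptor package; `build_feature_matrix()`
computes an open descriptor set from the structure backend by default
and accepts any user-supplied numeric table. Reported performance is
strictly out-of-fold under seeded 10-fold cross-validation — each
compound's prediction comes from a forest that never saw it — and the
retained-bit count is dataset-specific, so no particular number of
bits is asserted.

## Problem sizes used by the test suite

The shipped tests exercise the pipeline at sizes chosen to make the
statistical checks sharp while staying quick: generator calibration
at n = 8186 (prevalence) and n = 2000 (correlations, noise width);
parameter recovery over 20 replicates of n = 500 with known
coefficients; the tier-improvement property over five seeds of
n = 2000 with a 50-compound balanced subset. The recovery replicates
use 1,000 kept draws per chain — the two-column designs involved are
well-conditioned, and coverage is a tail-insensitive summary.

## Known limitations

* The shipped SMARTS are approximations; distributions attached to
  them are only as good as the patterns' fidelity to the original
  fragment definitions.
* Tier 2's value is bounded by its input: with cytotoxicity at
  $r^2 \approx 0.09$ the model correctly learns to nearly ignore it,
  which is the designed behaviour, not a deficiency of the sampler.
* The framework is categorical end to end; no continuous LD50
  posterior is produced.
* Reference confusion matrices for Tiers 1–2 depend on the original
  50-compound subset, proprietary descriptors and external tool
  outputs, and are not reproducible from a desk; the package instead
  asserts the qualitative tier-improvement property on calibrated
  synthetic data.
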