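#' Proportional-odds category probabilities
#'
#' Closed form of the ordinal logistic link: with latent severity
#' `eta` and ordered cut-points `c1 < c2 < c3 < c4`,
#' `P(category <= k) = logistic(c_k - eta)` and the five category
#' probabilities are successive differences. Orientation: larger `eta`
#' pushes probability mass toward higher-numbered (less toxic)
#' categories, so predictors on the log-LD50 scale are expected to
#' enter with positive coefficients.
#'
#' @param eta Numeric vector of latent severities.
#' @param cutpoints Strictly increasing numeric vector of four
#'   cut-points.
#' @return A matrix (length(eta) x 5) of category probabilities; each
#'   row sums to 1.
#' @examples
#' polr_category_probs(0, c(0, 1, 2, 3))
#' @export
polr_category_probs <- function(eta, cutpoints) {
  if (length(cutpoints) != 4L || anyNA(cutpoints) || any(diff(cutpoints) <= 0)) {
    stop("`cutpoints` must be four strictly increasing values", call. = FALSE)
  }
  if (!is.numeric(eta) || anyNA(eta)) {
    stop("`eta` must be numeric and non-missing", call. = FALSE)
  }
  cum <- stats::plogis(outer(eta, cutpoints, function(e, c) c - e))
  probs <- cbind(cum[, 1],
                 cum[, 2] - cum[, 1],
                 cum[, 3] - cum[, 2],
                 cum[, 4] - cum[, 3],
                 1 - cum[, 4])
  colnames(probs) <- paste0("cat", 1:5)
  probs
}

#' Sampler and prior configuration for the tier models
#'
#' Defaults follow the test profile (4 chains of 2,000 kept draws
#' after 1,000 warmup sweeps — enough for split-R-hat below 1.01 on
#' the collinear tier designs); the heavier production profile used
#' for final inference (4 chains of 10,000) is selected with
#' `profile = "full"`. Priors: Laplace(mu, sd = sigma) on regression
#' coefficients with hyperpriors mu ~ Normal(0, 1) and
#' sigma ~ half-Normal(0, 1); Normal(0, 20) on each cut-point.
#'
#' @param chains Number of chains.
#' @param iter Kept draws per chain.
#' @param warmup Warmup sweeps per chain (discarded).
#' @param seed Integer seed; chain c uses `seed + c` offsets.
#' @param cut_prior_sd,mu_prior_sd,sigma_prior_sd Prior scales.
#' @param rhat_max Convergence bound on split-R-hat (fit is rejected
#'   above it).
#' @param on_diagnostic_failure `"error"` (default) or `"warning"`.
#' @param profile `"test"` or `"full"` preset for chains/iter.
#' @return A list of class `polr_config`.
#' @export
polr_config <- function(chains = 4L, iter = 2000L, warmup = 1000L,
                        seed = 1L, cut_prior_sd = 20, mu_prior_sd = 1,
                        sigma_prior_sd = 1, rhat_max = 1.01,
                        on_diagnostic_failure = c("error", "warning"),
                        profile = c("test", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    chains <- 4L; iter <- 10000L; warmup <- 2000L
  }
  stopifnot(chains >= 1L, iter >= 10L, warmup >= 0L, cut_prior_sd > 0,
            mu_prior_sd > 0, sigma_prior_sd > 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 cut_prior_sd = cut_prior_sd, mu_prior_sd = mu_prior_sd,
                 sigma_prior_sd = sigma_prior_sd, rhat_max = rhat_max,
                 on_diagnostic_failure = match.arg(on_diagnostic_failure),
                 profile = profile),
            class = "polr_config")
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction computed after splitting each chain in
#' half, flagging both between-chain disagreement and within-chain
#' trend.
#'
#' @param draws A list of matrices (one per chain, iterations x
#'   parameters) with identical dimensions.
#' @return Named numeric vector of split-R-hat values per parameter.
#' @export
split_rhat <- function(draws) {
  stopifnot(is.list(draws), length(draws) >= 1L)
  half <- floor(nrow(draws[[1]]) / 2)
  pieces <- list()
  for (ch in draws) {
    pieces <- c(pieces, list(ch[seq_len(half), , drop = FALSE],
                             ch[half + seq_len(half), , drop = FALSE]))
  }
  m <- length(pieces)
  n <- half
  vapply(seq_len(ncol(draws[[1]])), function(j) {
    x <- vapply(pieces, function(p) mean(p[, j]), numeric(1))
    s2 <- vapply(pieces, function(p) stats::var(p[, j]), numeric(1))
    W <- mean(s2)
    B <- n * stats::var(x)
    if (W < .Machine$double.eps) return(1.0)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1), USE.NAMES = FALSE) -> rh
  stats::setNames(rh, colnames(draws[[1]]))
}

#' Fit the Bayesian proportional-odds tier model
#'
#' Samples the posterior of the proportional-odds logistic regression
#' with Laplace coefficient priors by a componentwise slice sampler
#' (deterministic under the configured seed), checks split-R-hat for
#' every parameter, and computes each compound's posterior-predictive
#' category distribution by averaging [polr_category_probs()] over the
#' kept draws.
#'
#' @param design Numeric design matrix (compounds x columns), or a
#'   `tier_design` from [build_tier_design()].
#' @param outcome Integer vector of observed categories 1..5; at least
#'   two distinct values are required.
#' @param config A [polr_config()].
#' @return An object of class `polr_fit`: `draws` (combined matrix),
#'   `chain_draws` (list per chain), `per_compound` (n x 5
#'   posterior-predictive matrix), `diagnostics` (chains, iterations,
#'   split-R-hat, divergence count — identically zero, as slice
#'   sampling has no divergence mechanism), `converged`, `config`,
#'   `column_names`.
#' @export
fit_polr <- function(design, outcome, config = polr_config()) {
  X <- if (inherits(design, "tier_design")) design$design_matrix else as.matrix(design)
  y <- as.integer(outcome)
  if (nrow(X) != length(y)) stop("design rows must match outcome length", call. = FALSE)
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  if (anyNA(y) || !all(y %in% 1:5)) stop("outcomes must lie in 1..5", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("at least two distinct outcome categories are required", call. = FALSE)
  }
  stopifnot(inherits(config, "polr_config"))
  P <- ncol(X)
  pnames <- c(if (!is.null(colnames(X))) colnames(X) else paste0("beta_", seq_len(P)),
              paste0("c", 1:4), "mu", "sigma")

  # Extra slice directions from the SVD of the column-centered design:
  # collinear carrier blocks make the likelihood ill-conditioned along
  # the natural axes, so each sweep also moves along whitened ones.
  # Because adding a constant to every eta trades off exactly against
  # the cut-points, each direction carries a compensating c1 component
  # (the other cut-points are increments and follow c1), letting the
  # sampler travel along the shift ridge of near-constant columns.
  xbar <- colMeans(X)
  sv <- svd(sweep(X, 2, xbar), nu = 0)
  extra <- if (length(sv$d) == P && max(sv$d) > 0) {
    scale_q <- sqrt(nrow(X)) / pmax(sv$d, max(sv$d) * 1e-3)
    beta_dirs <- sv$v %*% diag(scale_q, P)
    rbind(beta_dirs,
          c1 = as.numeric(xbar %*% beta_dirs),
          matrix(0, 5, P))
  } else {
    matrix(0, P + 6, 0)
  }

  # initial state: empirical logit cut-points, zero coefficients
  cum <- pmin(pmax(cumsum(tabulate(y, 5) / length(y))[1:4], 0.02), 0.98)
  c_init <- stats::qlogis(cummax(cum + seq(0, 3e-3, length.out = 4)))
  init <- c(rep(0, P), c_init[1], log(pmax(diff(c_init), 0.05)), 0, 0)
  widths <- c(rep(1, P), 1, 0.5, 0.5, 0.5, 0.5, 0.5)

  # Pilot run: estimate the posterior covariance in the unconstrained
  # parameterization and add its scaled eigen-directions to the slice
  # direction set. This lets later sweeps move along soft ridges (for
  # example the coefficient-magnitude / cut-point-spread trade-off
  # under quasi-separation) in one step. Directions are frozen before
  # any kept draw, so the kept chains remain valid MCMC.
  set.seed(config$seed * 1000L)
  pilot <- polr_slice_chain(X, y, extra, 300L, 500L, init, widths,
                            config$cut_prior_sd, config$mu_prior_sd,
                            config$sigma_prior_sd)
  U <- cbind(pilot[, seq_len(P), drop = FALSE],
             pilot[, P + 1],
             log(pmax(t(apply(pilot[, P + 1:4, drop = FALSE], 1, diff)), 1e-8)),
             pilot[, P + 5],
             log(pmax(pilot[, P + 6], 1e-8)))
  eg <- eigen(stats::cov(U), symmetric = TRUE)
  eigen_dirs <- eg$vectors %*% diag(1.5 * sqrt(pmax(eg$values, 1e-12)),
                                    ncol(U))
  dirs <- cbind(extra, eigen_dirs)

  chain_draws <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed * 1000L + ch)
    d <- polr_slice_chain(X, y, dirs, config$warmup, config$iter, init,
                          widths, config$cut_prior_sd, config$mu_prior_sd,
                          config$sigma_prior_sd)
    colnames(d) <- pnames
    chain_draws[[ch]] <- d
  }
  draws <- do.call(rbind, chain_draws)
  rhat <- split_rhat(chain_draws)
  converged <- all(rhat <= config$rhat_max)

  per_compound <- posterior_predictive(X, draws, P)
  rownames(per_compound) <- rownames(X)

  fit <- structure(list(
    draws = draws, chain_draws = chain_draws,
    per_compound = per_compound,
    diagnostics = list(chains = config$chains, iter = config$iter,
                       warmup = config$warmup, split_rhat = rhat,
                       divergences = 0L),
    converged = converged, config = config, column_names = colnames(X)
  ), class = "polr_fit")

  if (!converged) {
    msg <- sprintf(
      "tier model failed convergence: max split-R-hat %.4f > %.3f (worst: %s)",
      max(rhat), config$rhat_max, names(which.max(rhat)))
    cond_fun <- if (config$on_diagnostic_failure == "error") {
      function(m) stop(structure(class = c("toxtiers_diagnostic_failure",
                                           "error", "condition"),
                                 list(message = m, call = sys.call(-1),
                                      fit = fit)))
    } else {
      function(m) warning(m, call. = FALSE)
    }
    cond_fun(msg)
  }
  fit
}

# average polr_category_probs over posterior draws, vectorized over draws
posterior_predictive <- function(X, draws, P) {
  eta <- X %*% t(draws[, seq_len(P), drop = FALSE])   # n x S
  cuts <- draws[, P + 1:4, drop = FALSE]              # S x 4
  n <- nrow(X); S <- nrow(draws)
  acc <- matrix(0, n, 5)
  prev <- matrix(0, n, S)
  for (k in 1:4) {
    cum_k <- stats::plogis(matrix(cuts[, k], n, S, byrow = TRUE) - eta)
    acc[, k] <- rowMeans(cum_k - prev)
    prev <- cum_k
  }
  acc[, 5] <- rowMeans(1 - prev)
  colnames(acc) <- paste0("cat", 1:5)
  # guard tiny negatives from float cancellation
  acc[acc < 0 & acc > -1e-12] <- 0
  acc / rowSums(acc)
}

#' @export
print.polr_fit <- function(x, ...) {
  cat(sprintf("Bayesian proportional-odds fit: %d compounds, %d design columns\n",
              nrow(x$per_compound), length(x$column_names)))
  cat(sprintf("  %d chains x %d draws (warmup %d), seed %d [%s profile]\n",
              x$diagnostics$chains, x$diagnostics$iter, x$diagnostics$warmup,
              x$config$seed, x$config$profile))
  cat(sprintf("  max split-R-hat %.4f (%s); converged: %s\n",
              max(x$diagnostics$split_rhat),
              names(which.max(x$diagnostics$split_rhat)),
              x$converged))
  s <- apply(x$draws, 2, function(v) c(mean = mean(v), sd = stats::sd(v)))
  print(round(t(s), 3))
  invisible(x)
}
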