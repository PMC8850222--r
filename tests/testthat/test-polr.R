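test_that("category probabilities match independent logistic arithmetic", {
  got <- polr_category_probs(0, c(0, 1, 2, 3))
  expect_equal(unname(got[1, ]), oracle_polr_probs(0, c(0, 1, 2, 3)),
               tolerance = 1e-15)
  # frozen oracle values (4 d.p.): 0.5000 0.2311 0.1497 0.0718 0.0474
  expect_equal(round(unname(got[1, ]), 4),
               c(0.5000, 0.2311, 0.1497, 0.0718, 0.0474))
  sym <- polr_category_probs(0, c(-2, -1, 1, 2))[1, ]
  expect_equal(sym[["cat1"]], sym[["cat5"]], tolerance = 1e-12)
  expect_equal(sym[["cat2"]], sym[["cat4"]], tolerance = 1e-12)
  expect_equal(unname(polr_category_probs(50, c(0, 1, 2, 3))[1, ]),
               c(0, 0, 0, 0, 1), tolerance = 1e-12)
  expect_equal(unname(polr_category_probs(-50, c(0, 1, 2, 3))[1, ]),
               c(1, 0, 0, 0, 0), tolerance = 1e-12)
  expect_error(polr_category_probs(0, c(0, 2, 1, 3)), "increasing")
})

test_that("category probabilities sum to one and are stochastically monotone", {
  set.seed(31)
  for (i in 1:100) {
    cuts <- sort(rnorm(4, 0, 3))
    if (any(diff(cuts) <= 0)) next
    etas <- sort(rnorm(2, 0, 3))
    pr <- polr_category_probs(etas, cuts)
    expect_equal(unname(rowSums(pr)), c(1, 1), tolerance = 1e-12)
    expect_equal(unname(pr), t(vapply(etas, oracle_polr_probs, numeric(5),
                                      cuts = cuts)), tolerance = 1e-12)
    # larger eta shifts cumulative mass toward higher categories
    cum_lo <- cumsum(pr[1, ]); cum_hi <- cumsum(pr[2, ])
    expect_true(all(cum_hi[1:4] <= cum_lo[1:4] + 1e-12))
  }
})

test_that("split R-hat separates stationary from disagreeing chains", {
  set.seed(32)
  same <- replicate(4, matrix(rnorm(2000), ncol = 2,
                              dimnames = list(NULL, c("a", "b"))),
                    simplify = FALSE)
  expect_true(all(split_rhat(same) < 1.01))
  shifted <- same
  shifted[[1]][, 1] <- shifted[[1]][, 1] + 3
  expect_gt(split_rhat(shifted)[["a"]], 1.5)
  # within-chain trend is also caught by the split
  trended <- same
  trended[[2]][, 2] <- trended[[2]][, 2] + seq(0, 4, length.out = 1000)
  expect_gt(split_rhat(trended)[["b"]], 1.2)
})

test_that("the sampler is deterministic and validates inputs", {
  set.seed(33)
  X <- cbind(x = rnorm(120))
  pr <- polr_category_probs(as.numeric(X), c(-1.5, -0.5, 0.5, 1.5))
  y <- apply(pr, 1, function(p) sample.int(5, 1, prob = p))
  cfg <- polr_config(chains = 2, iter = 150, warmup = 100, seed = 7,
                     on_diagnostic_failure = "warning")
  f1 <- quiet_fit(X, y, cfg)
  f2 <- quiet_fit(X, y, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$per_compound, f2$per_compound)
  expect_identical(f1$diagnostics$divergences, 0L)
  expect_error(fit_polr(X, rep(3L, 120), cfg), "two distinct")
  expect_error(fit_polr(X, c(y[-1], 7L), cfg), "1..5")
  expect_error(fit_polr(X[1:10, , drop = FALSE], y, cfg), "match")
})

test_that("posterior predictive equals direct averaging over the draws", {
  set.seed(34)
  X <- cbind(a = rnorm(60), b = rnorm(60))
  pr <- polr_category_probs(as.numeric(X %*% c(1, -1)), c(-2, -0.5, 0.5, 2))
  y <- apply(pr, 1, function(p) sample.int(5, 1, prob = p))
  f <- quiet_fit(X, y, polr_config(chains = 2, iter = 200, warmup = 150,
                                   seed = 5,
                                   on_diagnostic_failure = "warning"))
  direct <- matrix(0, nrow(X), 5)
  for (s in seq_len(nrow(f$draws))) {
    direct <- direct + polr_category_probs(
      as.numeric(X %*% f$draws[s, 1:2]), f$draws[s, 3:6])
  }
  direct <- direct / nrow(f$draws)
  expect_equal(unname(f$per_compound), unname(direct), tolerance = 1e-10)
  expect_equal(unname(rowSums(f$per_compound)), rep(1, nrow(X)),
               tolerance = 1e-12)
})

test_that("an uninformative design column is governed by its prior", {
  set.seed(35)
  X <- cbind(info = rnorm(200), dead = rep(0, 200))
  pr <- polr_category_probs(X[, 1], c(-1.5, -0.5, 0.5, 1.5))
  y <- apply(pr, 1, function(p) sample.int(5, 1, prob = p))
  f <- quiet_fit(X, y, polr_config(chains = 2, iter = 500, warmup = 300,
                                   seed = 6,
                                   on_diagnostic_failure = "warning"))
  ci <- quantile(f$draws[, "dead"], c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)
  # its posterior spread reflects the (hyper)prior, not data collapse
  expect_gt(sd(f$draws[, "dead"]), 0.15)
  expect_lt(abs(mean(f$draws[, "dead"]) - mean(f$draws[, "mu"])), 0.35)
})

test_that("posterior means agree with the frequentist proportional-odds fit", {
  set.seed(36)
  n <- 400
  X <- cbind(a = rnorm(n), b = rnorm(n))
  pr <- polr_category_probs(as.numeric(X %*% c(1.2, -0.7)),
                            c(-1.8, -0.6, 0.6, 1.8))
  y <- apply(pr, 1, function(p) sample.int(5, 1, prob = p))
  f <- quiet_fit(X, y, polr_config(iter = 1000, seed = 8,
                                   on_diagnostic_failure = "warning"))
  mle <- MASS::polr(factor(y, levels = 1:5, ordered = TRUE) ~ X,
                    method = "logistic")
  expect_lt(max(abs(colMeans(f$draws[, 1:2]) - coef(mle))), 0.12)
  expect_lt(max(abs(colMeans(f$draws[, 3:6]) - mle$zeta)), 0.12)
})

test_that("posterior agrees with an independent Gibbs implementation", {
  skip_if_not_installed("rjags")
  set.seed(37)
  n <- 150
  X <- cbind(a = rnorm(n), b = rnorm(n))
  pr <- polr_category_probs(as.numeric(X %*% c(1.0, -0.6)),
                            c(-1.5, -0.5, 0.5, 1.5))
  y <- apply(pr, 1, function(p) sample.int(5, 1, prob = p))
  f <- quiet_fit(X, y, polr_config(chains = 2, iter = 1500, warmup = 500,
                                   seed = 9,
                                   on_diagnostic_failure = "warning"))
  model <- "model {
  for (j in 1:P) { beta[j] ~ ddexp(mu, lam) }
  lam <- sqrt(2) / sigma
  mu ~ dnorm(0, 1)
  sigma ~ dnorm(0, 1) T(0,)
  for (k in 1:4) { c0[k] ~ dnorm(0, 1 / 400) }
  cc[1:4] <- sort(c0)
  for (i in 1:N) {
    eta[i] <- inprod(X[i, 1:P], beta[1:P])
    q[i, 1] <- ilogit(cc[1] - eta[i])
    q[i, 2] <- ilogit(cc[2] - eta[i])
    q[i, 3] <- ilogit(cc[3] - eta[i])
    q[i, 4] <- ilogit(cc[4] - eta[i])
    p[i, 1] <- q[i, 1]
    p[i, 2] <- q[i, 2] - q[i, 1]
    p[i, 3] <- q[i, 3] - q[i, 2]
    p[i, 4] <- q[i, 4] - q[i, 3]
    p[i, 5] <- 1 - q[i, 4]
    y[i] ~ dcat(p[i, 1:5])
  }
  }"
  jm <- rjags::jags.model(
    textConnection(model), data = list(y = y, X = X, N = n, P = 2),
    inits = list(
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 11,
           c0 = c(-1.5, -0.5, 0.5, 1.5)),
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 12,
           c0 = c(-1.5, -0.5, 0.5, 1.5))),
    n.chains = 2, n.adapt = 500, quiet = TRUE)
  update(jm, 500, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("beta", "cc", "mu", "sigma"), 2000,
                            progress.bar = "none")
  jm_means <- summary(js)$statistics[, "Mean"]
  expect_lt(max(abs(colMeans(f$draws[, 1:2]) -
                      jm_means[c("beta[1]", "beta[2]")])), 0.12)
  expect_lt(max(abs(colMeans(f$draws[, 3:6]) -
                      jm_means[paste0("cc[", 1:4, "]")])), 0.18)
})
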