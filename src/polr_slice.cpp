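// Slice sampler for the Bayesian proportional-odds logistic
// regression used by the tier-update engine.
//
// State (unconstrained), dimension D = P + 6:
//   theta = (beta_1..beta_P, c1, d2, d3, d4, mu, log sigma)
// with ordered cut-points c_k = c_{k-1} + exp(d_k), k = 2..4.
//
// Log posterior = ordinal-logistic likelihood
//   P(y_i <= k) = logistic(c_k - eta_i),  eta_i = X_i . beta
// + Laplace(mu, scale sigma/sqrt(2)) prior on each beta_j
//   (so that sd(beta_j) = sigma)
// + Normal(0, cut_sd) prior on each c_k (plus log-Jacobian d2+d3+d4)
// + Normal(0, mu_sd) on mu, half-Normal(0, sigma_sd) on sigma
//   (plus log-Jacobian log sigma).
//
// Each iteration performs stepping-out slice updates (Neal 2003)
// along every natural coordinate and additionally along a caller-
// supplied set of directions in the coefficient block (typically the
// SVD-whitened axes of the design). The extra directions leave the
// posterior invariant and keep mixing fast when design columns are
// collinear — as the tier carrier blocks usually are. Draws are
// deterministic under R's RNG (set.seed before each chain).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int K = 5; // ordered categories

static inline double logistic(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

struct PolrModel {
  const NumericMatrix &X;
  const IntegerVector &y;
  int n, P;
  double cut_sd, mu_sd, sigma_sd;
  std::vector<double> eta; // running X beta, kept in sync with the state

  PolrModel(const NumericMatrix &X_, const IntegerVector &y_,
            double cut_sd_, double mu_sd_, double sigma_sd_)
    : X(X_), y(y_), n(X_.nrow()), P(X_.ncol()),
      cut_sd(cut_sd_), mu_sd(mu_sd_), sigma_sd(sigma_sd_), eta(X_.nrow()) {}

  void sync_eta(const std::vector<double> &th) {
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int j = 0; j < P; ++j) e += X(i, j) * th[j];
      eta[i] = e;
    }
  }

  // log posterior at state (th + t * dir), with deta = X dir_beta
  // precomputed so each evaluation is O(n + P)
  double log_post_at(const std::vector<double> &th,
                     const std::vector<double> &dir,
                     const std::vector<double> &deta, double t) const {
    double c[K - 1];
    c[0] = th[P] + t * dir[P];
    double jac = 0.0;
    for (int k = 1; k < K - 1; ++k) {
      double d = th[P + k] + t * dir[P + k];
      jac += d;
      c[k] = c[k - 1] + std::exp(d);
    }
    double mu = th[P + 4] + t * dir[P + 4];
    double ls = th[P + 5] + t * dir[P + 5];
    double sigma = std::exp(ls);

    double lp = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = eta[i] + t * deta[i];
      int k = y[i];
      double p;
      if (k == 1) p = logistic(c[0] - e);
      else if (k == K) p = 1.0 - logistic(c[K - 2] - e);
      else p = logistic(c[k - 1] - e) - logistic(c[k - 2] - e);
      if (p < 1e-300) p = 1e-300;
      lp += std::log(p);
    }
    // Laplace prior on beta: sd sigma  =>  scale b = sigma / sqrt(2)
    double b = sigma / M_SQRT2;
    for (int j = 0; j < P; ++j) {
      lp += -std::log(2.0 * b) - std::fabs(th[j] + t * dir[j] - mu) / b;
    }
    for (int k = 0; k < K - 1; ++k) {
      lp += -0.5 * (c[k] / cut_sd) * (c[k] / cut_sd);
    }
    lp += jac;
    lp += -0.5 * (mu / mu_sd) * (mu / mu_sd);
    lp += -0.5 * (sigma / sigma_sd) * (sigma / sigma_sd) + ls; // half-N + Jacobian
    return lp;
  }
};

// stepping-out slice update along direction `dir` (length D), scalar
// step t around the current point (Neal 2003, with shrinkage)
static void slice_dir(PolrModel &m, std::vector<double> &th,
                      const std::vector<double> &dir,
                      const std::vector<double> &deta,
                      double w, int max_steps) {
  const int D = (int)th.size();
  auto at = [&](double t) { return m.log_post_at(th, dir, deta, t); };
  double f0 = at(0.0);
  double z = f0 - exp_rand();
  double u = unif_rand();
  double L = -w * u;
  double R = L + w;
  int jl = (int)std::floor(max_steps * unif_rand());
  int jr = max_steps - 1 - jl;
  while (jl-- > 0 && at(L) > z) L -= w;
  while (jr-- > 0 && at(R) > z) R += w;
  double t_acc = 0.0;
  for (;;) {
    double t = L + unif_rand() * (R - L);
    if (at(t) >= z) { t_acc = t; break; }
    if (t < 0) L = t; else R = t;
    if (R - L < 1e-12) { t_acc = 0.0; break; }
  }
  if (t_acc != 0.0) {
    for (int j = 0; j < D; ++j) th[j] += t_acc * dir[j];
    for (int i = 0; i < m.n; ++i) m.eta[i] += t_acc * deta[i];
  }
}

// [[Rcpp::export]]
NumericMatrix polr_slice_chain(NumericMatrix X, IntegerVector y,
                               NumericMatrix extra_dirs,
                               int n_warmup, int n_iter,
                               NumericVector init, NumericVector widths,
                               double cut_sd, double mu_sd, double sigma_sd,
                               int max_steps = 30) {
  int P = X.ncol();
  int D = P + 6;
  if (init.size() != D) stop("init must have length ncol(X) + 6");
  if (widths.size() != D) stop("widths must have length ncol(X) + 6");
  if (extra_dirs.nrow() != D && extra_dirs.ncol() != 0)
    stop("extra_dirs must have ncol(X) + 6 rows");
  for (int i = 0; i < y.size(); ++i) {
    if (y[i] < 1 || y[i] > K) stop("outcomes must lie in 1..5");
  }
  PolrModel m(X, y, cut_sd, mu_sd, sigma_sd);
  std::vector<double> th(init.begin(), init.end());
  m.sync_eta(th);

  // unit directions for every coordinate, then the extra coefficient
  // directions padded with zeros over the tail parameters; each
  // direction's likelihood shift X dir_beta is precomputed once
  int n = X.nrow();
  int E = extra_dirs.ncol();
  std::vector< std::vector<double> > dirs;
  std::vector< std::vector<double> > detas;
  std::vector<double> dw;
  for (int j = 0; j < D; ++j) {
    std::vector<double> e(D, 0.0); e[j] = 1.0;
    dirs.push_back(e); dw.push_back(widths[j]);
  }
  for (int q = 0; q < E; ++q) {
    std::vector<double> e(D, 0.0);
    for (int j = 0; j < D; ++j) e[j] = extra_dirs(j, q);
    dirs.push_back(e); dw.push_back(1.0);
  }
  for (size_t q = 0; q < dirs.size(); ++q) {
    std::vector<double> de(n, 0.0);
    for (int j = 0; j < P; ++j) {
      double dj = dirs[q][j];
      if (dj != 0.0) for (int i = 0; i < n; ++i) de[i] += X(i, j) * dj;
    }
    detas.push_back(de);
  }

  RNGScope scope;
  NumericMatrix out(n_iter, D); // beta, c1..c4, mu, sigma (natural scale)
  for (int it = 0; it < n_warmup + n_iter; ++it) {
    if (it % 100 == 0) m.sync_eta(th); // limit incremental-update drift
    for (size_t q = 0; q < dirs.size(); ++q)
      slice_dir(m, th, dirs[q], detas[q], dw[q], max_steps);
    if (it >= n_warmup) {
      int r = it - n_warmup;
      for (int j = 0; j < P; ++j) out(r, j) = th[j];
      double c = th[P];
      out(r, P) = c;
      for (int k = 1; k < K - 1; ++k) { c += std::exp(th[P + k]); out(r, P + k) = c; }
      out(r, P + 4) = th[P + 4];
      out(r, P + 5) = std::exp(th[P + 5]);
    }
  }
  return out;
}
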