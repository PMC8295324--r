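#include <Rcpp.h>
#include <R_ext/Applic.h>
using namespace Rcpp;

// Delta-rule / softmax model over an encoded trial sequence. Parameters
// arrive in unbounded Gaussian space, laid out as [alpha slots...,
// beta slots...]; alpha = sigmoid(x), beta = exp(x) floored at
// BETA_FLOOR so the greedy limit stays well defined.
//
// Encoding (0-based, one entry per trial, ordered block-major):
//   new_block  : 1 when the trial opens a block (Q values reset to q0)
//   alpha_idx  : index into x of the alpha slot active on this trial
//   beta_idx   : index into x of the beta slot active on this trial
//   chose_high : 1 if the generative high-probability symbol was chosen
//   reward     : 0/1 outcome
//
// A block uses a single (alpha, beta) slot pair, so the link transforms
// are evaluated at block starts only.

static const double BETA_FLOOR = 1e-6;

// One subject's encoded trials plus the prior, as raw pointers so the
// same core serves single fits and whole-cohort expectation steps.
struct MapData {
  const int* new_block;
  const int* alpha_idx;
  const int* beta_idx;
  const int* chose_high;
  const int* reward;
  int n_trials;
  double q0;
  const double* mu;
  const double* sigma2;
  int k;
};

// log(1/(1+exp(-z))) without overflow at either tail
static inline double log_sigmoid(double z) {
  if (z >= 0.0) return -log1p(std::exp(-z));
  return z - log1p(std::exp(z));
}

static double forward_nll(const MapData& d, const double* x,
                          double* p_out) {
  double q_high = d.q0, q_low = d.q0, nll = 0.0;
  double alpha = 0.5, beta = 1.0;
  for (int t = 0; t < d.n_trials; ++t) {
    if (d.new_block[t]) {
      q_high = d.q0; q_low = d.q0;
      alpha = 1.0 / (1.0 + std::exp(-x[d.alpha_idx[t]]));
      beta = std::exp(x[d.beta_idx[t]]);
      if (beta < BETA_FLOOR) beta = BETA_FLOOR;
    }
    const double z = (q_high - q_low) / beta;
    const double lp = d.chose_high[t] ? log_sigmoid(z) : log_sigmoid(-z);
    nll -= lp;
    if (p_out) p_out[t] = std::exp(lp);
    if (d.chose_high[t]) q_high += alpha * (d.reward[t] - q_high);
    else                 q_low  += alpha * (d.reward[t] - q_low);
  }
  return nll;
}

// Negative log posterior: nll plus the full Gaussian prior terms
static double neg_log_post(const MapData& d, const double* x) {
  double obj = forward_nll(d, x, nullptr);
  for (int j = 0; j < d.k; ++j) {
    const double e = x[j] - d.mu[j];
    obj += 0.5 * (e * e / d.sigma2[j] + std::log(2.0 * M_PI * d.sigma2[j]));
  }
  return obj;
}

// Analytic gradient of the negative log posterior in Gaussian space, by
// forward accumulation: within a block the only parameters in play are
// its alpha slot (through the Q recursion; d alpha/dx = alpha(1-alpha))
// and its beta slot (through the softmax scale; d beta/dx = beta, so
// d z/d x_beta = -z, or 0 when beta sits on its floor).
static void analytic_grad(const MapData& d, const double* x, double* g) {
  for (int j = 0; j < d.k; ++j) g[j] = 0.0;
  double q_high = d.q0, q_low = d.q0, dqh = 0.0, dql = 0.0;
  double alpha = 0.5, da_dx = 0.25, beta = 1.0;
  bool floored = false;
  int ai = 0, bi = 0;
  for (int t = 0; t < d.n_trials; ++t) {
    if (d.new_block[t]) {
      q_high = d.q0; q_low = d.q0; dqh = 0.0; dql = 0.0;
      ai = d.alpha_idx[t]; bi = d.beta_idx[t];
      alpha = 1.0 / (1.0 + std::exp(-x[ai]));
      da_dx = alpha * (1.0 - alpha);
      beta = std::exp(x[bi]);
      floored = beta < BETA_FLOOR;
      if (floored) beta = BETA_FLOOR;
    }
    const double z = (q_high - q_low) / beta;
    const double p_high = 1.0 / (1.0 + std::exp(-z));
    // d(-log p_chosen)/dz
    const double dnll_dz = d.chose_high[t] ? (p_high - 1.0) : p_high;
    g[ai] += dnll_dz * (dqh - dql) / beta;
    if (!floored) g[bi] += dnll_dz * (-z);
    if (d.chose_high[t]) {
      dqh = dqh * (1.0 - alpha) + (d.reward[t] - q_high) * da_dx;
      q_high += alpha * (d.reward[t] - q_high);
    } else {
      dql = dql * (1.0 - alpha) + (d.reward[t] - q_low) * da_dx;
      q_low += alpha * (d.reward[t] - q_low);
    }
  }
  for (int j = 0; j < d.k; ++j) g[j] += (x[j] - d.mu[j]) / d.sigma2[j];
}

static double vm_fn(int n, double* x, void* ex) {
  return neg_log_post(*static_cast<MapData*>(ex), x);
}

static void vm_gr(int n, double* x, double* g, void* ex) {
  analytic_grad(*static_cast<MapData*>(ex), x, g);
}

// Central finite-difference Hessian of the negative log posterior
static void fd_hessian(const MapData& d, const double* x_in, double h,
                       double* H /* k*k, column-major */) {
  const int k = d.k;
  std::vector<double> xt(x_in, x_in + k);
  const double f0 = neg_log_post(d, xt.data());
  for (int i = 0; i < k; ++i) {
    const double xi = xt[i];
    xt[i] = xi + h; const double fp = neg_log_post(d, xt.data());
    xt[i] = xi - h; const double fm = neg_log_post(d, xt.data());
    xt[i] = xi;
    H[i + k * i] = (fp - 2.0 * f0 + fm) / (h * h);
    for (int j = i + 1; j < k; ++j) {
      const double xj = xt[j];
      xt[i] = xi + h; xt[j] = xj + h;
      const double fpp = neg_log_post(d, xt.data());
      xt[j] = xj - h;
      const double fpm = neg_log_post(d, xt.data());
      xt[i] = xi - h; xt[j] = xj + h;
      const double fmp = neg_log_post(d, xt.data());
      xt[j] = xj - h;
      const double fmm = neg_log_post(d, xt.data());
      xt[i] = xi; xt[j] = xj;
      H[i + k * j] = H[j + k * i] = (fpp - fpm - fmp + fmm) / (4.0 * h * h);
    }
  }
}

// Cholesky H = L L^T (lower). Returns false if not positive definite.
// On success fills logdet(H) and the diagonal of H^{-1}.
static bool chol_summaries(const double* H, int k, double* logdet,
                           double* inv_diag) {
  std::vector<double> L(k * k, 0.0);
  for (int j = 0; j < k; ++j) {
    double s = H[j + k * j];
    for (int p = 0; p < j; ++p) s -= L[j + k * p] * L[j + k * p];
    if (s <= 0.0 || !R_finite(s)) return false;
    L[j + k * j] = std::sqrt(s);
    for (int i = j + 1; i < k; ++i) {
      double v = H[i + k * j];
      for (int p = 0; p < j; ++p) v -= L[i + k * p] * L[j + k * p];
      L[i + k * j] = v / L[j + k * j];
    }
  }
  double ld = 0.0;
  for (int j = 0; j < k; ++j) ld += std::log(L[j + k * j]);
  *logdet = 2.0 * ld;
  // M = L^{-1} by forward substitution; diag(H^{-1}) = colsums of M^2
  std::vector<double> M(k * k, 0.0);
  for (int j = 0; j < k; ++j) {
    M[j + k * j] = 1.0 / L[j + k * j];
    for (int i = j + 1; i < k; ++i) {
      double v = 0.0;
      for (int p = j; p < i; ++p) v -= L[i + k * p] * M[p + k * j];
      M[i + k * j] = v / L[i + k * i];
    }
  }
  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    for (int i = j; i < k; ++i) s += M[i + k * j] * M[i + k * j];
    inv_diag[j] = s;
  }
  return true;
}

// Multi-start BFGS MAP fit for one subject; fills the output slices.
// Returns false only if every start failed to produce a finite value.
static bool fit_one(const MapData& d, const double* starts, int n_starts,
                    int maxit, double reltol, double hessian_step,
                    double* x_hat, double* value, double* log_lik,
                    double* log_prior, double* logdet, double* inv_diag,
                    int* pd, int* converged) {
  const int k = d.k;
  std::vector<double> work(k);
  std::vector<int> mask(k, 1);
  double best_val = R_PosInf;
  bool any_run = false, any_conv = false;
  for (int s = 0; s < n_starts; ++s) {
    for (int j = 0; j < k; ++j) work[j] = starts[j + k * s];
    double fmin = R_PosInf;
    int fncount = 0, grcount = 0, fail = 1;
    vmmin(k, work.data(), &fmin, vm_fn, vm_gr, maxit, 0, mask.data(),
          -1e35, reltol, 10, const_cast<MapData*>(&d), &fncount, &grcount,
          &fail);
    if (!R_finite(fmin)) continue;
    any_run = true;
    if (fail == 0) any_conv = true;
    if (fmin < best_val - 1e-12) {
      best_val = fmin;
      std::copy(work.begin(), work.end(), x_hat);
    }
  }
  if (!any_run) return false;
  *value = best_val;
  *converged = any_conv ? 1 : 0;
  const double nll = forward_nll(d, x_hat, nullptr);
  *log_lik = -nll;
  double lp = 0.0;
  for (int j = 0; j < k; ++j) {
    const double e = x_hat[j] - d.mu[j];
    lp += -0.5 * (e * e / d.sigma2[j] + std::log(2.0 * M_PI * d.sigma2[j]));
  }
  *log_prior = lp;
  std::vector<double> H(k * k);
  fd_hessian(d, x_hat, hessian_step, H.data());
  if (chol_summaries(H.data(), k, logdet, inv_diag)) {
    *pd = 1;
  } else {
    *pd = 0;
    *logdet = NA_REAL;
    // no curvature credit if the mode is degenerate
    for (int j = 0; j < k; ++j) inv_diag[j] = 0.0;
  }
  return true;
}

static MapData subject_view(const IntegerVector& new_block,
                            const IntegerVector& alpha_idx,
                            const IntegerVector& beta_idx,
                            const IntegerVector& chose_high,
                            const IntegerVector& reward,
                            int from, int n_trials, double q0,
                            const NumericVector& mu,
                            const NumericVector& sigma2) {
  return MapData{
    new_block.begin() + from, alpha_idx.begin() + from,
    beta_idx.begin() + from, chose_high.begin() + from,
    reward.begin() + from, n_trials, q0, mu.begin(), sigma2.begin(),
    static_cast<int>(mu.size())
  };
}

// [[Rcpp::export(name = ".rl_nll_cpp")]]
List rl_nll_cpp(IntegerVector new_block, IntegerVector alpha_idx,
                IntegerVector beta_idx, IntegerVector chose_high,
                IntegerVector reward, NumericVector x, double q0) {
  NumericVector p(new_block.size());
  NumericVector dummy(x.size());
  MapData d = subject_view(new_block, alpha_idx, beta_idx, chose_high,
                           reward, 0, new_block.size(), q0, dummy, dummy);
  double nll = forward_nll(d, x.begin(), p.begin());
  return List::create(_["nll"] = nll, _["p_chosen"] = p);
}

// [[Rcpp::export(name = ".map_objective_cpp")]]
double map_objective_cpp(NumericVector x, IntegerVector new_block,
                         IntegerVector alpha_idx, IntegerVector beta_idx,
                         IntegerVector chose_high, IntegerVector reward,
                         double q0, NumericVector mu, NumericVector sigma2) {
  MapData d = subject_view(new_block, alpha_idx, beta_idx, chose_high,
                           reward, 0, new_block.size(), q0, mu, sigma2);
  return neg_log_post(d, x.begin());
}

// [[Rcpp::export(name = ".map_gradient_cpp")]]
NumericVector map_gradient_cpp(NumericVector x, IntegerVector new_block,
                               IntegerVector alpha_idx,
                               IntegerVector beta_idx,
                               IntegerVector chose_high,
                               IntegerVector reward, double q0,
                               NumericVector mu, NumericVector sigma2) {
  MapData d = subject_view(new_block, alpha_idx, beta_idx, chose_high,
                           reward, 0, new_block.size(), q0, mu, sigma2);
  NumericVector g(x.size());
  analytic_grad(d, x.begin(), g.begin());
  return g;
}

// Central finite-difference gradient; retained as an independent check
// on the analytic gradient.
// [[Rcpp::export(name = ".map_gradient_fd_cpp")]]
NumericVector map_gradient_fd_cpp(NumericVector x, IntegerVector new_block,
                                  IntegerVector alpha_idx,
                                  IntegerVector beta_idx,
                                  IntegerVector chose_high,
                                  IntegerVector reward, double q0,
                                  NumericVector mu, NumericVector sigma2,
                                  double h = 1e-6) {
  MapData d = subject_view(new_block, alpha_idx, beta_idx, chose_high,
                           reward, 0, new_block.size(), q0, mu, sigma2);
  const int k = x.size();
  NumericVector g(k);
  std::vector<double> xt(x.begin(), x.end());
  for (int j = 0; j < k; ++j) {
    const double x0 = xt[j];
    xt[j] = x0 + h;
    const double fp = neg_log_post(d, xt.data());
    xt[j] = x0 - h;
    const double fm = neg_log_post(d, xt.data());
    xt[j] = x0;
    g[j] = (fp - fm) / (2.0 * h);
  }
  return g;
}

// [[Rcpp::export(name = ".map_hessian_cpp")]]
NumericMatrix map_hessian_cpp(NumericVector x, IntegerVector new_block,
                              IntegerVector alpha_idx,
                              IntegerVector beta_idx,
                              IntegerVector chose_high,
                              IntegerVector reward, double q0,
                              NumericVector mu, NumericVector sigma2,
                              double h = 1e-4) {
  MapData d = subject_view(new_block, alpha_idx, beta_idx, chose_high,
                           reward, 0, new_block.size(), q0, mu, sigma2);
  const int k = x.size();
  NumericMatrix H(k, k);
  fd_hessian(d, x.begin(), h, H.begin());
  return H;
}

// Expectation step for a whole cohort in one call. Trials of all subjects
// are concatenated; `offsets` has n_subjects + 1 entries delimiting each
// subject's slice. `starts` is k x n_starts x n_subjects (column-major
// slabs per subject). Returns per-subject MAP summaries; the Hessian is
// summarised by its log-determinant and inverse diagonal (all that the
// evidence and the maximisation step need).
// [[Rcpp::export(name = ".em_estep_cpp")]]
List em_estep_cpp(NumericVector starts, int n_starts,
                  IntegerVector offsets, IntegerVector new_block,
                  IntegerVector alpha_idx, IntegerVector beta_idx,
                  IntegerVector chose_high, IntegerVector reward,
                  double q0, NumericVector mu, NumericVector sigma2,
                  int maxit = 500, double reltol = 1e-10,
                  double hessian_step = 1e-4) {
  const int k = mu.size();
  const int ns = offsets.size() - 1;
  NumericMatrix X(k, ns), inv_diag(k, ns);
  NumericVector value(ns), log_lik(ns), log_prior(ns), logdet(ns);
  IntegerVector pd(ns), converged(ns);
  for (int s = 0; s < ns; ++s) {
    MapData d = subject_view(new_block, alpha_idx, beta_idx, chose_high,
                             reward, offsets[s], offsets[s + 1] - offsets[s],
                             q0, mu, sigma2);
    bool ok = fit_one(d, starts.begin() + k * n_starts * s, n_starts,
                      maxit, reltol, hessian_step,
                      &X(0, s), &value[s], &log_lik[s], &log_prior[s],
                      &logdet[s], &inv_diag(0, s), &pd[s], &converged[s]);
    if (!ok) {
      stop("subject-level optimisation failed from every start (subject %d).",
           s + 1);
    }
  }
  return List::create(_["x"] = X, _["value"] = value,
                      _["log_lik"] = log_lik, _["log_prior"] = log_prior,
                      _["logdet"] = logdet, _["inv_diag"] = inv_diag,
                      _["pd"] = pd, _["converged"] = converged);
}

// Per-subject log mean likelihood under Monte-Carlo prior draws, computed
// with a stable log-sum-exp; used by the integrated BIC.
// xs: n_samples x k matrix of Gaussian-space prior draws.
// [[Rcpp::export(name = ".loglik_mc_cpp")]]
double loglik_mc_cpp(NumericMatrix xs, IntegerVector new_block,
                     IntegerVector alpha_idx, IntegerVector beta_idx,
                     IntegerVector chose_high, IntegerVector reward,
                     double q0) {
  const int m = xs.nrow(), k = xs.ncol();
  NumericVector dummy(k);
  MapData d = subject_view(new_block, alpha_idx, beta_idx, chose_high,
                           reward, 0, new_block.size(), q0, dummy, dummy);
  std::vector<double> ll(m);
  std::vector<double> x(k);
  double mx = R_NegInf;
  for (int s = 0; s < m; ++s) {
    for (int j = 0; j < k; ++j) x[j] = xs(s, j);
    ll[s] = -forward_nll(d, x.data(), nullptr);
    if (ll[s] > mx) mx = ll[s];
  }
  double acc = 0.0;
  for (int s = 0; s < m; ++s) acc += std::exp(ll[s] - mx);
  return mx + std::log(acc / m);
}
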