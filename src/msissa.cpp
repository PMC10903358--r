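#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-choice-set, per-state log choice probabilities.
// X: covariate matrix, rows grouped by choice set (m1 rows each, row 0 = used).
// coef: p x N matrix of state-specific coefficients.
// Returns nsets x N matrix of log p_{0,t,i} = w_0 - logsumexp_m(w_m).
// [[Rcpp::export]]
NumericMatrix cc_state_logprob_cpp(NumericMatrix X, NumericMatrix coef, int m1) {
  const int n = X.nrow(), p = X.ncol(), N = coef.ncol();
  if (n % m1 != 0) stop("row count not a multiple of the choice-set size");
  const int nsets = n / m1;
  NumericMatrix out(nsets, N);
  std::vector<double> W(n);
  for (int i = 0; i < N; ++i) {
    std::fill(W.begin(), W.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double c = coef(j, i);
      if (c == 0.0) continue;
      const double* xj = &X(0, j);
      for (int r = 0; r < n; ++r) W[r] += c * xj[r];
    }
    for (int s = 0; s < nsets; ++s) {
      const double* w = &W[(size_t)s * m1];
      double mx = w[0];
      for (int m = 1; m < m1; ++m) if (w[m] > mx) mx = w[m];
      if (!std::isfinite(mx)) stop("non-finite weight in choice set %d, state %d",
                                   s + 1, i + 1);
      double se = 0.0;
      for (int m = 0; m < m1; ++m) se += std::exp(w[m] - mx);
      out(s, i) = w[0] - mx - std::log(se);
    }
  }
  return out;
}

// Scaled forward-algorithm negative log-likelihood of an HMM given the
// per-observation, per-state log densities (or log choice probabilities).
// A change in burst id restarts the recursion at delta.
// [[Rcpp::export]]
double hmm_forward_nll_cpp(NumericMatrix logp, NumericMatrix Gamma,
                           NumericVector delta, IntegerVector burst) {
  const int n = logp.nrow(), N = logp.ncol();
  if (burst.size() != n) stop("burst length mismatch");
  std::vector<double> phi(N), v(N);
  double ll = 0.0;
  for (int s = 0; s < n; ++s) {
    double c = logp(s, 0);
    for (int i = 1; i < N; ++i) if (logp(s, i) > c) c = logp(s, i);
    const bool restart = (s == 0) || (burst[s] != burst[s - 1]);
    double tot = 0.0;
    for (int j = 0; j < N; ++j) {
      double pre;
      if (restart) {
        pre = delta[j];
      } else {
        pre = 0.0;
        for (int i = 0; i < N; ++i) pre += phi[i] * Gamma(i, j);
      }
      v[j] = pre * std::exp(logp(s, j) - c);
      tot += v[j];
    }
    if (!(tot > 0.0) || !std::isfinite(tot) || !std::isfinite(c)) {
      return 1e12;  // signals underflow/invalid region to the optimiser
    }
    ll += std::log(tot) + c;
    for (int j = 0; j < N; ++j) phi[j] = v[j] / tot;
  }
  return -ll;
}

// Negative log-likelihood and analytic gradient (with respect to the
// state-specific coefficient columns) of the Markov-switching conditional
// logistic model. The gradient combines the forward-backward state
// posteriors u_t(i) with the per-choice-set softmax score
// X_0 - E_pi[X]; the per-set log choice probabilities are also returned so
// the caller can differentiate the transition parameters by rerunning the
// (cheap) forward recursion alone.
// [[Rcpp::export]]
List cc_nll_grad_cpp(NumericMatrix X, NumericMatrix coef, int m1,
                     NumericMatrix Gamma, NumericVector delta,
                     IntegerVector burst) {
  const int n = X.nrow(), p = X.ncol(), N = coef.ncol();
  if (n % m1 != 0) stop("row count not a multiple of the choice-set size");
  const int nsets = n / m1;
  NumericMatrix logp(nsets, N);
  // score[(s*N + i)*p + j] = d logp(s,i) / d coef(j,i)
  std::vector<double> score((size_t)nsets * N * p);
  std::vector<double> W(n), pi(m1);
  for (int i = 0; i < N; ++i) {
    std::fill(W.begin(), W.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double c = coef(j, i);
      if (c == 0.0) continue;
      const double* xj = &X(0, j);
      for (int r = 0; r < n; ++r) W[r] += c * xj[r];
    }
    for (int s = 0; s < nsets; ++s) {
      const double* w = &W[(size_t)s * m1];
      double mx = w[0];
      for (int m = 1; m < m1; ++m) if (w[m] > mx) mx = w[m];
      if (!std::isfinite(mx)) {
        // overflowing line-search step: flag as invalid, let the caller
        // penalise instead of aborting the optimisation
        NumericMatrix grad0(p, N);
        return List::create(_["nll"] = 1e12, _["grad_coef"] = grad0,
                            _["logp"] = logp, _["ok"] = false);
      }
      double se = 0.0;
      for (int m = 0; m < m1; ++m) { pi[m] = std::exp(w[m] - mx); se += pi[m]; }
      logp(s, i) = w[0] - mx - std::log(se);
      double* sc = &score[((size_t)s * N + i) * p];
      for (int j = 0; j < p; ++j) {
        double ex = 0.0;
        const double* xj = &X((size_t)s * m1, j);
        for (int m = 0; m < m1; ++m) ex += pi[m] * xj[m];
        sc[j] = X((size_t)s * m1, j) - ex / se;
      }
    }
  }
  // scaled forward pass (store normalised alpha and log-scales)
  NumericMatrix alpha(nsets, N);
  std::vector<double> cmax(nsets);
  std::vector<double> v(N);
  double ll = 0.0;
  bool bad = false;
  for (int s = 0; s < nsets && !bad; ++s) {
    double c = logp(s, 0);
    for (int i = 1; i < N; ++i) if (logp(s, i) > c) c = logp(s, i);
    cmax[s] = c;
    const bool restart = (s == 0) || (burst[s] != burst[s - 1]);
    double tot = 0.0;
    for (int j = 0; j < N; ++j) {
      double pre;
      if (restart) {
        pre = delta[j];
      } else {
        pre = 0.0;
        for (int i = 0; i < N; ++i) pre += alpha(s - 1, i) * Gamma(i, j);
      }
      v[j] = pre * std::exp(logp(s, j) - c);
      tot += v[j];
    }
    if (!(tot > 0.0) || !std::isfinite(tot) || !std::isfinite(c)) bad = true;
    else {
      ll += std::log(tot) + c;
      for (int j = 0; j < N; ++j) alpha(s, j) = v[j] / tot;
    }
  }
  NumericMatrix grad(p, N);
  if (bad) {
    return List::create(_["nll"] = 1e12, _["grad_coef"] = grad,
                        _["logp"] = logp, _["ok"] = false);
  }
  // scaled backward pass and posterior-weighted scores
  std::vector<double> beta_cur(N, 1.0), beta_next(N);
  for (int s = nsets - 1; s >= 0; --s) {
    const bool at_end = (s == nsets - 1) || (burst[s + 1] != burst[s]);
    if (at_end) {
      std::fill(beta_cur.begin(), beta_cur.end(), 1.0);
    } else {
      double norm = 0.0;
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int j = 0; j < N; ++j) {
          acc += Gamma(i, j) * std::exp(logp(s + 1, j) - cmax[s + 1]) * beta_next[j];
        }
        beta_cur[i] = acc;
        norm += acc;
      }
      for (int i = 0; i < N; ++i) beta_cur[i] /= norm;
    }
    double tot = 0.0;
    for (int i = 0; i < N; ++i) { v[i] = alpha(s, i) * beta_cur[i]; tot += v[i]; }
    for (int i = 0; i < N; ++i) {
      const double u = v[i] / tot;
      const double* sc = &score[((size_t)s * N + i) * p];
      for (int j = 0; j < p; ++j) grad(j, i) -= u * sc[j];
    }
    beta_next = beta_cur;
  }
  return List::create(_["nll"] = -ll, _["grad_coef"] = grad,
                      _["logp"] = logp, _["ok"] = true);
}

// Single-state conditional-logistic negative log-likelihood and analytic
// gradient with respect to the coefficient vector.
// [[Rcpp::export]]
List cc_clogit_nll_grad_cpp(NumericMatrix X, NumericVector coef, int m1) {
  const int n = X.nrow(), p = X.ncol();
  if (n % m1 != 0) stop("row count not a multiple of the choice-set size");
  const int nsets = n / m1;
  std::vector<double> w(m1), pi(m1);
  NumericVector grad(p);
  double nll = 0.0;
  for (int s = 0; s < nsets; ++s) {
    const int base = s * m1;
    double mx = R_NegInf;
    for (int m = 0; m < m1; ++m) {
      double acc = 0.0;
      for (int j = 0; j < p; ++j) acc += X(base + m, j) * coef[j];
      w[m] = acc;
      if (acc > mx) mx = acc;
    }
    double se = 0.0;
    for (int m = 0; m < m1; ++m) { pi[m] = std::exp(w[m] - mx); se += pi[m]; }
    nll -= w[0] - mx - std::log(se);
    for (int m = 0; m < m1; ++m) pi[m] /= se;
    for (int j = 0; j < p; ++j) {
      double ex = 0.0;
      for (int m = 0; m < m1; ++m) ex += pi[m] * X(base + m, j);
      grad[j] -= X(base, j) - ex;
    }
  }
  return List::create(_["nll"] = nll, _["grad"] = grad);
}
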