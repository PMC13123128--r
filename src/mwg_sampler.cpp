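// Metropolis-Hastings-within-Gibbs chain loop for the hierarchical logistic
// model. Semantics (and RNG consumption, draw for draw) match the R
// reference engine in R/sampler.R: per iteration one intercept update, a
// componentwise fixed-effect sweep, a per-center random-intercept sweep, and
// an exact Inverse-Gamma draw for the between-center variance. Proposal
// scales adapt multiplicatively during burn-in only.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double log1pexp_c(double x) {
  if (x > 33.3) return x;
  if (x > 18.0) return x + std::exp(-x);
  if (x > -37.0) return std::log1p(std::exp(x));
  return std::exp(x);
}

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// one MH decision; always consumes one uniform (parity with the R engine)
static inline bool mh_decide(double logr) {
  double lu = std::log(unif_rand());
  if (!R_finite(logr) && logr < 0) return false;  // -Inf proposal
  return lu < logr;
}

static inline double adapt_scale(double rate, double tau, double lo, double hi) {
  if (rate > hi) return tau * 1.1;
  if (rate < lo) return tau / 1.1;
  return tau;
}

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(IntegerVector y, NumericMatrix X, IntegerVector center,
                   int J,
                   double sigma2_alpha, NumericVector sigma2_beta,
                   double a0, double b0,
                   int n_iter, int burn_in, int thin,
                   double init_alpha, NumericVector init_beta,
                   NumericVector init_u, double init_sigma2,
                   double tau_alpha, NumericVector tau_beta,
                   NumericVector tau_u,
                   bool adapt, int adapt_window,
                   double target_lo, double target_hi,
                   int kernel) {
  const int n = y.size();
  const int p = X.ncol();
  const bool mala = kernel == 1;

  // sparse column access: dummy-coded columns are mostly zero
  std::vector< std::vector<int> > col_idx(p);
  std::vector< std::vector<double> > col_val(p);
  for (int k = 0; k < p; ++k)
    for (int i = 0; i < n; ++i)
      if (X(i, k) != 0.0) { col_idx[k].push_back(i); col_val[k].push_back(X(i, k)); }

  std::vector< std::vector<int> > cen_idx(J);
  if (J > 0)
    for (int i = 0; i < n; ++i) cen_idx[center[i] - 1].push_back(i);

  double alpha = init_alpha;
  std::vector<double> beta(init_beta.begin(), init_beta.end());
  std::vector<double> u(init_u.begin(), init_u.end());
  double sigma2_u = init_sigma2;

  std::vector<double> eta(n), lse(n);
  for (int i = 0; i < n; ++i) {
    double e = alpha;
    for (int k = 0; k < p; ++k) if (X(i, k) != 0.0) e += X(i, k) * beta[k];
    if (J > 0) e += u[center[i] - 1];
    eta[i] = e;
    lse[i] = log1pexp_c(e);
  }

  double ta = tau_alpha;
  std::vector<double> tb(tau_beta.begin(), tau_beta.end());
  std::vector<double> tu(tau_u.begin(), tau_u.end());

  const int S = (n_iter - burn_in) / thin;
  NumericVector alpha_d(S), s2_d(S);
  NumericMatrix beta_d(S, p), u_d(S, J);
  int acc_alpha = 0, win_alpha = 0;
  std::vector<int> acc_beta(p, 0), win_beta(p, 0), acc_u(J, 0), win_u(J, 0);

  RNGScope scope;
  int s = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // ---- intercept ----
    {
      double prop, corr = 0.0;
      if (mala) {
        double g = -alpha / sigma2_alpha;
        for (int i = 0; i < n; ++i) g += y[i] - sigmoid(eta[i]);
        double m = alpha + 0.5 * ta * ta * g;
        prop = R::rnorm(m, ta);
        double d = prop - alpha;
        double gp = -prop / sigma2_alpha;
        for (int i = 0; i < n; ++i) gp += y[i] - sigmoid(eta[i] + d);
        double mb = prop + 0.5 * ta * ta * gp;
        corr = -(alpha - mb) * (alpha - mb) / (2 * ta * ta)
             + (prop - m) * (prop - m) / (2 * ta * ta);
      } else {
        prop = R::rnorm(alpha, ta);
      }
      double d = prop - alpha;
      double logr = corr - (prop * prop - alpha * alpha) / (2 * sigma2_alpha);
      for (int i = 0; i < n; ++i)
        logr += y[i] * d - (log1pexp_c(eta[i] + d) - lse[i]);
      if (mh_decide(logr)) {
        alpha = prop;
        for (int i = 0; i < n; ++i) { eta[i] += d; lse[i] = log1pexp_c(eta[i]); }
        ++win_alpha;
        if (it > burn_in) ++acc_alpha;
      }
    }
    // ---- fixed effects, ascending k ----
    for (int k = 0; k < p; ++k) {
      const std::vector<int>& idx = col_idx[k];
      const std::vector<double>& val = col_val[k];
      double prop, corr = 0.0;
      if (mala) {
        double g = -beta[k] / sigma2_beta[k];
        for (size_t t = 0; t < idx.size(); ++t)
          g += (y[idx[t]] - sigmoid(eta[idx[t]])) * val[t];
        double m = beta[k] + 0.5 * tb[k] * tb[k] * g;
        prop = R::rnorm(m, tb[k]);
        double d = prop - beta[k];
        double gp = -prop / sigma2_beta[k];
        for (size_t t = 0; t < idx.size(); ++t)
          gp += (y[idx[t]] - sigmoid(eta[idx[t]] + d * val[t])) * val[t];
        double mb = prop + 0.5 * tb[k] * tb[k] * gp;
        corr = -(beta[k] - mb) * (beta[k] - mb) / (2 * tb[k] * tb[k])
             + (prop - m) * (prop - m) / (2 * tb[k] * tb[k]);
      } else {
        prop = R::rnorm(beta[k], tb[k]);
      }
      double d = prop - beta[k];
      double logr = corr -
        (prop * prop - beta[k] * beta[k]) / (2 * sigma2_beta[k]);
      for (size_t t = 0; t < idx.size(); ++t) {
        int i = idx[t];
        double dv = d * val[t];
        logr += y[i] * dv - (log1pexp_c(eta[i] + dv) - lse[i]);
      }
      if (mh_decide(logr)) {
        beta[k] = prop;
        for (size_t t = 0; t < idx.size(); ++t) {
          int i = idx[t];
          eta[i] += d * val[t];
          lse[i] = log1pexp_c(eta[i]);
        }
        ++win_beta[k];
        if (it > burn_in) ++acc_beta[k];
      }
    }
    // ---- center effects + conjugate variance draw ----
    if (J > 0) {
      for (int j = 0; j < J; ++j) {
        const std::vector<int>& idx = cen_idx[j];
        double prop, corr = 0.0;
        if (mala) {
          double g = -u[j] / sigma2_u;
          for (size_t t = 0; t < idx.size(); ++t)
            g += y[idx[t]] - sigmoid(eta[idx[t]]);
          double m = u[j] + 0.5 * tu[j] * tu[j] * g;
          prop = R::rnorm(m, tu[j]);
          double d = prop - u[j];
          double gp = -prop / sigma2_u;
          for (size_t t = 0; t < idx.size(); ++t)
            gp += y[idx[t]] - sigmoid(eta[idx[t]] + d);
          double mb = prop + 0.5 * tu[j] * tu[j] * gp;
          corr = -(u[j] - mb) * (u[j] - mb) / (2 * tu[j] * tu[j])
               + (prop - m) * (prop - m) / (2 * tu[j] * tu[j]);
        } else {
          prop = R::rnorm(u[j], tu[j]);
        }
        double d = prop - u[j];
        double logr = corr - (prop * prop - u[j] * u[j]) / (2 * sigma2_u);
        for (size_t t = 0; t < idx.size(); ++t) {
          int i = idx[t];
          logr += y[i] * d - (log1pexp_c(eta[i] + d) - lse[i]);
        }
        if (mh_decide(logr)) {
          u[j] = prop;
          for (size_t t = 0; t < idx.size(); ++t) {
            int i = idx[t];
            eta[i] += d;
            lse[i] = log1pexp_c(eta[i]);
          }
          ++win_u[j];
          if (it > burn_in) ++acc_u[j];
        }
      }
      // long-double accumulation matches R's sum(), keeping the conjugate
      // draw bit-identical to the reference engine
      long double ssq = 0.0;
      for (int j = 0; j < J; ++j) ssq += (long double) u[j] * u[j];
      double shape = a0 + J / 2.0;
      double rate = b0 + 0.5 * (double) ssq;
      sigma2_u = 1.0 / R::rgamma(shape, 1.0 / rate);
    }
    // ---- burn-in-only adaptation ----
    if (adapt && it <= burn_in && it % adapt_window == 0) {
      double w = (double) adapt_window;
      ta = adapt_scale(win_alpha / w, ta, target_lo, target_hi);
      for (int k = 0; k < p; ++k)
        tb[k] = adapt_scale(win_beta[k] / w, tb[k], target_lo, target_hi);
      for (int j = 0; j < J; ++j)
        tu[j] = adapt_scale(win_u[j] / w, tu[j], target_lo, target_hi);
      win_alpha = 0;
      std::fill(win_beta.begin(), win_beta.end(), 0);
      std::fill(win_u.begin(), win_u.end(), 0);
    }
    // ---- retention ----
    if (it > burn_in && (it - burn_in) % thin == 0) {
      alpha_d[s] = alpha;
      for (int k = 0; k < p; ++k) beta_d(s, k) = beta[k];
      for (int j = 0; j < J; ++j) u_d(s, j) = u[j];
      s2_d[s] = sigma2_u;
      ++s;
    }
  }

  return List::create(
    _["alpha"] = alpha_d, _["beta"] = beta_d, _["u"] = u_d,
    _["sigma2_u"] = s2_d,
    _["accept_alpha"] = acc_alpha,
    _["accept_beta"] = IntegerVector(acc_beta.begin(), acc_beta.end()),
    _["accept_u"] = IntegerVector(acc_u.begin(), acc_u.end()),
    _["tau_final"] = List::create(_["alpha"] = ta,
                                  _["beta"] = NumericVector(tb.begin(), tb.end()),
                                  _["u"] = NumericVector(tu.begin(), tu.end())),
    _["S"] = S);
}
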