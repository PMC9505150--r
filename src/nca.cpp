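#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Regularized neighbourhood component analysis for feature weighting.
// Squared-weight parameterization with L1 per-feature distances:
//   d_ij = sum_r w_r^2 |x_ir - x_jr|,  k_ij = exp(-d_ij),
//   p_ij = k_ij / sum_{l != i} k_il,
//   F(w) = (1/n) sum_i p_i - lambda sum_r w_r^2,  p_i = sum_{j ~ i} p_ij
// (the averaged-loss convention under which a regularization strength of
// about 1/n is the neutral default).
// Maximized by per-sample stochastic gradient ascent with a
// 1/(1 + decay * epoch) learning-rate schedule. Deterministic given the
// seed (own xorshift shuffling, independent of R's RNG stream).

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17;
  return s;
}

// [[Rcpp::export]]
NumericVector nca_sgd_cpp(NumericMatrix X, IntegerVector y, double lambda,
                          int epochs, double lr0, double decay,
                          int seed) {
  int n = X.nrow(), p = X.ncol();
  // start at the unit average-metric scale: with z-scored features the
  // initial distances are O(mean |x_i - x_j|), keeping the soft-neighbour
  // kernel responsive from the first step instead of saturated
  std::vector<double> w(p, 1.0 / std::sqrt((double)p));
  std::vector<double> kij(n), term1(p), term2(p);
  // transposed copy for cache-friendly row access
  std::vector<double> Xt((size_t)n * p);
  for (int i = 0; i < n; ++i)
    for (int r = 0; r < p; ++r)
      Xt[(size_t)i * p + r] = X(i, r);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint64_t rs = (uint64_t)seed * 2685821657736338717ULL + 1442695040888963407ULL;

  for (int ep = 0; ep < epochs; ++ep) {
    double lr = lr0 / (1.0 + decay * ep);
    // keep the regularizer's gradient-descent map contractive
    if (lambda > 0 && lr > 0.45 / lambda) lr = 0.45 / lambda;
    // Fisher-Yates shuffle driven by the private stream
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(xorshift64(rs) % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      const double *xi = &Xt[(size_t)i * p];
      double S = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { kij[j] = 0.0; continue; }
        const double *xj = &Xt[(size_t)j * p];
        double d = 0.0;
        for (int r = 0; r < p; ++r)
          d += w[r] * w[r] * std::fabs(xi[r] - xj[r]);
        kij[j] = std::exp(-d);
        S += kij[j];
      }
      double pi = 0.0;
      std::fill(term1.begin(), term1.end(), 0.0);
      std::fill(term2.begin(), term2.end(), 0.0);
      if (S > 1e-300) {
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double pij = kij[j] / S;
          if (pij < 1e-14) continue;
          const double *xj = &Xt[(size_t)j * p];
          bool same = (y[j] == y[i]);
          if (same) pi += pij;
          for (int r = 0; r < p; ++r) {
            double D = std::fabs(xi[r] - xj[r]);
            term1[r] += pij * D;
            if (same) term2[r] += pij * D;
          }
        }
      }
      for (int r = 0; r < p; ++r) {
        double grad = 2.0 * w[r] * (pi * term1[r] - term2[r]) -
                      2.0 * lambda * w[r];
        w[r] += lr * grad;
      }
    }
  }
  NumericVector out(p);
  for (int r = 0; r < p; ++r) out[r] = std::fabs(w[r]);
  return out;
}

// Objective value at a given weight vector (used for convergence checks).
// [[Rcpp::export]]
double nca_objective_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                         double lambda) {
  int n = X.nrow(), p = X.ncol();
  double total = 0.0;
  std::vector<double> kij(n);
  for (int i = 0; i < n; ++i) {
    double S = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) { kij[j] = 0.0; continue; }
      double d = 0.0;
      for (int r = 0; r < p; ++r)
        d += w[r] * w[r] * std::fabs(X(i, r) - X(j, r));
      kij[j] = std::exp(-d);
      S += kij[j];
    }
    if (S <= 1e-300) continue;
    double pi = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i && y[j] == y[i]) pi += kij[j] / S;
    total += pi;
  }
  double reg = 0.0;
  for (int r = 0; r < p; ++r) reg += w[r] * w[r];
  return total / n - lambda * reg;
}
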