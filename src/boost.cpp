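#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------
// Weighted binary CART, best-first, capped number of internal splits.
// Labels are +1/-1; impurity is weighted Gini. Leaves carry the weighted
// class-probability difference as score; prediction is its sign with
// ties to the negative class.
// ---------------------------------------------------------------------

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;  // -1 for leaf
  std::vector<double> score;     // (w+ - w-)/(w+ + w-)
};

struct NodeWork {
  int node;
  std::vector<int> idx;
  double gain;
  int best_feat;
  double best_thr;
};

static inline double gini_w(double wp, double wn) {
  double tot = wp + wn;
  if (tot <= 0) return 0.0;
  double pp = wp / tot, pn = wn / tot;
  return tot * (1.0 - pp * pp - pn * pn);
}

static void best_split(const NumericMatrix &X, const IntegerVector &y,
                       const NumericVector &w, NodeWork &nw) {
  nw.gain = 0.0; nw.best_feat = -1; nw.best_thr = 0.0;
  int m = (int)nw.idx.size(), p = X.ncol();
  if (m < 2) return;
  double wp0 = 0, wn0 = 0;
  for (int k = 0; k < m; ++k) {
    if (y[nw.idx[k]] > 0) wp0 += w[nw.idx[k]]; else wn0 += w[nw.idx[k]];
  }
  double g0 = gini_w(wp0, wn0);
  if (g0 <= 1e-15) return;
  std::vector<std::pair<double, int> > vals(m);
  for (int j = 0; j < p; ++j) {
    for (int k = 0; k < m; ++k)
      vals[k] = std::make_pair(X(nw.idx[k], j), nw.idx[k]);
    std::sort(vals.begin(), vals.end());
    double wp = 0, wn = 0;
    for (int k = 0; k < m - 1; ++k) {
      int i = vals[k].second;
      if (y[i] > 0) wp += w[i]; else wn += w[i];
      if (vals[k + 1].first <= vals[k].first) continue;  // not a boundary
      if (wp + wn <= 0 || (wp0 - wp) + (wn0 - wn) <= 0) continue;
      double g = g0 - gini_w(wp, wn) - gini_w(wp0 - wp, wn0 - wn);
      if (g > nw.gain + 1e-15) {
        nw.gain = g;
        nw.best_feat = j;
        nw.best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
}

static Tree fit_tree(const NumericMatrix &X, const IntegerVector &y,
                     const NumericVector &w, int max_splits) {
  int n = X.nrow();
  Tree tr;
  std::vector<NodeWork> open;
  NodeWork root;
  root.node = 0;
  root.idx.resize(n);
  for (int i = 0; i < n; ++i) root.idx[i] = i;
  double wp = 0, wn = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] > 0) wp += w[i]; else wn += w[i];
  }
  tr.feature.push_back(-1);
  tr.threshold.push_back(0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.score.push_back((wp + wn) > 0 ? (wp - wn) / (wp + wn) : 0.0);
  if (max_splits > 0) {
    best_split(X, y, w, root);
    if (root.best_feat >= 0) open.push_back(root);
  }
  int splits = 0;
  while (splits < max_splits && !open.empty()) {
    // best-first: take the open leaf with the largest impurity decrease
    size_t bi = 0;
    for (size_t k = 1; k < open.size(); ++k)
      if (open[k].gain > open[bi].gain) bi = k;
    NodeWork cur = open[bi];
    open.erase(open.begin() + bi);
    if (cur.gain <= 1e-15 || cur.best_feat < 0) break;
    int nodeL = (int)tr.feature.size(), nodeR = nodeL + 1;
    tr.feature[cur.node] = cur.best_feat;
    tr.threshold[cur.node] = cur.best_thr;
    tr.left[cur.node] = nodeL;
    tr.right[cur.node] = nodeR;
    NodeWork chl, chr;
    chl.node = nodeL; chr.node = nodeR;
    for (size_t k = 0; k < cur.idx.size(); ++k) {
      int i = cur.idx[k];
      if (X(i, cur.best_feat) < cur.best_thr) chl.idx.push_back(i);
      else chr.idx.push_back(i);
    }
    NodeWork *children[2] = {&chl, &chr};
    for (int c = 0; c < 2; ++c) {
      double cwp = 0, cwn = 0;
      for (size_t k = 0; k < children[c]->idx.size(); ++k) {
        int i = children[c]->idx[k];
        if (y[i] > 0) cwp += w[i]; else cwn += w[i];
      }
      tr.feature.push_back(-1);
      tr.threshold.push_back(0);
      tr.left.push_back(-1);
      tr.right.push_back(-1);
      tr.score.push_back((cwp + cwn) > 0 ? (cwp - cwn) / (cwp + cwn) : 0.0);
    }
    ++splits;
    best_split(X, y, w, chl);
    if (chl.best_feat >= 0) open.push_back(chl);
    best_split(X, y, w, chr);
    if (chr.best_feat >= 0) open.push_back(chr);
  }
  return tr;
}

static inline double tree_score_row(const Tree &tr, const NumericMatrix &X,
                                    int i) {
  int node = 0;
  while (tr.feature[node] >= 0)
    node = (X(i, tr.feature[node]) < tr.threshold[node]) ? tr.left[node]
                                                         : tr.right[node];
  return tr.score[node];
}

static List tree_to_list(const Tree &tr) {
  return List::create(_["feature"] = wrap(tr.feature),
                      _["threshold"] = wrap(tr.threshold),
                      _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
                      _["score"] = wrap(tr.score));
}

static Tree tree_from_list(List l) {
  Tree tr;
  tr.feature = as<std::vector<int> >(l["feature"]);
  tr.threshold = as<std::vector<double> >(l["threshold"]);
  tr.left = as<std::vector<int> >(l["left"]);
  tr.right = as<std::vector<int> >(l["right"]);
  tr.score = as<std::vector<double> >(l["score"]);
  return tr;
}

// [[Rcpp::export]]
List tree_fit_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                  int max_splits) {
  return tree_to_list(fit_tree(X, y, w, max_splits));
}

// [[Rcpp::export]]
NumericVector tree_predict_cpp(List tree, NumericMatrix X) {
  Tree tr = tree_from_list(tree);
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tree_score_row(tr, X, i);
  return out;
}

// ---------------------------------------------------------------------
// RobustBoost: continuous-time boost-by-majority. Each example carries a
// real margin m_i; the algorithm runs in self-time t from 0 to 1 with
//   sigma(t)^2 = (sigma_f^2 + 1) e^{2(1-t)} - 1
//   mu(t)     = (theta - 2 rho) e^{1-t} + 2 rho
// and weighs example i by exp(-(m_i - mu(t))^2 / (2 sigma(t)^2)). rho is
// set so the average initial potential equals the error goal epsilon. At
// each cycle a weak tree is fitted to the current weights and a joint
// root search finds the time step dt > 0 and vote weight alpha that zero
// the weighted correlation at t + dt while conserving average potential.
// ---------------------------------------------------------------------

static inline double erf_fast(double x) { return std::erf(x); }

struct RBState {
  double sigma_f, theta, rho;
  double sigma2(double t) const {
    return (sigma_f * sigma_f + 1.0) * std::exp(2.0 * (1.0 - t)) - 1.0;
  }
  double mu(double t) const {
    return (theta - 2.0 * rho) * std::exp(1.0 - t) + 2.0 * rho;
  }
  double weight(double m, double t) const {
    double s2 = sigma2(t);
    double d = m - mu(t);
    return std::exp(-d * d / (2.0 * s2));
  }
  double potential(double m, double t) const {
    double s = std::sqrt(sigma2(t));
    return 0.5 * (1.0 - erf_fast((m - mu(t)) / (std::sqrt(2.0) * s)));
  }
};

// weighted correlation of the weak hypothesis at margins m + alpha*yh,
// time t (unnormalized)
static double rb_corr(const RBState &st, const std::vector<double> &m,
                      const std::vector<double> &yh, double alpha, double t) {
  double s = 0;
  for (size_t i = 0; i < m.size(); ++i)
    s += st.weight(m[i] + alpha * yh[i], t) * yh[i];
  return s;
}

static double rb_potsum(const RBState &st, const std::vector<double> &m,
                        const std::vector<double> &yh, double alpha,
                        double t) {
  double s = 0;
  for (size_t i = 0; i < m.size(); ++i)
    s += st.potential(m[i] + alpha * yh[i], t);
  return s;
}

// solve rb_corr(alpha) = 0 for alpha >= 0 at fixed time, bisection with
// bracket doubling
static double rb_solve_alpha(const RBState &st, const std::vector<double> &m,
                             const std::vector<double> &yh, double t) {
  double lo = 0.0, flo = rb_corr(st, m, yh, 0.0, t);
  if (flo <= 0) return 0.0;
  double hi = 0.25;
  double fhi = rb_corr(st, m, yh, hi, t);
  int guard = 0;
  while (fhi > 0 && guard++ < 12) {
    hi *= 2.0;
    fhi = rb_corr(st, m, yh, hi, t);
  }
  if (fhi > 0) return hi;  // cap; pathological
  for (int it = 0; it < 50; ++it) {
    double mid = 0.5 * (lo + hi);
    double fm = rb_corr(st, m, yh, mid, t);
    if (fm > 0) { lo = mid; flo = fm; } else { hi = mid; fhi = fm; }
    if (hi - lo < 1e-9 * (1.0 + hi)) break;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
List robustboost_cpp(NumericMatrix X, IntegerVector y, double error_goal,
                     double sigma_f, double theta, int max_cycles,
                     int max_splits) {
  int n = X.nrow();
  RBState st;
  st.sigma_f = sigma_f;
  st.theta = theta;
  double s0 = std::sqrt(st.sigma2(0.0));
  // rho from requiring the average potential at (m=0, t=0) to equal the
  // error goal: erfinv via the normal quantile
  double erfinv = R::qnorm((1.0 - 2.0 * error_goal + 1.0) / 2.0, 0.0, 1.0,
                           1, 0) / std::sqrt(2.0);
  st.rho = (std::exp(1.0) * theta + std::sqrt(2.0) * s0 * erfinv) /
           (2.0 * (std::exp(1.0) - 1.0));

  std::vector<double> margins(n, 0.0), yh(n);
  std::vector<Tree> trees;
  std::vector<double> alphas, tpath, dts;
  double t = 0.0;
  bool hit_time = false;
  NumericVector w(n);
  IntegerVector yy(y);

  int cycle = 0;
  for (cycle = 0; cycle < max_cycles; ++cycle) {
    double wsum = 0;
    for (int i = 0; i < n; ++i) {
      w[i] = st.weight(margins[i], t);
      wsum += w[i];
    }
    if (wsum < 1e-300) break;
    Tree tr = fit_tree(X, yy, w, max_splits);
    double edge = 0;
    for (int i = 0; i < n; ++i) {
      double h = tree_score_row(tr, X, i) > 0 ? 1.0 : -1.0;
      yh[i] = h * y[i];
      edge += w[i] * yh[i];
    }
    if (edge / wsum <= 1e-9) break;  // no usable edge left

    double pot0 = rb_potsum(st, margins, yh, 0.0, t);
    // potential-conservation residual as a function of dt (alpha solved
    // inside): g(dt) = potsum(m + alpha(dt) yh, t+dt) - potsum(m, t)
    double tmax = 1.0 - t;
    double alpha_hi = rb_solve_alpha(st, margins, yh, t + tmax);
    double g_hi = rb_potsum(st, margins, yh, alpha_hi, t + tmax) - pot0;
    double dt, alpha;
    if (g_hi <= 0) {
      dt = tmax;                      // can jump straight to t = 1
      alpha = alpha_hi;
    } else {
      double lo = std::min(tmax, 1e-4);
      double alpha_lo = rb_solve_alpha(st, margins, yh, t + lo);
      double g_lo = rb_potsum(st, margins, yh, alpha_lo, t + lo) - pot0;
      int tries = 0;
      while (g_lo > 0 && tries++ < 20) {  // halve the target step, retry
        lo *= 0.5;
        alpha_lo = rb_solve_alpha(st, margins, yh, t + lo);
        g_lo = rb_potsum(st, margins, yh, alpha_lo, t + lo) - pot0;
      }
      if (g_lo > 0) break;  // cannot advance self-time: stop early
      double hi = tmax;
      for (int it = 0; it < 40; ++it) {
        double mid = 0.5 * (lo + hi);
        double a_mid = rb_solve_alpha(st, margins, yh, t + mid);
        double g_mid = rb_potsum(st, margins, yh, a_mid, t + mid) - pot0;
        if (g_mid <= 0) lo = mid; else hi = mid;
        if (hi - lo < 1e-7) break;
      }
      dt = lo;
      alpha = rb_solve_alpha(st, margins, yh, t + dt);
    }
    if (alpha <= 0 || dt <= 0) break;
    for (int i = 0; i < n; ++i) margins[i] += alpha * yh[i];
    t += dt;
    trees.push_back(tr);
    alphas.push_back(alpha);
    tpath.push_back(t);
    dts.push_back(dt);
    if (t >= 1.0 - 1e-9) { hit_time = true; break; }
  }

  List tlist(trees.size());
  for (size_t k = 0; k < trees.size(); ++k) tlist[k] = tree_to_list(trees[k]);
  return List::create(_["trees"] = tlist, _["alphas"] = wrap(alphas),
                      _["t_path"] = wrap(tpath), _["dt"] = wrap(dts),
                      _["rho"] = st.rho, _["self_time"] = t,
                      _["hit_time"] = hit_time,
                      _["n_cycles"] = (int)trees.size());
}

// Discrete AdaBoost with the same weak learner, kept as a comparator
// behind the same ensemble interface.
// [[Rcpp::export]]
List adaboost_cpp(NumericMatrix X, IntegerVector y, int max_cycles,
                  int max_splits) {
  int n = X.nrow();
  std::vector<double> wv(n, 1.0 / n);
  std::vector<Tree> trees;
  std::vector<double> alphas;
  NumericVector w(n);
  for (int cycle = 0; cycle < max_cycles; ++cycle) {
    for (int i = 0; i < n; ++i) w[i] = wv[i];
    Tree tr = fit_tree(X, y, w, max_splits);
    double err = 0, tot = 0;
    std::vector<double> h(n);
    for (int i = 0; i < n; ++i) {
      h[i] = tree_score_row(tr, X, i) > 0 ? 1.0 : -1.0;
      tot += wv[i];
      if (h[i] * y[i] < 0) err += wv[i];
    }
    err /= tot;
    if (err >= 0.5) break;
    double e = std::max(err, 1e-10);
    double alpha = 0.5 * std::log((1.0 - e) / e);
    trees.push_back(tr);
    alphas.push_back(alpha);
    if (err <= 0) break;
    double z = 0;
    for (int i = 0; i < n; ++i) {
      wv[i] *= std::exp(-alpha * y[i] * h[i]);
      z += wv[i];
    }
    for (int i = 0; i < n; ++i) wv[i] /= z;
  }
  List tlist(trees.size());
  for (size_t k = 0; k < trees.size(); ++k) tlist[k] = tree_to_list(trees[k]);
  return List::create(_["trees"] = tlist, _["alphas"] = wrap(alphas),
                      _["n_cycles"] = (int)trees.size());
}

// Ensemble score: weighted vote over the sign predictions of the trees.
// [[Rcpp::export]]
NumericVector ensemble_score_cpp(List trees, NumericVector alphas,
                                 NumericMatrix X) {
  int n = X.nrow(), K = trees.size();
  NumericVector out(n);
  for (int k = 0; k < K; ++k) {
    Tree tr = tree_from_list(trees[k]);
    double a = alphas[k];
    for (int i = 0; i < n; ++i)
      out[i] += a * (tree_score_row(tr, X, i) > 0 ? 1.0 : -1.0);
  }
  return out;
}
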