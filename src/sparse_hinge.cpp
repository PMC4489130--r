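#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// L1-regularized squared-hinge linear classification by cyclic coordinate
// descent with exact one-dimensional minimization. Objective:
//   F(w, b) = cost * sum_i max(0, 1 - y_i (x_i . w + b))^2 + eps * ||w||_1
// The intercept b is unpenalized. Along one coordinate the objective is a
// convex piecewise quadratic, so its derivative is piecewise linear and
// monotone non-decreasing: the exact minimizer is found by a safeguarded
// Newton search on the (sub)derivative, and every update decreases F.
// Sweeps alternate between the full coordinate set and the active (non-zero)
// set, glmnet-style. Deterministic for fixed inputs; the cyclic update order
// makes the solver assign weight to the first of a set of duplicated columns
// and leave the later duplicates at zero.

// derivative (and slope) of the smooth loss along coordinate step d:
//   dL/dd = -2c * sum_{i: v_i - s_i d > 0} u_i s_i (v_i - s_i d)
// with v_i = 1 - margin_i, s_i = y_i x_ij and per-sample weights u_i that
// give both classes equal total weight (matching the balanced-accuracy goal
// criterion, so that an intercept-dominated model sits at the class midpoint
// rather than echoing the majority class of an imbalanced training fold).
static inline double loss_deriv(const double* s, const double* v,
                                const double* u, int n,
                                double cost, double d, double* slope) {
  double g = 0.0, h = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = v[i] - s[i] * d;
    if (r > 0) { g += u[i] * s[i] * r; h += u[i] * s[i] * s[i]; }
  }
  if (slope) *slope = 2.0 * cost * h;
  return -2.0 * cost * g;
}

// root of the monotone piecewise-linear function loss_deriv(d) + shift,
// restricted to d >= lo (dir > 0) or d <= lo (dir < 0). Assumes the function
// has the sign of -dir at the starting point. Safeguarded Newton: each step
// is projected into the current bracket, which bisects on failure.
static double solve_root(const double* s, const double* v, const double* u,
                         int n, double cost, double shift, double start,
                         int dir) {
  double lo = start, hi = start;
  double step = 1.0;
  // expand a bracket in the search direction
  for (int guard = 0; guard < 200; ++guard) {
    double cand = start + dir * step;
    double val = loss_deriv(s, v, u, n, cost, cand, nullptr) + shift;
    if (dir > 0) {
      if (val >= 0) { hi = cand; break; }
      lo = cand;
    } else {
      if (val <= 0) { hi = cand; break; }
      lo = cand;
    }
    step *= 2.0;
  }
  // now the root lies between lo and hi (in direction dir)
  double a = std::min(lo, hi), b = std::max(lo, hi);
  double d = 0.5 * (a + b);
  for (int it = 0; it < 100; ++it) {
    if (b - a < 1e-12 * (1.0 + std::fabs(a) + std::fabs(b))) break;
    double slope;
    double val = loss_deriv(s, v, u, n, cost, d, &slope) + shift;
    if (std::fabs(val) < 1e-14) break;
    if (val < 0) a = d; else b = d;
    double dn = (slope > 0) ? d - val / slope : a - 1;  // Newton proposal
    d = (dn > a && dn < b) ? dn : 0.5 * (a + b);
  }
  return d;
}

// exact minimization of the penalized objective along coordinate j;
// returns the step d (0 when the coordinate is already optimal).
static inline double coord_step(const double* s, const double* v,
                                const double* u, int n,
                                double cost, double eps, double wj,
                                bool penalized) {
  if (penalized) {
    // subdifferential at the L1 kink d = -wj is [gk - eps, gk + eps]; the
    // slack keeps coordinates whose gradient sits exactly on the penalty
    // boundary (e.g. exact duplicates of an already-active column) at zero
    // instead of chasing rounding noise
    double slack = 1e-9 * (1.0 + eps);
    double gk = loss_deriv(s, v, u, n, cost, -wj, nullptr);
    if (gk + eps < -slack) return solve_root(s, v, u, n, cost, eps, -wj, +1);
    if (gk - eps > slack) return solve_root(s, v, u, n, cost, -eps, -wj, -1);
    return -wj;  // exact zero is optimal (may be a null step if wj == 0)
  }
  double g0 = loss_deriv(s, v, u, n, cost, 0.0, nullptr);
  if (g0 < 0) return solve_root(s, v, u, n, cost, 0.0, 0.0, +1);
  if (g0 > 0) return solve_root(s, v, u, n, cost, 0.0, 0.0, -1);
  return 0.0;
}

// core solver; X column-major (n x p); w and b are the warm start and are
// overwritten. Returns the number of coordinate sweeps used.
static int cd_core(const double* X, const double* y, int n, int p,
                   double cost, double eps, double* w, double* b,
                   int max_sweeps, double tol) {
  std::vector<double> v(n), s(n);
  // class-balanced sample weights: each class carries total weight n / 2
  std::vector<double> u(n);
  {
    int npos = 0;
    for (int i = 0; i < n; ++i) if (y[i] > 0) ++npos;
    int nneg = n - npos;
    for (int i = 0; i < n; ++i) {
      u[i] = (y[i] > 0) ? 0.5 * n / npos : 0.5 * n / nneg;
    }
  }
  for (int i = 0; i < n; ++i) {
    double f = *b;
    for (int j = 0; j < p; ++j) {
      if (w[j] != 0.0) f += X[(size_t)j * n + i] * w[j];
    }
    v[i] = 1.0 - y[i] * f;
  }
  auto do_sweep = [&](const std::vector<int>& coords) {
    double max_step = 0.0;
    for (int j : coords) {
      const bool penalized = j < p;
      const double* xj = penalized ? X + (size_t)j * n : nullptr;
      for (int i = 0; i < n; ++i) s[i] = penalized ? y[i] * xj[i] : y[i];
      double wj = penalized ? w[j] : *b;
      double d = coord_step(s.data(), v.data(), u.data(), n, cost, eps, wj, penalized);
      if (d == 0.0) continue;
      for (int i = 0; i < n; ++i) v[i] -= s[i] * d;
      if (penalized) {
        w[j] = (d == -wj) ? 0.0 : wj + d;
      } else {
        *b = wj + d;
      }
      max_step = std::max(max_step, std::fabs(d));
    }
    return max_step;
  };

  std::vector<int> all(p + 1);
  for (int j = 0; j <= p; ++j) all[j] = j;

  // objective, recomputed from the maintained v (O(n + p))
  auto objective = [&]() {
    double loss = 0.0, l1 = 0.0;
    for (int i = 0; i < n; ++i) if (v[i] > 0) loss += u[i] * v[i] * v[i];
    for (int j = 0; j < p; ++j) l1 += std::fabs(w[j]);
    return cost * loss + eps * l1;
  };

  // stop when a sweep neither moves any coordinate appreciably nor improves
  // the objective beyond a relative stall tolerance: near-collinear features
  // produce long flat valleys where step sizes decay very slowly while the
  // objective is already converged
  double fprev = objective();
  int sweeps = 0;
  while (sweeps < max_sweeps) {
    ++sweeps;
    double step_full = do_sweep(all);
    double fcur = objective();
    bool stalled = fprev - fcur < tol * (1.0 + std::fabs(fcur));
    fprev = fcur;
    if (step_full < tol || stalled) break;
    // iterate on the active set (non-zero coordinates + intercept)
    std::vector<int> active;
    for (int j = 0; j < p; ++j) if (w[j] != 0.0) active.push_back(j);
    active.push_back(p);
    while (sweeps < max_sweeps) {
      ++sweeps;
      double step = do_sweep(active);
      double f2 = objective();
      bool stalled2 = fprev - f2 < tol * (1.0 + std::fabs(f2));
      fprev = f2;
      if (step < tol || stalled2) break;
    }
  }
  return sweeps;
}

// [[Rcpp::export(name = ".sparse_hinge_fit")]]
List sparse_hinge_fit(NumericMatrix x, NumericVector y, double cost,
                      double eps, int max_sweeps = 2000, double tol = 1e-9) {
  const int n = x.nrow(), p = x.ncol();
  std::vector<double> w(p, 0.0);
  double b = 0.0;
  int sweeps = cd_core(REAL(x), REAL(y), n, p, cost, eps, w.data(), &b,
                       max_sweeps, tol);
  int npos = 0;
  for (int i = 0; i < n; ++i) if (y[i] > 0) ++npos;
  double l1 = 0.0, loss = 0.0;
  NumericVector wout(p);
  for (int j = 0; j < p; ++j) { wout[j] = w[j]; l1 += std::fabs(w[j]); }
  for (int i = 0; i < n; ++i) {
    double f = b;
    for (int j = 0; j < p; ++j) f += x(i, j) * w[j];
    double v = 1.0 - y[i] * f;
    double ui = (y[i] > 0) ? 0.5 * n / npos : 0.5 * n / (n - npos);
    if (v > 0) loss += ui * v * v;
  }
  return List::create(_["weights"] = wout, _["intercept"] = b,
                      _["objective"] = cost * loss + eps * l1,
                      _["sweeps"] = sweeps);
}

// All leave-two-out fits of a nested leave-one-out cross-validation over a
// (cost, epsilon) grid. The inner model of outer fold i and inner fold j is
// trained on all samples except {i, j} — identical for (i, j) and (j, i) —
// so each unordered pair is fit once and scored on both held-out samples.
// Training columns are standardized (mean, sd with n-1 denominator) on the
// n-2 training rows only; fits are warm-started along the pair sequence and,
// at the start of each cost, down the epsilon path. Returns, for every
// (outer, inner, cost, epsilon) combination, the inner held-out decision
// score and the number of selected features.
// [[Rcpp::export(name = ".sparse_hinge_nested_cv")]]
List sparse_hinge_nested_cv(NumericMatrix x, NumericVector y,
                            NumericVector costs, NumericVector epsilons,
                            int max_sweeps = 300, double tol = 1e-7) {
  const int n = x.nrow(), p = x.ncol();
  const int nc = costs.size(), ne = epsilons.size();

  // epsilon processed in decreasing order for warm starting
  std::vector<int> eord(ne);
  for (int e = 0; e < ne; ++e) eord[e] = e;
  std::sort(eord.begin(), eord.end(), [&](int a, int bb) {
    return epsilons[a] > epsilons[bb];
  });

  NumericVector score((size_t)n * n * nc * ne);
  IntegerVector nsel((size_t)n * n * nc * ne);
  const int ntr = n - 2;

  std::vector<double> Xtr((size_t)ntr * p), ytr(ntr), xi(p), xj(p);
  // warm starts are used only along the epsilon path within one pair and
  // cost: every model in the chain is trained on the same n-2 rows, so no
  // information about either held-out sample can leak through the
  // initialization of a capped solve
  std::vector<double> w(p);

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int r = 0;
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        for (int q = 0; q < p; ++q) Xtr[(size_t)q * ntr + r] = x(k, q);
        ytr[r] = y[k];
        ++r;
      }
      for (int q = 0; q < p; ++q) {
        double m = 0.0;
        for (int k = 0; k < ntr; ++k) m += Xtr[(size_t)q * ntr + k];
        m /= ntr;
        double ss = 0.0;
        for (int k = 0; k < ntr; ++k) {
          double cdev = Xtr[(size_t)q * ntr + k] - m;
          ss += cdev * cdev;
        }
        double s = std::sqrt(ss / (ntr - 1));
        if (s == 0) s = 1.0;
        for (int k = 0; k < ntr; ++k) {
          Xtr[(size_t)q * ntr + k] = (Xtr[(size_t)q * ntr + k] - m) / s;
        }
        xi[q] = (x(i, q) - m) / s;
        xj[q] = (x(j, q) - m) / s;
      }
      for (int c = 0; c < nc; ++c) {
        std::fill(w.begin(), w.end(), 0.0);
        double b = 0.0;
        for (int e = 0; e < ne; ++e) {
          int eidx = eord[e];
          cd_core(Xtr.data(), ytr.data(), ntr, p, costs[c], epsilons[eidx],
                  w.data(), &b, max_sweeps, tol);
          double fi = b, fj = b;
          int k = 0;
          for (int q = 0; q < p; ++q) {
            fi += xi[q] * w[q];
            fj += xj[q] * w[q];
            if (w[q] != 0.0) ++k;
          }
          // outer i / inner j sees score of j; outer j / inner i sees i
          size_t base_ij = (((size_t)i * n + j) * nc + c) * ne + eidx;
          size_t base_ji = (((size_t)j * n + i) * nc + c) * ne + eidx;
          score[base_ij] = fj;
          score[base_ji] = fi;
          nsel[base_ij] = k;
          nsel[base_ji] = k;
        }
      }
    }
  }
  return List::create(_["score"] = score, _["n_selected"] = nsel);
}
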