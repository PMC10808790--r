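// Hartigan & Hartigan's dip statistic, computed from the definition:
//
//   dip(F_n) = inf { sup_x |F_n(x) - G(x)| : G a unimodal CDF },
//
// where a unimodal CDF is convex up to its mode, concave after it, and
// may jump only at the mode.  For a candidate sup-distance d the
// existence of such a G is a finite geometric feasibility problem:
//
//  * at each distinct data value u_j, with the cumulative ECDF stepping
//    from top_j = c_{j-1}/n to bot_j = c_j/n, any admissible G must
//    pass through the corridor [bot_j - d, top_j + d] (the lower end
//    binds just right of u_j, the upper end just left of it);
//  * a convex branch passes through a set of corridors iff the lower
//    convex hull of the corridor tops stays above the corridor
//    bottoms;
//  * with the mode at m, the convex branch must additionally reach m
//    without rising above the local ECDF band: chords from corridor
//    tops to the anchor (m, level + d) must clear intermediate
//    corridor bottoms, which bounds m from above.  Because any chord
//    from a hull point to the anchor lies above the anchored hull, the
//    binding chord always emanates from a prefix-hull vertex, so the
//    reach is maintained incrementally with per-vertex minima;
//  * the exit value of the convex branch at the mode (a maximum of
//    chord extrapolations through corridor top/bottom pairs) must not
//    exceed the entry value of the concave branch.  Both are maxima of
//    finitely many lines in m; infeasibility over a mode window is
//    certified by sweeping the window with per-line-pair positivity
//    intervals;
//  * the concave side reuses the convex machinery on the mirrored
//    sample via G~(x) = 1 - G(-x).
//
// All conditions relax monotonically in d; the dip is found by
// bisection on d.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Side {
  std::vector<double> u;    // distinct values, increasing
  std::vector<double> top;  // ECDF just below the value: c_{j-1}/n
  std::vector<double> bot;  // ECDF at the value:          c_j/n
};

// Largest s in 0..K such that a nondecreasing convex function can pass
// through corridors [bot_j - d, top_j + d] for j = 0..s-1.
int prefix_feasible(const Side& S, double d) {
  const int K = (int) S.u.size();
  std::vector<int> st;
  st.reserve(K);
  for (int j = 0; j < K; ++j) {
    if (S.bot[j] - S.top[j] > 2.0 * d) return j;      // empty corridor
    while ((int) st.size() >= 2) {
      int a = st[st.size() - 2], b = st[st.size() - 1];
      double cr = (S.u[j] - S.u[a]) * (S.top[b] - S.top[a]) -
                  (S.u[b] - S.u[a]) * (S.top[j] - S.top[a]);
      if (cr >= 0) st.pop_back(); else break;         // b on/above segment a->j
    }
    if (!st.empty()) {
      int a = st.back();
      double slope = (S.top[j] - S.top[a]) / (S.u[j] - S.u[a]);
      for (int i = a + 1; i < j; ++i) {
        double hull = S.top[a] + slope * (S.u[i] - S.u[a]);
        if (S.bot[i] - hull > 2.0 * d) return j;      // prefix j+1 infeasible
      }
    }
    st.push_back(j);
  }
  return K;
}

// Anchored reach for every prefix up to smax, in one incremental pass.
// reach_gap[s]  (1 <= s <= min(smax, K-1)): largest anchor position m for
//   prefix s at anchor level bot[s-1] (mode in the gap right of u_{s-1});
// reach_pt[j]   (0 <= j <= min(smax, K-1)): same for prefix j at anchor
//   level top[j] (mode at the data value u_j).
// A chord from hull vertex h through intermediate point i bounds m by
//   u_h + (lev - top_h) * w,  w = (u_i - u_h)/(bot_i - 2d - top_h),
// and only the smallest w per vertex can bind, whatever the level.
void build_reach(const Side& S, double d, int smax,
                 std::vector<double>& reach_gap,
                 std::vector<double>& reach_pt) {
  const int K = (int) S.u.size();
  reach_gap.assign(K, INF);
  reach_pt.assign(K, INF);
  std::vector<int> st;
  std::vector<double> minw;
  st.reserve(K); minw.reserve(K);
  const int jmax = std::min(smax, K - 1);
  for (int j = 0; j <= jmax; ++j) {
    double mp = INF, mg = INF;
    for (size_t t = 0; t < st.size(); ++t) {
      if (minw[t] < INF) {
        int h = st[t];
        double v = S.u[h] + (S.top[j] - S.top[h]) * minw[t];
        if (v < mp) mp = v;
        if (j >= 1) {
          double g = S.u[h] + (S.bot[j - 1] - S.top[h]) * minw[t];
          if (g < mg) mg = g;
        }
      }
    }
    reach_pt[j] = mp;
    if (j >= 1) reach_gap[j] = mg;
    // point j now becomes an intermediate obstacle for current vertices
    for (size_t t = 0; t < st.size(); ++t) {
      double den = S.bot[j] - 2.0 * d - S.top[st[t]];
      if (den > 0) {
        double w = (S.u[j] - S.u[st[t]]) / den;
        if (w < minw[t]) minw[t] = w;
      }
    }
    // and joins the lower hull of the corridor tops
    while ((int) st.size() >= 2) {
      int a = st[st.size() - 2], b = st[st.size() - 1];
      double cr = (S.u[j] - S.u[a]) * (S.top[b] - S.top[a]) -
                  (S.u[b] - S.u[a]) * (S.top[j] - S.top[a]);
      if (cr >= 0) { st.pop_back(); minw.pop_back(); } else break;
    }
    st.push_back(j);
    minw.push_back(INF);
  }
}

// Exit-chord slopes: eslope[q] = max over p<q of
// (bot_q - top_p - 2d)/(u_q - u_p); the smallest exit value of the
// convex branch of prefix s at position m is
//   max_{1<=q<s} bot_q - d + eslope[q]*(m - u_q).
// Slope from an external point on the right is maximized on the lower
// hull of (u_p, top_p), along which it is unimodal (ternary search,
// with a local scan for near-collinear plateaus).
struct ExitLines {
  bool ready = false;
  std::vector<double> eslope;
  void build(const Side& S, double d) {
    const int K = (int) S.u.size();
    eslope.assign(K, -INF);
    std::vector<int> hull;                 // lower hull of (u_p, top_p)
    hull.reserve(K);
    for (int q = 1; q < K; ++q) {
      int p = q - 1;
      while ((int) hull.size() >= 2) {
        int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
        double cr = (S.u[p] - S.u[a]) * (S.top[b] - S.top[a]) -
                    (S.u[b] - S.u[a]) * (S.top[p] - S.top[a]);
        if (cr >= 0) hull.pop_back(); else break;     // keep lower hull
      }
      hull.push_back(p);
      auto sl = [&](int t) {
        int v = hull[t];
        return (S.bot[q] - 2.0 * d - S.top[v]) / (S.u[q] - S.u[v]);
      };
      int loi = 0, hii = (int) hull.size() - 1;
      if (hii - loi <= 32) {
        double best = -INF;
        for (int t = loi; t <= hii; ++t) best = std::max(best, sl(t));
        eslope[q] = best;
      } else {
        while (hii - loi > 8) {
          int m1 = loi + (hii - loi) / 3, m2 = hii - (hii - loi) / 3;
          if (sl(m1) < sl(m2)) loi = m1 + 1; else hii = m2;
        }
        double best = -INF;
        for (int t = std::max(0, loi - 2);
             t <= std::min((int) hull.size() - 1, hii + 2); ++t)
          best = std::max(best, sl(t));
        eslope[q] = best;
      }
    }
    ready = true;
  }
  double line(const Side& S, int q, double d, double m) const {
    return S.bot[q] - d + eslope[q] * (m - S.u[q]);
  }
  double eval(const Side& S, int s, double d, double m, int& wq) const {
    double v = -INF;
    for (int q = 1; q < s; ++q) {
      double y = line(S, q, d, m);
      if (y > v) { v = y; wq = q; }
    }
    return v;
  }
};

struct Feas {
  const Side& L;
  const Side& R;
  double d;
  int K;
  ExitLines exL, exR;
  int cwL = -1, cwR = -1;                  // cached refuting line pair

  Feas(const Side& l, const Side& r, double dd)
    : L(l), R(r), d(dd), K((int) l.u.size()) {}

  void need_lines() {
    if (!exL.ready) exL.build(L, d);
    if (!exR.ready) exR.build(R, d);
  }

  // Is there m in [mA, mB] with exitL(m) + exitR(-m) <= 1?  The gap
  // g(m) is a sum of two maxima of lines; any line pair lower-bounds
  // it, and a pair positive across an interval certifies g > 0 there.
  bool cross_ok(int sL, int sR, double mA, double mB) {
    if (sL < 2 || sR < 2) return true;     // a side with no chord pairs
    need_lines();
    if (cwL >= 1 && cwL < sL && cwR >= 1 && cwR < sR) {
      double ga = exL.line(L, cwL, d, mA) + exR.line(R, cwR, d, -mA) - 1.0;
      double gb = exL.line(L, cwL, d, mB) + exR.line(R, cwR, d, -mB) - 1.0;
      if (ga > 0 && gb > 0) return false;  // pair-sum is linear in m
    }
    double m = mA;
    int qa = -1, qb = -1;
    bool refuted = false;
    for (int it = 0; it < 40; ++it) {
      double g = exL.eval(L, sL, d, m, qa) + exR.eval(R, sR, d, -m, qb) - 1.0;
      if (g <= 0) return true;
      // active pair-sum: value g at m, slope eslope_L[qa] - eslope_R[qb];
      // it stays positive up to its root — skip that stretch
      double sl = exL.eslope[qa] - exR.eslope[qb];
      if (sl >= 0) { refuted = true; break; }  // positive, nondecreasing: done
      double m2 = m - g / sl;              // root of the active pair-sum
      if (m2 >= mB) {
        double gB = exL.eval(L, sL, d, mB, qa) + exR.eval(R, sR, d, -mB, qb) - 1.0;
        if (gB <= 0) return true;
        refuted = true;
        break;
      }
      if (m2 <= m) { refuted = true; break; }  // numerical safety
      m = m2;
    }
    if (!refuted) {
      // many short positivity stretches: g is convex piecewise linear,
      // so certify min > 0 by golden section on the remaining interval
      const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
      double a = m, b = mB;
      double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
      int w1, w2, w3, w4;
      double f1 = exL.eval(L, sL, d, x1, w1) + exR.eval(R, sR, d, -x1, w2) - 1.0;
      double f2 = exL.eval(L, sL, d, x2, w3) + exR.eval(R, sR, d, -x2, w4) - 1.0;
      for (int it = 0; it < 90 && b - a > 1e-14 * (1.0 + std::fabs(b)); ++it) {
        if (f1 <= 0 || f2 <= 0) return true;
        if (f1 <= f2) {
          b = x2; x2 = x1; f2 = f1;
          x1 = b - gr * (b - a);
          f1 = exL.eval(L, sL, d, x1, w1) + exR.eval(R, sR, d, -x1, w2) - 1.0;
        } else {
          a = x1; x1 = x2; f1 = f2;
          x2 = a + gr * (b - a);
          f2 = exL.eval(L, sL, d, x2, w3) + exR.eval(R, sR, d, -x2, w4) - 1.0;
        }
      }
      if (f1 <= 0 || f2 <= 0) return true;
      qa = (f1 < f2) ? w1 : w3;
      qb = (f1 < f2) ? w2 : w4;
    }
    cwL = qa; cwR = qb;
    return false;
  }
};

bool feasible(const Side& L, const Side& R, double d) {
  const int K = (int) L.u.size();
  int SL = prefix_feasible(L, d);
  int SR = prefix_feasible(R, d);
  if (SL == K || SR == K) return true;     // mode beyond the data
  if (SL + SR < K - 1) return false;       // no split can cover the sample

  std::vector<double> mlg, mlp, mrg_m, mrp_m;
  build_reach(L, d, SL, mlg, mlp);
  build_reach(R, d, SR, mrg_m, mrp_m);
  Feas F(L, R, d);

  int lo = std::max(1, K - SR), hi = std::min(SL, K - 1);
  for (int s = lo; s <= hi; ++s) {         // mode in gap (u_{s-1}, u_s)
    double mA = L.u[s - 1], mB = L.u[s];
    double ML = mlg[s];
    if (ML < mA) continue;
    double MR = -mrg_m[K - s];
    if (MR > mB) continue;
    double wA = std::max(mA, MR), wB = std::min(mB, ML);
    if (wA <= wB && F.cross_ok(s, K - s, wA, wB)) return true;
  }
  for (int j = 0; j < K; ++j) {            // mode at the data value u_j
    if (j > SL || (K - 1 - j) > SR) continue;
    if (mlp[j] < L.u[j]) continue;
    if (mrp_m[K - 1 - j] < -L.u[j]) continue;
    double vmin = L.top[j] - d, vmax = L.bot[j] + d;
    if (j >= 2 || K - 1 - j >= 2) {
      F.need_lines();
      int wq;
      if (j >= 2)
        vmin = std::max(vmin, F.exL.eval(L, j, d, L.u[j], wq));
      if (K - 1 - j >= 2)
        vmax = std::min(vmax, 1.0 - F.exR.eval(R, K - 1 - j, d, -L.u[j], wq));
    }
    if (vmin <= vmax) return true;
  }
  return false;
}

} // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(Rcpp::NumericVector x_sorted, double tol = 1e-13) {
  const int n = x_sorted.size();
  if (n < 2) Rcpp::stop("dip statistic needs at least 2 observations");
  std::vector<double> u;
  std::vector<double> cc;
  for (int i = 0; i < n; ++i) {
    if (u.empty() || x_sorted[i] > u.back()) { u.push_back(x_sorted[i]); cc.push_back(0); }
    cc.back() += 1.0;
  }
  const int K = (int) u.size();
  if (K == 1) return 0.0;                  // degenerate sample
  Side L, R;
  L.u = u;
  L.top.resize(K); L.bot.resize(K);
  double run = 0.0;
  for (int j = 0; j < K; ++j) {
    L.top[j] = run / n;
    run += cc[j];
    L.bot[j] = run / n;
  }
  R.u.resize(K); R.top.resize(K); R.bot.resize(K);
  for (int j = 0; j < K; ++j) {
    R.u[j] = -L.u[K - 1 - j];
    R.top[j] = 1.0 - L.bot[K - 1 - j];
    R.bot[j] = 1.0 - L.top[K - 1 - j];
  }
  double lo = 0.0, hi = 0.25;
  while (!feasible(L, R, hi) && hi < 2.0) hi *= 2.0;  // defensive; dip <= 1/4
  for (int it = 0; it < 100 && hi - lo > tol; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(L, R, mid)) hi = mid; else lo = mid;
  }
  return hi;
}
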