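#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Hartigan's dip statistic: the minimum over unimodal CDFs G of
// sup_x |F_n(x) - G(x)|.  A unimodal CDF is convex up to its mode and
// concave after it; an atom is allowed at the mode.
//
// For a candidate mode m the smallest feasible band half-width rho is
// governed by three requirements:
//   (1) a convex branch within the band over the jump corners left of m
//       (read off a greatest-convex-minorant construction),
//   (2) a concave branch within the band right of m (least concave
//       majorant, mirrored),
//   (3) the branches must join monotonically at the mode: the smallest
//       value the convex branch can take at m (forced up by chords from
//       an upper corner on the left through a lower corner nearer m)
//       must not exceed the largest value the concave branch can start
//       from (forced down symmetrically).
// (1) and (2) scale linearly in rho, so they are solved in closed form;
// (3) couples nonlinearly and is solved by bisection on rho, but only
// for candidate modes whose (1)-(2) bound could still win (the branch
// values are checked once at the bound first, which usually suffices).
// rho_L is nondecreasing and rho_R nonincreasing in the mode location,
// so the uncoupled bound is quasiconvex over modes; candidates are data
// points and gaps, with golden-section refinement inside the best gaps.

namespace {

struct SidePts {
  // constraint corners for one branch: x positions, lower heights
  // (ECDF value the branch must reach from below) and upper heights
  // (value it must stay under), all on the unshifted ECDF scale; the
  // band adds -rho / +rho.
  std::vector<double> x, low0, up0;
};

// max over queries of (qy - lower_convex_hull(points)(qx));
// px strictly increasing, qx nondecreasing.
double max_above_lower_hull(const std::vector<double>& px,
                            const std::vector<double>& py,
                            const std::vector<double>& qx,
                            const std::vector<double>& qy) {
  const int n = (int)px.size();
  if (n == 0 || qx.empty()) return 0.0;
  std::vector<int> h;
  h.reserve(n);
  for (int i = 0; i < n; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      double cr = (px[b] - px[a]) * (py[i] - py[a]) -
                  (py[b] - py[a]) * (px[i] - px[a]);
      if (cr <= 0) h.pop_back(); else break;
    }
    h.push_back(i);
  }
  double best = 0.0;
  int seg = 0;
  for (size_t j = 0; j < qx.size(); ++j) {
    double X = qx[j];
    while (seg + 1 < (int)h.size() && px[h[seg + 1]] < X) ++seg;
    double hv;
    int a = h[seg];
    if (seg + 1 < (int)h.size()) {
      int b = h[seg + 1];
      hv = py[a] + (py[b] - py[a]) * (X - px[a]) / (px[b] - px[a]);
    } else {
      hv = py[a];
    }
    double d = qy[j] - hv;
    if (d > best) best = d;
  }
  return best;
}

// smallest 2*rho for which a convex branch exists through the side's
// corners (terminal included as last entry of s): the deviation of the
// ECDF's upper corners above the GCM of its lower corners.
double side_dev_left(const SidePts& s) {
  const int k = (int)s.x.size();
  if (k <= 1) return 0.0;
  std::vector<double> qx(s.x.begin(), s.x.end() - 1);
  std::vector<double> qy(s.low0.begin(), s.low0.end() - 1);
  return max_above_lower_hull(s.x, s.up0, qx, qy);
}

// mirrored (x -> -x, y -> -y) version for the concave branch.
double side_dev_right(const SidePts& s) {
  const int k = (int)s.x.size();
  if (k <= 1) return 0.0;
  std::vector<double> px(k), py(k), qx, qy;
  for (int i = 0; i < k; ++i) {
    px[i] = -s.x[k - 1 - i];
    py[i] = -s.low0[k - 1 - i];
  }
  qx.reserve(k - 1); qy.reserve(k - 1);
  for (int i = k - 1; i >= 1; --i) {
    qx.push_back(-s.x[i]);
    qy.push_back(-s.up0[i]);
  }
  return max_above_lower_hull(px, py, qx, qy);
}

// minimal value the convex branch can take at m = s.x.back(), given the
// band width rho: the largest of the lower constants (monotonicity) and
// of chords through an upper corner p and lower corner q > p, extended
// to m with slope floored at zero (convexity).  The best p for each q
// is the tangent point from (x_q, low_q) to the lower convex hull of
// the upper corners, found by ternary search on the hull as it grows.
double v_left_min(const SidePts& s, double rho) {
  const int k = (int)s.x.size();
  const double m = s.x[k - 1];
  double best = -1e100;
  std::vector<int> h;   // lower hull of (x_p, up0_p), p < q
  h.reserve(k);
  for (int q = 0; q < k; ++q) {
    double lq = s.low0[q] - rho;
    if (lq > best) best = lq;
    if (!h.empty()) {
      // max slope from hull vertices to (x_q, lq - rho... already shifted)
      int lo = 0, hi = (int)h.size() - 1;
      auto slope = [&](int idx) {
        int p = h[idx];
        return (lq - (s.up0[p] + rho)) / (s.x[q] - s.x[p]);
      };
      while (hi - lo > 2) {
        int m1 = lo + (hi - lo) / 3, m2 = hi - (hi - lo) / 3;
        if (slope(m1) < slope(m2)) lo = m1 + 1; else hi = m2 - 1;
      }
      double sl = slope(lo);
      for (int t = lo + 1; t <= hi; ++t) sl = std::max(sl, slope(t));
      if (sl > 0) {
        double val = lq + sl * (m - s.x[q]);
        if (val > best) best = val;
      }
    }
    // push (x_q, up0_q) onto the hull for later q
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      double cr = (s.x[b] - s.x[a]) * (s.up0[q] - s.up0[a]) -
                  (s.up0[b] - s.up0[a]) * (s.x[q] - s.x[a]);
      if (cr <= 0) h.pop_back(); else break;
    }
    h.push_back(q);
  }
  return best;
}

// maximal value the concave branch can start from at m = s.x.front();
// the exact mirror (x -> -x, y -> -y) of v_left_min.
double v_right_max(const SidePts& s, double rho) {
  const int k = (int)s.x.size();
  SidePts t;
  t.x.resize(k); t.low0.resize(k); t.up0.resize(k);
  for (int i = 0; i < k; ++i) {
    t.x[i] = -s.x[k - 1 - i];
    t.low0[i] = -s.up0[k - 1 - i];
    t.up0[i] = -s.low0[k - 1 - i];
  }
  return -v_left_min(t, rho);
}

inline bool junction_ok(const SidePts& L, const SidePts& R, double rho) {
  return v_left_min(L, rho) <= v_right_max(R, rho) + 1e-13;
}

// band half-width for one candidate mode, with the junction constraint.
double corrected_rho(const SidePts& L, const SidePts& R, double prune_at) {
  double base = std::max(side_dev_left(L), side_dev_right(R)) / 2.0;
  if (base >= prune_at) return base;          // cannot win; exact value moot
  if (junction_ok(L, R, base)) return base;
  double lo = base, hi = 0.30;
  for (int it = 0; it < 45; ++it) {
    double mid = 0.5 * (lo + hi);
    if (junction_ok(L, R, mid)) hi = mid; else lo = mid;
  }
  return hi;
}

struct DipCtx {
  std::vector<double> v, lo, hi;
};

// constraint sides for a mode inside gap g at position m (ECDF level
// hi[g] there), or exactly at data point j (atom absorbs the jump).
SidePts left_side_gap(const DipCtx& c, int g, double m) {
  SidePts s;
  s.x.assign(c.v.begin(), c.v.begin() + g + 1);
  s.low0.assign(c.hi.begin(), c.hi.begin() + g + 1);
  s.up0.assign(c.lo.begin(), c.lo.begin() + g + 1);
  s.x.push_back(m); s.low0.push_back(c.hi[g]); s.up0.push_back(c.hi[g]);
  return s;
}
SidePts right_side_gap(const DipCtx& c, int g, double m) {
  SidePts s;
  s.x.push_back(m); s.low0.push_back(c.hi[g]); s.up0.push_back(c.hi[g]);
  for (size_t d = g + 1; d < c.v.size(); ++d) {
    s.x.push_back(c.v[d]); s.low0.push_back(c.hi[d]); s.up0.push_back(c.lo[d]);
  }
  return s;
}
SidePts left_side_point(const DipCtx& c, int j) {
  SidePts s;
  s.x.assign(c.v.begin(), c.v.begin() + j);
  s.low0.assign(c.hi.begin(), c.hi.begin() + j);
  s.up0.assign(c.lo.begin(), c.lo.begin() + j);
  s.x.push_back(c.v[j]); s.low0.push_back(c.lo[j]); s.up0.push_back(c.lo[j]);
  return s;
}
SidePts right_side_point(const DipCtx& c, int j) {
  SidePts s;
  s.x.push_back(c.v[j]); s.low0.push_back(c.hi[j]); s.up0.push_back(c.hi[j]);
  for (size_t d = j + 1; d < c.v.size(); ++d) {
    s.x.push_back(c.v[d]); s.low0.push_back(c.hi[d]); s.up0.push_back(c.lo[d]);
  }
  return s;
}

double gap_rho(const DipCtx& c, int g, double m, double prune_at) {
  SidePts L = left_side_gap(c, g, m);
  SidePts R = right_side_gap(c, g, m);
  return corrected_rho(L, R, prune_at);
}

double point_rho(const DipCtx& c, int j, double prune_at) {
  SidePts L = left_side_point(c, j);
  SidePts R = right_side_point(c, j);
  return corrected_rho(L, R, prune_at);
}

double golden_gap(const DipCtx& c, int g, double prune_at, int iters) {
  const double gr = 0.618033988749894903;
  double a = c.v[g], b = c.v[g + 1];
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = gap_rho(c, g, x1, prune_at);
  double f2 = gap_rho(c, g, x2, prune_at);
  for (int it = 0; it < iters; ++it) {
    if (f1 <= f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = gap_rho(c, g, x1, prune_at);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = gap_rho(c, g, x2, prune_at);
    }
  }
  return std::min(f1, f2);
}

} // namespace

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x) {
  const int n = x.size();
  if (n < 2) stop("dip statistic requires at least 2 observations");
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());

  DipCtx c;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || xs[i] != xs[i - 1]) {
      c.v.push_back(xs[i]);
      c.lo.push_back((double)i / n);
      c.hi.push_back((double)(i + 1) / n);
    } else {
      c.hi.back() = (double)(i + 1) / n;
    }
  }
  const int D = (int)c.v.size();
  const double floor_dip = 0.5 / n;
  if (D == 1) return floor_dip;

  double best = 0.5;
  for (int j = 0; j < D; ++j) {
    double val = point_rho(c, j, best);
    if (val < best) best = val;
  }
  std::vector<double> gv(D - 1);
  std::vector<int> order(D - 1);
  for (int g = 0; g < D - 1; ++g) {
    gv[g] = gap_rho(c, g, 0.5 * (c.v[g] + c.v[g + 1]), best);
    if (gv[g] < best) best = gv[g];
    order[g] = g;
  }
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return gv[a] < gv[b]; });
  int refine = std::min(5, D - 1);
  for (int r = 0; r < refine; ++r) {
    double val = golden_gap(c, order[r], best, 70);
    if (val < best) best = val;
  }
  return best > floor_dip ? best : floor_dip;
}

// [[Rcpp::export]]
NumericVector dip_stat_columns(NumericMatrix m) {
  NumericVector out(m.ncol());
  for (int j = 0; j < m.ncol(); ++j) {
    NumericVector col = m(_, j);
    out[j] = dip_stat_cpp(col);
  }
  return out;
}
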