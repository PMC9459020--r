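#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Uniform grid (cell list) over circle centers. Bin side >= interaction
// cutoff so every interacting pair falls in a 3x3 bin neighbourhood.
struct Grid {
  double x0, y0, h;
  int nx, ny;
  std::vector<int> head;  // bin -> first index, -1 terminated
  std::vector<int> nxt;   // index -> next index in same bin

  Grid(const NumericVector& x, const NumericVector& y, double cutoff) {
    int n = x.size();
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; i++) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    h = std::max(cutoff, 1e-9);
    x0 = xmin; y0 = ymin;
    nx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
    head.assign((size_t)nx * ny, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; i++) {
      int b = bin(x[i], y[i]);
      nxt[i] = head[b];
      head[b] = i;
    }
  }
  inline int bin(double px, double py) const {
    int ix = std::min(nx - 1, std::max(0, (int)std::floor((px - x0) / h)));
    int iy = std::min(ny - 1, std::max(0, (int)std::floor((py - y0) / h)));
    return iy * nx + ix;
  }
};

// visit all j in the 3x3 neighbourhood of point (px, py); calls f(j)
template <typename F>
static inline void for_neighbors(const Grid& g, double px, double py, F f) {
  int ix = std::min(g.nx - 1, std::max(0, (int)std::floor((px - g.x0) / g.h)));
  int iy = std::min(g.ny - 1, std::max(0, (int)std::floor((py - g.y0) / g.h)));
  for (int dy = -1; dy <= 1; dy++) {
    int jy = iy + dy;
    if (jy < 0 || jy >= g.ny) continue;
    for (int dx = -1; dx <= 1; dx++) {
      int jx = ix + dx;
      if (jx < 0 || jx >= g.nx) continue;
      for (int j = g.head[jy * g.nx + jx]; j != -1; j = g.nxt[j]) f(j);
    }
  }
}

// One-or-more Jacobi iterations of the pairwise spring relaxation:
// overlapping pairs repel along the center line proportionally to overlap
// depth (k_rep), near pairs with gap > gap_threshold attract weakly (k_att,
// only within attract_range). Centers are clamped so circles stay inside the
// rectangular domain (or at its midline when a circle is wider than the
// domain). Stops early when max overlap <= tol.
// [[Rcpp::export]]
List relax_cpp(NumericVector x, NumericVector y, NumericVector r,
               NumericVector domain, double k_rep, double k_att,
               double gap_threshold, double attract_range,
               double tol, int max_iters, bool clamp) {
  int n = x.size();
  NumericVector xs = clone(x), ys = clone(y);
  std::vector<double> dx(n), dy(n);
  double rmax = 0.0;
  for (int i = 0; i < n; i++) rmax = std::max(rmax, r[i]);
  int iters = 0;
  double max_ov = 0.0;
  NumericVector disp_per_iter(max_iters);

  for (int it = 0; it < max_iters; it++) {
    double cutoff = 2.0 * rmax + std::max(attract_range, 0.0);
    Grid g(xs, ys, cutoff);
    std::fill(dx.begin(), dx.end(), 0.0);
    std::fill(dy.begin(), dy.end(), 0.0);
    max_ov = 0.0;
    for (int i = 0; i < n; i++) {
      double xi = xs[i], yi = ys[i], ri = r[i];
      for_neighbors(g, xi, yi, [&](int j) {
        if (j <= i) return;
        double ddx = xs[j] - xi, ddy = ys[j] - yi;
        double d2 = ddx * ddx + ddy * ddy;
        double sum = ri + r[j];
        double reach = sum + attract_range;
        if (d2 >= reach * reach) return;
        double d = std::sqrt(d2);
        double ux, uy;
        if (d > 1e-12) { ux = ddx / d; uy = ddy / d; }
        else { ux = ((i + j) % 2) ? 1.0 : -1.0; uy = 0.0; d = 1e-12; }
        double ov = sum - d;
        if (ov > 0) {
          if (ov > max_ov) max_ov = ov;
          double m = 0.5 * k_rep * ov;  // each partner moves half
          dx[i] -= m * ux; dy[i] -= m * uy;
          dx[j] += m * ux; dy[j] += m * uy;
        } else {
          double gap = -ov;
          if (gap > gap_threshold) {
            double m = 0.5 * k_att * (gap - gap_threshold);
            dx[i] += m * ux; dy[i] += m * uy;
            dx[j] -= m * ux; dy[j] -= m * uy;
          }
        }
      });
    }
    double total_disp = 0.0;
    for (int i = 0; i < n; i++) {
      xs[i] += dx[i]; ys[i] += dy[i];
      total_disp += std::sqrt(dx[i] * dx[i] + dy[i] * dy[i]);
      if (clamp) {
        // clamp circle inside domain; midline if too wide
        double lo = domain[0] + r[i], hi = domain[1] - r[i];
        if (lo > hi) { xs[i] = 0.5 * (domain[0] + domain[1]); }
        else { xs[i] = std::min(hi, std::max(lo, xs[i])); }
        lo = domain[2] + r[i]; hi = domain[3] - r[i];
        if (lo > hi) { ys[i] = 0.5 * (domain[2] + domain[3]); }
        else { ys[i] = std::min(hi, std::max(lo, ys[i])); }
      }
    }
    disp_per_iter[it] = total_disp;
    iters = it + 1;
    // recompute max overlap after the move for the stopping test
    Grid g2(xs, ys, 2.0 * rmax);
    max_ov = 0.0;
    for (int i = 0; i < n; i++) {
      double xi = xs[i], yi = ys[i], ri = r[i];
      for_neighbors(g2, xi, yi, [&](int j) {
        if (j <= i) return;
        double ddx = xs[j] - xi, ddy = ys[j] - yi;
        double d = std::sqrt(ddx * ddx + ddy * ddy);
        double ov = ri + r[j] - d;
        if (ov > max_ov) max_ov = ov;
      });
    }
    if (max_ov <= tol) break;
  }
  return List::create(_["x"] = xs, _["y"] = ys, _["iters"] = iters,
                      _["max_overlap"] = max_ov,
                      _["displacement"] = disp_per_iter[Range(0, std::max(0, iters - 1))]);
}

// Maximum pairwise overlap depth, grid-accelerated (for invariant checks on
// large epithelia; tests cross-check against an O(n^2) scan on small ones).
// [[Rcpp::export]]
double max_overlap_cpp(NumericVector x, NumericVector y, NumericVector r) {
  int n = x.size();
  if (n < 2) return 0.0;
  double rmax = 0.0;
  for (int i = 0; i < n; i++) rmax = std::max(rmax, r[i]);
  Grid g(x, y, 2.0 * rmax);
  double max_ov = 0.0;
  for (int i = 0; i < n; i++) {
    for_neighbors(g, x[i], y[i], [&](int j) {
      if (j <= i) return;
      double ddx = x[j] - x[i], ddy = y[j] - y[i];
      double d = std::sqrt(ddx * ddx + ddy * ddy);
      double ov = r[i] + r[j] - d;
      if (ov > max_ov) max_ov = ov;
    });
  }
  return max_ov;
}

// Sum of pairwise overlap depths (relaxation progress diagnostic).
// [[Rcpp::export]]
double overlap_sum_cpp(NumericVector x, NumericVector y, NumericVector r) {
  int n = x.size();
  if (n < 2) return 0.0;
  double rmax = 0.0;
  for (int i = 0; i < n; i++) rmax = std::max(rmax, r[i]);
  Grid g(x, y, 2.0 * rmax);
  double s = 0.0;
  for (int i = 0; i < n; i++) {
    for_neighbors(g, x[i], y[i], [&](int j) {
      if (j <= i) return;
      double ddx = x[j] - x[i], ddy = y[j] - y[i];
      double d = std::sqrt(ddx * ddx + ddy * ddy);
      double ov = r[i] + r[j] - d;
      if (ov > 0) s += ov;
    });
  }
  return s;
}

// Indices (1-based) of points whose center lies within `radius` of the query
// point, grid-accelerated. Excludes none; caller filters.
// [[Rcpp::export]]
IntegerVector within_radius_cpp(NumericVector x, NumericVector y,
                                double qx, double qy, double radius) {
  int n = x.size();
  std::vector<int> out;
  if (n == 0 || radius < 0) return IntegerVector(0);
  double rmax = 0.0;
  // grid bin must cover the query radius
  Grid g(x, y, std::max(radius, 1e-9));
  (void)rmax;
  double r2 = radius * radius;
  for_neighbors(g, qx, qy, [&](int j) {
    double ddx = x[j] - qx, ddy = y[j] - qy;
    if (ddx * ddx + ddy * ddy <= r2) out.push_back(j + 1);
  });
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// Contact pairs between a query subset A (1-based indices) and all points:
// center distance <= r_i + r_j + slack. Returns a two-column matrix of
// (a_index, other_index), both 1-based into the full vectors.
// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(NumericVector x, NumericVector y,
                                NumericVector r, IntegerVector a_idx,
                                double slack) {
  int n = x.size();
  std::vector<int> ai, bi;
  if (n == 0 || a_idx.size() == 0) return IntegerMatrix(0, 2);
  double rmax = 0.0;
  for (int i = 0; i < n; i++) rmax = std::max(rmax, r[i]);
  Grid g(x, y, 2.0 * rmax + std::max(slack, 0.0));
  for (int k = 0; k < a_idx.size(); k++) {
    int i = a_idx[k] - 1;
    for_neighbors(g, x[i], y[i], [&](int j) {
      if (j == i) return;
      double ddx = x[j] - x[i], ddy = y[j] - y[i];
      double d = std::sqrt(ddx * ddx + ddy * ddy);
      if (d <= r[i] + r[j] + slack) { ai.push_back(i + 1); bi.push_back(j + 1); }
    });
  }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); k++) { out(k, 0) = ai[k]; out(k, 1) = bi[k]; }
  return out;
}
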