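#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Computational geometry kernels for laminar boundary estimation and
// segmentation polygon handling. All routines are exact up to floating
// point; the corresponding brute-force oracles live in the test suite.

static const double TWOPI = 6.283185307179586476925286766559;

// ---- alpha-extreme points -------------------------------------------------
//
// A point p is alpha-extreme iff some open ball of radius alpha has p on its
// boundary and contains no other input point. Candidate ball centers form a
// circle of radius alpha around p; every other point q with |pq| < 2*alpha
// forbids an open arc of center directions. p is extreme iff the forbidden
// arcs do not cover the full circle. Coverage is decided by a circular
// sweep over sorted open intervals (open arcs cannot cover across a shared
// endpoint).

// [[Rcpp::export]]
LogicalVector cpp_alpha_extreme(NumericMatrix pts, double alpha) {
  const int n = pts.nrow();
  LogicalVector out(n);
  const double lim2 = 4.0 * alpha * alpha;
  const double tol = 1e-10;
  std::vector<double> starts, ends;
  starts.reserve(n);
  ends.reserve(n);
  for (int i = 0; i < n; ++i) {
    starts.clear();
    ends.clear();
    const double px = pts(i, 0), py = pts(i, 1);
    bool dup_blocked = false;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double vx = pts(j, 0) - px, vy = pts(j, 1) - py;
      const double d2 = vx * vx + vy * vy;
      if (d2 >= lim2 || d2 == 0.0) continue;  // coincident points do not block (open ball)
      const double d = std::sqrt(d2);
      const double w = std::acos(std::min(1.0, d / (2.0 * alpha)));
      const double phi = std::atan2(vy, vx);
      double a = phi - w;
      // normalize start into [0, 2pi)
      a -= TWOPI * std::floor(a / TWOPI);
      starts.push_back(a);
      ends.push_back(a + 2.0 * w);
    }
    (void)dup_blocked;
    const int m = (int)starts.size();
    if (m == 0) { out[i] = true; continue; }
    // sort intervals by start (starts normalized to [0, 2pi); ends may
    // exceed 2pi when the arc wraps)
    std::vector<int> ord(m);
    for (int k = 0; k < m; ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(), [&](int a_, int b_) {
      return starts[a_] < starts[b_];
    });
    // cut the circle at x0, the smallest arc start: an uncovered direction
    // exists iff either x0 itself is uncovered (only wrapping arcs can cover
    // it) or the linear greedy sweep over [x0, x0 + 2pi] leaves a gap
    const double x0 = starts[ord[0]];
    const double target = x0 + TWOPI;
    double reach = -1.0;  // coverage of x0 by wrapping arcs
    for (int k = 0; k < m; ++k) {
      if (ends[k] > target + tol && ends[k] - TWOPI > reach) {
        reach = ends[k] - TWOPI;
      }
    }
    bool covered;
    if (reach < x0 + tol) {
      covered = false;  // the direction at x0 is uncovered
    } else {
      covered = true;
      for (int k = 0; k < m; ++k) {
        if (reach >= target - tol) break;
        const double s = starts[ord[k]];
        if (s >= reach - tol) { covered = false; break; }  // open-arc gap
        const double e = ends[ord[k]];
        if (e > reach) reach = e;
      }
      if (reach < target - tol) covered = false;
    }
    out[i] = !covered;
  }
  return out;
}

// ---- alpha-shape edges ----------------------------------------------------
//
// An (unordered) pair of alpha-extreme points {p,q} with |pq| < 2*alpha is an
// alpha-shape edge iff at least one of the two balls of radius alpha through
// p and q is empty of all other input points. Both witness centers and their
// emptiness are reported (needed for apical/basal classification).

// [[Rcpp::export]]
NumericMatrix cpp_alpha_edges(NumericMatrix pts, double alpha,
                              IntegerVector extreme_idx) {
  const int n = pts.nrow();
  const int m = extreme_idx.size();
  const double tol = 1e-9 * alpha;
  std::vector<double> rows;  // i, j, c1x, c1y, e1, c2x, c2y, e2
  for (int a = 0; a < m; ++a) {
    const int i = extreme_idx[a] - 1;
    const double px = pts(i, 0), py = pts(i, 1);
    for (int b = a + 1; b < m; ++b) {
      const int j = extreme_idx[b] - 1;
      const double qx = pts(j, 0), qy = pts(j, 1);
      const double dx = qx - px, dy = qy - py;
      const double d2 = dx * dx + dy * dy;
      if (d2 >= 4.0 * alpha * alpha || d2 == 0.0) continue;
      const double d = std::sqrt(d2);
      const double h = std::sqrt(std::max(0.0, alpha * alpha - d2 / 4.0));
      const double mx = (px + qx) / 2.0, my = (py + qy) / 2.0;
      const double ux = -dy / d, uy = dx / d;  // unit perpendicular
      const double c1x = mx + h * ux, c1y = my + h * uy;
      const double c2x = mx - h * ux, c2y = my - h * uy;
      bool e1 = true, e2 = true;
      for (int r = 0; r < n && (e1 || e2); ++r) {
        if (r == i || r == j) continue;
        const double rx = pts(r, 0), ry = pts(r, 1);
        if (e1) {
          const double t1 = std::hypot(rx - c1x, ry - c1y);
          if (t1 < alpha - tol) e1 = false;
        }
        if (e2) {
          const double t2 = std::hypot(rx - c2x, ry - c2y);
          if (t2 < alpha - tol) e2 = false;
        }
      }
      if (e1 || e2) {
        rows.push_back(i + 1);
        rows.push_back(j + 1);
        rows.push_back(c1x); rows.push_back(c1y); rows.push_back(e1 ? 1.0 : 0.0);
        rows.push_back(c2x); rows.push_back(c2y); rows.push_back(e2 ? 1.0 : 0.0);
      }
    }
  }
  const int ne = (int)rows.size() / 8;
  NumericMatrix out(ne, 8);
  for (int r = 0; r < ne; ++r)
    for (int c = 0; c < 8; ++c) out(r, c) = rows[r * 8 + c];
  colnames(out) = CharacterVector::create("i", "j", "c1x", "c1y", "empty1",
                                          "c2x", "c2y", "empty2");
  return out;
}

// ---- minimum enclosing circle (Welzl) -------------------------------------

struct Circle { double x, y, r; };

static Circle circ2(double ax, double ay, double bx, double by) {
  Circle c;
  c.x = (ax + bx) / 2.0;
  c.y = (ay + by) / 2.0;
  c.r = std::hypot(ax - bx, ay - by) / 2.0;
  return c;
}

static Circle circ3(double ax, double ay, double bx, double by, double cx,
                    double cy) {
  const double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-14) {
    // collinear: diameter of the farthest pair
    Circle c1 = circ2(ax, ay, bx, by), c2 = circ2(ax, ay, cx, cy),
           c3 = circ2(bx, by, cx, cy);
    Circle best = c1;
    if (c2.r > best.r) best = c2;
    if (c3.r > best.r) best = c3;
    return best;
  }
  const double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
               c2_ = cx * cx + cy * cy;
  Circle c;
  c.x = (a2 * (by - cy) + b2 * (cy - ay) + c2_ * (ay - by)) / d;
  c.y = (a2 * (cx - bx) + b2 * (ax - cx) + c2_ * (bx - ax)) / d;
  c.r = std::hypot(ax - c.x, ay - c.y);
  return c;
}

static bool in_circle(const Circle& c, double x, double y) {
  return std::hypot(x - c.x, y - c.y) <= c.r * (1.0 + 1e-12) + 1e-12;
}

// Welzl's move-to-front algorithm, deterministic point order (callers may
// pre-shuffle; polygon rings are small so worst case is irrelevant).
static Circle welzl(std::vector<double>& xs, std::vector<double>& ys) {
  const int n = (int)xs.size();
  Circle c{xs[0], ys[0], 0.0};
  for (int i = 1; i < n; ++i) {
    if (in_circle(c, xs[i], ys[i])) continue;
    c = Circle{xs[i], ys[i], 0.0};
    for (int j = 0; j < i; ++j) {
      if (in_circle(c, xs[j], ys[j])) continue;
      c = circ2(xs[i], ys[i], xs[j], ys[j]);
      for (int k = 0; k < j; ++k) {
        if (in_circle(c, xs[k], ys[k])) continue;
        c = circ3(xs[i], ys[i], xs[j], ys[j], xs[k], ys[k]);
      }
    }
  }
  return c;
}

// [[Rcpp::export]]
NumericVector cpp_min_enclosing_circle(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n == 0) stop("empty point set");
  std::vector<double> xs(n), ys(n);
  for (int i = 0; i < n; ++i) { xs[i] = pts(i, 0); ys[i] = pts(i, 1); }
  Circle c = welzl(xs, ys);
  return NumericVector::create(_["x"] = c.x, _["y"] = c.y, _["r"] = c.r);
}

// ---- point-to-polyline distance -------------------------------------------

static inline double seg_dist(double px, double py, double ax, double ay,
                              double bx, double by) {
  const double vx = bx - ax, vy = by - ay;
  const double L2 = vx * vx + vy * vy;
  double t = 0.0;
  if (L2 > 0.0) t = ((px - ax) * vx + (py - ay) * vy) / L2;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  return std::hypot(px - (ax + t * vx), py - (ay + t * vy));
}

// [[Rcpp::export]]
NumericVector cpp_dist_to_chain(NumericMatrix pts, NumericMatrix chain) {
  const int n = pts.nrow(), m = chain.nrow();
  if (m < 2) stop("chain needs at least one segment");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int s = 0; s + 1 < m; ++s) {
      const double d = seg_dist(pts(i, 0), pts(i, 1), chain(s, 0), chain(s, 1),
                                chain(s + 1, 0), chain(s + 1, 1));
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// minimum distance from points to an explicit segment set (x1,y1,x2,y2 rows)

// [[Rcpp::export]]
NumericVector cpp_dist_to_segments(NumericMatrix pts, NumericMatrix segs) {
  const int n = pts.nrow(), m = segs.nrow();
  if (m < 1) stop("need at least one segment");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int s = 0; s < m; ++s) {
      const double d = seg_dist(pts(i, 0), pts(i, 1), segs(s, 0), segs(s, 1),
                                segs(s, 2), segs(s, 3));
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// nearest point on a segment set (x1,y1,x2,y2 rows)

// [[Rcpp::export]]
NumericMatrix cpp_nearest_on_segments(NumericMatrix pts, NumericMatrix segs) {
  const int n = pts.nrow(), m = segs.nrow();
  if (m < 1) stop("need at least one segment");
  NumericMatrix out(n, 3);  // nx, ny, dist
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf, bx = NA_REAL, by = NA_REAL;
    const double px = pts(i, 0), py = pts(i, 1);
    for (int s = 0; s < m; ++s) {
      const double ax = segs(s, 0), ay = segs(s, 1);
      const double cx = segs(s, 2), cy = segs(s, 3);
      const double vx = cx - ax, vy = cy - ay;
      const double L2 = vx * vx + vy * vy;
      double t = 0.0;
      if (L2 > 0.0) t = ((px - ax) * vx + (py - ay) * vy) / L2;
      if (t < 0.0) t = 0.0;
      if (t > 1.0) t = 1.0;
      const double qx = ax + t * vx, qy = ay + t * vy;
      const double d = std::hypot(px - qx, py - qy);
      if (d < best) { best = d; bx = qx; by = qy; }
    }
    out(i, 0) = bx;
    out(i, 1) = by;
    out(i, 2) = best;
  }
  return out;
}

// nearest point on the chain, and whether the point lies radially outward of
// it with respect to a center (used for layer assignment)

// [[Rcpp::export]]
NumericMatrix cpp_nearest_on_chain(NumericMatrix pts, NumericMatrix chain) {
  const int n = pts.nrow(), m = chain.nrow();
  if (m < 2) stop("chain needs at least one segment");
  NumericMatrix out(n, 3);  // nx, ny, dist
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf, bx = NA_REAL, by = NA_REAL;
    const double px = pts(i, 0), py = pts(i, 1);
    for (int s = 0; s + 1 < m; ++s) {
      const double ax = chain(s, 0), ay = chain(s, 1);
      const double cx = chain(s + 1, 0), cy = chain(s + 1, 1);
      const double vx = cx - ax, vy = cy - ay;
      const double L2 = vx * vx + vy * vy;
      double t = 0.0;
      if (L2 > 0.0) t = ((px - ax) * vx + (py - ay) * vy) / L2;
      if (t < 0.0) t = 0.0;
      if (t > 1.0) t = 1.0;
      const double qx = ax + t * vx, qy = ay + t * vy;
      const double d = std::hypot(px - qx, py - qy);
      if (d < best) { best = d; bx = qx; by = qy; }
    }
    out(i, 0) = bx;
    out(i, 1) = by;
    out(i, 2) = best;
  }
  return out;
}

// ---- k nearest neighbours (brute force, small d) ---------------------------

// [[Rcpp::export]]
List cpp_knn(NumericMatrix ref, NumericMatrix query, int k) {
  const int n = ref.nrow(), m = query.nrow(), d = ref.ncol();
  if (k < 1 || k > n) stop("k out of range");
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<std::pair<double, int>> buf(n);
  for (int q = 0; q < m; ++q) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double t = query(q, c) - ref(i, c);
        s += t * t;
      }
      buf[i] = {s, i};
    }
    std::partial_sort(buf.begin(), buf.begin() + k, buf.end());
    for (int j = 0; j < k; ++j) {
      idx(q, j) = buf[j].second + 1;
      dist(q, j) = std::sqrt(buf[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// ---- point in polygon (boundary counts as inside) ---------------------------

static bool pip(double px, double py, const double* vx, const double* vy,
                int nv, double tol) {
  // boundary check
  for (int i = 0; i < nv; ++i) {
    const int j = (i + 1) % nv;
    if (seg_dist(px, py, vx[i], vy[i], vx[j], vy[j]) <= tol) return true;
  }
  // ray casting
  bool inside = false;
  for (int i = 0, j = nv - 1; i < nv; j = i++) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericMatrix pts, NumericMatrix poly) {
  const int n = pts.nrow(), nv = poly.nrow();
  if (nv < 3) stop("polygon needs >= 3 vertices");
  std::vector<double> vx(nv), vy(nv);
  double scale = 0.0;
  for (int i = 0; i < nv; ++i) {
    vx[i] = poly(i, 0);
    vy[i] = poly(i, 1);
    scale = std::max(scale, std::fabs(vx[i]) + std::fabs(vy[i]));
  }
  const double tol = 1e-12 * std::max(1.0, scale);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pip(pts(i, 0), pts(i, 1), vx.data(), vy.data(), nv, tol);
  return out;
}

// ---- transcript-to-cell assignment ------------------------------------------
//
// Each spot goes to the polygon that contains it, else to the polygon with
// minimum boundary distance. Candidates are pulled by centroid proximity and
// the pool expands until the best boundary distance is certified minimal:
// for any unexamined polygon, boundary distance >= centroid distance minus
// the global maximum polygon radius. Polygons must be supplied in the
// caller's tie-break order (lexicographically smallest id first).

// [[Rcpp::export]]
IntegerVector cpp_assign_spots(NumericMatrix spots, List polys,
                               NumericMatrix centroids, int pool,
                               double max_dist) {
  const int ns = spots.nrow(), np = polys.size();
  if (np == 0) stop("empty polygon set");
  std::vector<std::vector<double>> VX(np), VY(np);
  double max_rad = 0.0, scale = 1.0;
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int p = 0; p < np; ++p) {
    NumericMatrix v = polys[p];
    const int nv = v.nrow();
    VX[p].resize(nv);
    VY[p].resize(nv);
    double r = 0.0;
    for (int i = 0; i < nv; ++i) {
      VX[p][i] = v(i, 0);
      VY[p][i] = v(i, 1);
      r = std::max(r, std::hypot(v(i, 0) - centroids(p, 0),
                                 v(i, 1) - centroids(p, 1)));
      scale = std::max(scale, std::fabs(v(i, 0)) + std::fabs(v(i, 1)));
    }
    max_rad = std::max(max_rad, r);
    xmin = std::min(xmin, centroids(p, 0));
    xmax = std::max(xmax, centroids(p, 0));
    ymin = std::min(ymin, centroids(p, 1));
    ymax = std::max(ymax, centroids(p, 1));
  }
  const double btol = 1e-12 * scale;   // boundary tolerance for containment
  const double etol = 1e-9 * scale;    // distance-equality tolerance for ties

  // uniform grid over polygon centroids for candidate retrieval
  const double span_x = std::max(xmax - xmin, 1e-9),
               span_y = std::max(ymax - ymin, 1e-9);
  double h = std::sqrt(span_x * span_y / np) * 2.0;
  if (!R_finite(h) || h <= 0) h = 1.0;
  const int nx = std::max(1, std::min(2048, (int)(span_x / h) + 1));
  const int ny = std::max(1, std::min(2048, (int)(span_y / h) + 1));
  const double hx = span_x / nx, hy = span_y / ny;
  const double hmin = std::min(hx, hy);
  std::vector<std::vector<int>> bucket((size_t)nx * ny);
  auto bx_of = [&](double x) {
    int b = (int)((x - xmin) / hx);
    return std::max(0, std::min(nx - 1, b));
  };
  auto by_of = [&](double y) {
    int b = (int)((y - ymin) / hy);
    return std::max(0, std::min(ny - 1, b));
  };
  for (int p = 0; p < np; ++p) {
    bucket[(size_t)bx_of(centroids(p, 0)) + (size_t)nx * by_of(centroids(p, 1))]
        .push_back(p);
  }
  const int max_ring = nx + ny;  // enough rings to cover the grid from any bucket

  IntegerVector out(ns);
  for (int s = 0; s < ns; ++s) {
    const double px = spots(s, 0), py = spots(s, 1);
    const int sx = bx_of(px), sy = by_of(py);
    double best = R_PosInf;
    int best_p = -1;
    int examined = 0;
    auto consider = [&](int p) {
      const int nv = (int)VX[p].size();
      double bd = R_PosInf;
      if (pip(px, py, VX[p].data(), VY[p].data(), nv, btol)) {
        bd = 0.0;
      } else {
        for (int i = 0; i < nv; ++i) {
          const int j = (i + 1) % nv;
          const double d =
              seg_dist(px, py, VX[p][i], VY[p][i], VX[p][j], VY[p][j]);
          if (d < bd) bd = d;
        }
      }
      if (bd < best - etol || (bd < best + etol && best_p >= 0 && p < best_p)) {
        best = bd;
        best_p = p;
      }
      ++examined;
    };
    for (int ring = 0; ring <= max_ring; ++ring) {
      // after all buckets at Chebyshev distance <= ring-1 are examined, any
      // unexamined centroid is at least (ring-1)*hmin away, so its boundary
      // is at least that minus the maximal polygon radius
      if (ring > 0 && best_p >= 0 && examined >= std::max(1, pool) &&
          best <= (ring - 1) * hmin - max_rad + etol)
        break;
      bool any_bucket = false;
      const int x0 = sx - ring, x1 = sx + ring, y0 = sy - ring, y1 = sy + ring;
      for (int bx = x0; bx <= x1; ++bx) {
        if (bx < 0 || bx >= nx) continue;
        for (int by = y0; by <= y1; ++by) {
          if (by < 0 || by >= ny) continue;
          if (ring > 0 && bx != x0 && bx != x1 && by != y0 && by != y1)
            continue;  // interior buckets already done
          any_bucket = true;
          for (int p : bucket[(size_t)bx + (size_t)nx * by]) consider(p);
        }
      }
      (void)any_bucket;
    }
    if (max_dist >= 0.0 && best > max_dist) {
      out[s] = NA_INTEGER;
    } else {
      out[s] = best_p + 1;
    }
  }
  return out;
}
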