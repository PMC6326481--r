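// Low-level planar geometry kernels.
//
// Polygons are passed from R as lists of rings; each ring is an n x 2
// numeric matrix of OPEN vertex chains (no repeated closing vertex).
// Orientation convention: exterior ring counter-clockwise, holes
// clockwise, so that the sum of signed fan triangles over all rings is
// +1 inside the polygon and 0 outside.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// ---------------------------------------------------------------------------
// Triangle machinery for exact intersection areas
// ---------------------------------------------------------------------------

struct Tri {
  double x[3], y[3];
  double sgn;                     // +1 / -1 from the signed fan area
  double xmin, xmax, ymin, ymax;  // bbox for cheap rejection
};

// Fan-triangulate every ring of a polygon; each triangle is stored CCW
// with the sign of its original signed area.
static void fan_polygon(const List& rings, std::vector<Tri>& tris) {
  for (int r = 0; r < rings.size(); ++r) {
    NumericMatrix m = rings[r];
    int n = m.nrow();
    for (int i = 1; i + 1 < n; ++i) {
      double ax = m(0, 0), ay = m(0, 1);
      double bx = m(i, 0), by = m(i, 1);
      double cx = m(i + 1, 0), cy = m(i + 1, 1);
      double s2 = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
      if (s2 == 0.0) continue;  // degenerate sliver contributes nothing
      Tri t;
      t.sgn = s2 > 0.0 ? 1.0 : -1.0;
      t.x[0] = ax; t.y[0] = ay;
      if (s2 > 0.0) { t.x[1] = bx; t.y[1] = by; t.x[2] = cx; t.y[2] = cy; }
      else          { t.x[1] = cx; t.y[1] = cy; t.x[2] = bx; t.y[2] = by; }
      t.xmin = std::min({ax, bx, cx}); t.xmax = std::max({ax, bx, cx});
      t.ymin = std::min({ay, by, cy}); t.ymax = std::max({ay, by, cy});
      tris.push_back(t);
    }
  }
}

// Clip convex polygon (px,py) by the left half-plane of a->b.
static void clip_halfplane(std::vector<double>& px, std::vector<double>& py,
                           double ax, double ay, double bx, double by,
                           std::vector<double>& qx, std::vector<double>& qy) {
  qx.clear(); qy.clear();
  const size_t n = px.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    double s = cross3(ax, ay, bx, by, px[i], py[i]);
    double t = cross3(ax, ay, bx, by, px[j], py[j]);
    bool si = s >= 0.0, sj = t >= 0.0;
    if (si) { qx.push_back(px[i]); qy.push_back(py[i]); }
    if (si != sj) {
      double u = s / (s - t);
      qx.push_back(px[i] + u * (px[j] - px[i]));
      qy.push_back(py[i] + u * (py[j] - py[i]));
    }
  }
}

static double tri_tri_area(const Tri& a, const Tri& b) {
  if (a.xmax <= b.xmin || b.xmax <= a.xmin ||
      a.ymax <= b.ymin || b.ymax <= a.ymin) return 0.0;
  std::vector<double> px(a.x, a.x + 3), py(a.y, a.y + 3), qx, qy;
  for (int e = 0; e < 3; ++e) {
    int f = (e + 1) % 3;
    clip_halfplane(px, py, b.x[e], b.y[e], b.x[f], b.y[f], qx, qy);
    px.swap(qx); py.swap(qy);
    if (px.empty()) return 0.0;
  }
  double s = 0.0;
  const size_t n = px.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    s += px[i] * py[j] - px[j] * py[i];
  }
  return 0.5 * s;
}

// Area of intersection of two polygons-with-holes.
// [[Rcpp::export]]
double cpp_poly_inter_area(List ringsP, List ringsQ) {
  std::vector<Tri> tp, tq;
  fan_polygon(ringsP, tp);
  fan_polygon(ringsQ, tq);
  double total = 0.0;
  for (size_t i = 0; i < tp.size(); ++i)
    for (size_t j = 0; j < tq.size(); ++j) {
      double a = tri_tri_area(tp[i], tq[j]);
      if (a != 0.0) total += tp[i].sgn * tq[j].sgn * a;
    }
  return total;
}

// ---------------------------------------------------------------------------
// Distances
// ---------------------------------------------------------------------------

static inline double pt_seg_dist2(double px, double py, double ax, double ay,
                                  double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double l2 = dx * dx + dy * dy;
  double t = 0.0;
  if (l2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / l2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

static inline bool seg_seg_intersect(double ax, double ay, double bx, double by,
                                     double cx, double cy, double dx, double dy) {
  double d1 = cross3(cx, cy, dx, dy, ax, ay);
  double d2 = cross3(cx, cy, dx, dy, bx, by);
  double d3 = cross3(ax, ay, bx, by, cx, cy);
  double d4 = cross3(ax, ay, bx, by, dx, dy);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  return false;
}

static double seg_seg_dist2(double ax, double ay, double bx, double by,
                            double cx, double cy, double dx, double dy) {
  if (seg_seg_intersect(ax, ay, bx, by, cx, cy, dx, dy)) return 0.0;
  double d = pt_seg_dist2(ax, ay, cx, cy, dx, dy);
  d = std::min(d, pt_seg_dist2(bx, by, cx, cy, dx, dy));
  d = std::min(d, pt_seg_dist2(cx, cy, ax, ay, bx, by));
  d = std::min(d, pt_seg_dist2(dx, dy, ax, ay, bx, by));
  return d;
}

// Even-odd point-in-polygon over all rings; boundary (within eps) counts
// as inside. Returns 1 inside / 0 outside per point.
// [[Rcpp::export]]
IntegerVector cpp_points_in_poly(NumericMatrix pts, List rings,
                                 double eps = 1e-9) {
  int np = pts.nrow();
  IntegerVector out(np);
  double e2 = eps * eps;
  for (int p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1);
    bool inside = false, boundary = false;
    for (int r = 0; r < rings.size() && !boundary; ++r) {
      NumericMatrix m = rings[r];
      int n = m.nrow();
      for (int i = 0, j = n - 1; i < n; j = i++) {
        double xi = m(i, 0), yi = m(i, 1), xj = m(j, 0), yj = m(j, 1);
        if (pt_seg_dist2(x, y, xi, yi, xj, yj) <= e2) { boundary = true; break; }
        if (((yi > y) != (yj > y)) &&
            (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
          inside = !inside;
      }
    }
    out[p] = (inside || boundary) ? 1 : 0;
  }
  return out;
}

// Minimum boundary-to-boundary distance between two polygons; 0 when
// they touch, cross, or one contains the other.
// [[Rcpp::export]]
double cpp_poly_min_dist(List ringsP, List ringsQ) {
  // containment / overlap check via representative vertices
  NumericMatrix p0 = ringsP[0], q0 = ringsQ[0];
  NumericMatrix vp(1, 2), vq(1, 2);
  vp(0, 0) = p0(0, 0); vp(0, 1) = p0(0, 1);
  vq(0, 0) = q0(0, 0); vq(0, 1) = q0(0, 1);
  if (cpp_points_in_poly(vq, ringsP)[0] == 1) return 0.0;
  if (cpp_points_in_poly(vp, ringsQ)[0] == 1) return 0.0;
  double best = R_PosInf;
  for (int r = 0; r < ringsP.size(); ++r) {
    NumericMatrix a = ringsP[r];
    int na = a.nrow();
    for (int s = 0; s < ringsQ.size(); ++s) {
      NumericMatrix b = ringsQ[s];
      int nb = b.nrow();
      for (int i = 0, i2 = na - 1; i < na; i2 = i++)
        for (int j = 0, j2 = nb - 1; j < nb; j2 = j++) {
          double d = seg_seg_dist2(a(i2, 0), a(i2, 1), a(i, 0), a(i, 1),
                                   b(j2, 0), b(j2, 1), b(j, 0), b(j, 1));
          if (d < best) {
            best = d;
            if (best == 0.0) return 0.0;
          }
        }
    }
  }
  return std::sqrt(best);
}

// Distance from each point to a polyline (n x 2 vertex chain).
// [[Rcpp::export]]
NumericVector cpp_point_polyline_dist(NumericMatrix pts, NumericMatrix line) {
  int np = pts.nrow(), n = line.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf;
    for (int i = 0; i + 1 < n; ++i) {
      double d = pt_seg_dist2(pts(p, 0), pts(p, 1), line(i, 0), line(i, 1),
                              line(i + 1, 0), line(i + 1, 1));
      if (d < best) best = d;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// Side of a polyline for each point: sign of the cross product against
// the nearest segment (+1 left of the segment direction, -1 right,
// 0 on the line). Used for the land/sea pixel-centre rule.
// [[Rcpp::export]]
IntegerVector cpp_polyline_side(NumericMatrix pts, NumericMatrix line) {
  int np = pts.nrow(), n = line.nrow();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf, sgn = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      double d = pt_seg_dist2(pts(p, 0), pts(p, 1), line(i, 0), line(i, 1),
                              line(i + 1, 0), line(i + 1, 1));
      if (d < best) {
        best = d;
        sgn = cross3(line(i, 0), line(i, 1), line(i + 1, 0), line(i + 1, 1),
                     pts(p, 0), pts(p, 1));
      }
    }
    out[p] = sgn > 0.0 ? 1 : (sgn < 0.0 ? -1 : 0);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Raster kernels
// ---------------------------------------------------------------------------

// 4-connected component labelling of a logical matrix. Background = 0,
// components numbered from 1 in row-major discovery order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> c = q.front(); q.pop();
        for (int k = 0; k < 4; ++k) {
          int ii = c.first + di[k], jj = c.second + dj[k];
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  return lab;
}

// Greedy region growing inside `mask`. Bands come as a list of equally
// shaped matrices. A neighbouring pixel joins the current segment when
// its Euclidean distance in band space to the running segment mean is
// <= thr. Deterministic: seeds scanned in row-major order.
// [[Rcpp::export]]
IntegerMatrix cpp_region_grow(List bands, LogicalMatrix mask, double thr) {
  int nb = bands.size();
  std::vector<NumericMatrix> bd(nb);
  for (int b = 0; b < nb; ++b) bd[b] = as<NumericMatrix>(bands[b]);
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  std::vector<double> mean(nb), val(nb);
  for (int i0 = 0; i0 < nr; ++i0)
    for (int j0 = 0; j0 < nc; ++j0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      lab(i0, j0) = next;
      double cnt = 1.0;
      for (int b = 0; b < nb; ++b) mean[b] = bd[b](i0, j0);
      std::queue<std::pair<int, int> > q;
      q.push(std::make_pair(i0, j0));
      while (!q.empty()) {
        std::pair<int, int> c = q.front(); q.pop();
        for (int k = 0; k < 4; ++k) {
          int ii = c.first + di[k], jj = c.second + dj[k];
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
          if (!mask(ii, jj) || lab(ii, jj) != 0) continue;
          double d2 = 0.0;
          for (int b = 0; b < nb; ++b) {
            double dv = bd[b](ii, jj) - mean[b];
            d2 += dv * dv;
          }
          if (std::sqrt(d2) <= thr) {
            lab(ii, jj) = next;
            for (int b = 0; b < nb; ++b)
              mean[b] = (mean[b] * cnt + bd[b](ii, jj)) / (cnt + 1.0);
            cnt += 1.0;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  return lab;
}
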