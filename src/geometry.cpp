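#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Polygons are open rings: n x 2 matrices, last vertex not repeated.

static double shoelace_abs(const std::vector<double>& x,
                           const std::vector<double>& y) {
  const int n = (int)x.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++) a += x[j] * y[i] - x[i] * y[j];
  return std::fabs(0.5 * a);
}

// [[Rcpp::export]]
double ring_area_cpp(NumericMatrix ring) {
  std::vector<double> x(ring.nrow()), y(ring.nrow());
  for (int i = 0; i < ring.nrow(); ++i) { x[i] = ring(i, 0); y[i] = ring(i, 1); }
  return shoelace_abs(x, y);
}

// Sutherland-Hodgman: clip an arbitrary simple ring by a CONVEX ring given
// counter-clockwise.  Returns area of the intersection (correct for
// non-convex subjects: degenerate bridging edges cancel in the shoelace sum).
static double clip_area_convex(const double* sx, const double* sy, int ns,
                               const double* cx, const double* cy, int nc) {
  static std::vector<double> px, py, qx, qy;  // reused work buffers
  px.assign(sx, sx + ns); py.assign(sy, sy + ns);
  qx.reserve(ns + nc + 4); qy.reserve(ns + nc + 4);
  for (int e = 0; e < nc && px.size() >= 3; ++e) {
    const double ax = cx[e], ay = cy[e];
    const double bx = cx[(e + 1) % nc], by = cy[(e + 1) % nc];
    const double ex = bx - ax, ey = by - ay;
    qx.clear(); qy.clear();
    const int n = (int)px.size();
    double dprev = ex * (py[n - 1] - ay) - ey * (px[n - 1] - ax);
    for (int i = 0, j = n - 1; i < n; j = i++) {
      const double di = ex * (py[i] - ay) - ey * (px[i] - ax);
      const bool inj = dprev >= 0.0, ini = di >= 0.0;
      if (ini != inj) {
        const double t = dprev / (dprev - di);
        qx.push_back(px[j] + t * (px[i] - px[j]));
        qy.push_back(py[j] + t * (py[i] - py[j]));
      }
      if (ini) { qx.push_back(px[i]); qy.push_back(py[i]); }
      dprev = di;
    }
    px.swap(qx); py.swap(qy);
  }
  return shoelace_abs(px, py);
}

// [[Rcpp::export]]
double clip_area_cpp(NumericMatrix subject, NumericMatrix clip) {
  std::vector<double> sx(subject.nrow()), sy(subject.nrow());
  std::vector<double> cx(clip.nrow()), cy(clip.nrow());
  for (int i = 0; i < subject.nrow(); ++i) { sx[i] = subject(i, 0); sy[i] = subject(i, 1); }
  for (int i = 0; i < clip.nrow(); ++i) { cx[i] = clip(i, 0); cy[i] = clip(i, 1); }
  return clip_area_convex(sx.data(), sy.data(), (int)sx.size(),
                          cx.data(), cy.data(), (int)cx.size());
}

struct BBox { double xmin, xmax, ymin, ymax; };

static BBox ring_bbox(const NumericMatrix& m) {
  BBox b; b.xmin = b.xmax = m(0, 0); b.ymin = b.ymax = m(0, 1);
  for (int i = 1; i < m.nrow(); ++i) {
    if (m(i, 0) < b.xmin) b.xmin = m(i, 0);
    if (m(i, 0) > b.xmax) b.xmax = m(i, 0);
    if (m(i, 1) < b.ymin) b.ymin = m(i, 1);
    if (m(i, 1) > b.ymax) b.ymax = m(i, 1);
  }
  return b;
}

// Boundary-inclusive point-in-ring (ray casting + on-segment test).
static bool point_in_ring(double px, double py, const NumericMatrix& m) {
  const int n = m.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    const double xi = m(i, 0), yi = m(i, 1), xj = m(j, 0), yj = m(j, 1);
    // on-segment check
    const double cross = (xj - xi) * (py - yi) - (yj - yi) * (px - xi);
    const double seg2 = (xj - xi) * (xj - xi) + (yj - yi) * (yj - yi);
    if (cross * cross <= 1e-18 * seg2 &&
        px >= std::min(xi, xj) - 1e-12 && px <= std::max(xi, xj) + 1e-12 &&
        py >= std::min(yi, yj) - 1e-12 && py <= std::max(yi, yj) + 1e-12)
      return true;
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector points_in_ring_cpp(NumericVector px, NumericVector py,
                                 NumericMatrix ring) {
  const int n = px.size();
  LogicalVector out(n);
  BBox b = ring_bbox(ring);
  for (int i = 0; i < n; ++i) {
    out[i] = (px[i] >= b.xmin && px[i] <= b.xmax &&
              py[i] >= b.ymin && py[i] <= b.ymax) &&
             point_in_ring(px[i], py[i], ring);
  }
  return out;
}

// Index (1-based) of the FIRST polygon containing each point; NA if none.
// [[Rcpp::export]]
IntegerVector locate_polygon_cpp(NumericVector px, NumericVector py,
                                 List polys) {
  const int n = px.size(), np = polys.size();
  std::vector<NumericMatrix> rings(np);
  std::vector<BBox> boxes(np);
  for (int p = 0; p < np; ++p) {
    rings[p] = as<NumericMatrix>(polys[p]);
    boxes[p] = ring_bbox(rings[p]);
  }
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(px[i]) || NumericVector::is_na(py[i])) continue;
    for (int p = 0; p < np; ++p) {
      const BBox& b = boxes[p];
      if (px[i] < b.xmin || px[i] > b.xmax || py[i] < b.ymin || py[i] > b.ymax)
        continue;
      if (point_in_ring(px[i], py[i], rings[p])) { out[i] = p + 1; break; }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector nearest_dist_cpp(NumericVector px, NumericVector py,
                               NumericVector fx, NumericVector fy) {
  const int n = px.size(), m = fx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(px[i]) || NumericVector::is_na(py[i])) {
      out[i] = NA_REAL; continue;
    }
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = px[i] - fx[j], dy = py[i] - fy[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Area of (buffer n-gon around each point) /\ (each land-cover category).
// polys: list of open rings; cat: 1-based category index per polygon.
// Returns npts x ncat matrix of intersection areas (m^2) plus an attribute
// "buffer_area" (the n-gon area, the denominator for fractions).
// [[Rcpp::export]]
NumericMatrix buffer_category_areas_cpp(NumericVector px, NumericVector py,
                                        double radius, int nseg, List polys,
                                        IntegerVector cat, int ncat) {
  const int n = px.size(), np = polys.size();
  std::vector<NumericMatrix> rings(np);
  std::vector<BBox> boxes(np);
  for (int p = 0; p < np; ++p) {
    rings[p] = as<NumericMatrix>(polys[p]);
    boxes[p] = ring_bbox(rings[p]);
  }
  // template CCW buffer ring at origin
  std::vector<double> ux(nseg), uy(nseg);
  for (int k = 0; k < nseg; ++k) {
    const double th = 2.0 * M_PI * k / nseg;
    ux[k] = radius * std::cos(th);
    uy[k] = radius * std::sin(th);
  }
  const double buf_area = shoelace_abs(ux, uy);
  // inscribed-circle radius of the buffer polygon: a bbox entirely within
  // this distance of the centre lies fully inside the buffer
  const double r_in = radius * std::cos(M_PI / nseg);
  std::vector<double> parea(np);
  std::vector< std::vector<double> > pxs(np), pys(np);
  for (int p = 0; p < np; ++p) {
    const NumericMatrix& r = rings[p];
    const int ns = r.nrow();
    pxs[p].resize(ns); pys[p].resize(ns);
    for (int k = 0; k < ns; ++k) { pxs[p][k] = r(k, 0); pys[p][k] = r(k, 1); }
    parea[p] = shoelace_abs(pxs[p], pys[p]);
  }
  NumericMatrix out(n, ncat);
  std::vector<double> bx(nseg), by(nseg);
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(px[i]) || NumericVector::is_na(py[i])) {
      for (int c = 0; c < ncat; ++c) out(i, c) = NA_REAL;
      continue;
    }
    for (int k = 0; k < nseg; ++k) { bx[k] = ux[k] + px[i]; by[k] = uy[k] + py[i]; }
    const double xmin = px[i] - radius, xmax = px[i] + radius;
    const double ymin = py[i] - radius, ymax = py[i] + radius;
    for (int p = 0; p < np; ++p) {
      const BBox& b = boxes[p];
      if (b.xmax < xmin || b.xmin > xmax || b.ymax < ymin || b.ymin > ymax)
        continue;
      // bbox fully inside the buffer's inscribed circle: take the whole area
      const double dx = std::max(std::fabs(b.xmin - px[i]), std::fabs(b.xmax - px[i]));
      const double dy = std::max(std::fabs(b.ymin - py[i]), std::fabs(b.ymax - py[i]));
      double a;
      if (dx * dx + dy * dy <= r_in * r_in) {
        a = parea[p];
      } else {
        a = clip_area_convex(pxs[p].data(), pys[p].data(), (int)pxs[p].size(),
                             bx.data(), by.data(), nseg);
      }
      out(i, cat[p] - 1) += a;
    }
  }
  out.attr("buffer_area") = buf_area;
  return out;
}
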