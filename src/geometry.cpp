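// Minimum edge-to-edge distance between polygon sets.
//
// A patch geometry is a list of rings; each ring is a list(x, y) of open
// (unclosed) vertex sequences. Distance between two patches is the minimum
// Euclidean distance between their boundaries, zero when boundaries cross
// or one patch lies inside the other (even-odd containment, so a patch
// sitting inside another patch's hole is *not* contained).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct PatchGeom {
  // flattened segments
  std::vector<double> ax, ay, bx, by;
};

void buildPatch(const List &geom, PatchGeom &out) {
  for (R_xlen_t r = 0; r < geom.size(); ++r) {
    List ring = geom[r];
    NumericVector x = ring["x"], y = ring["y"];
    int m = x.size();
    if (m < 3) continue;
    for (int i = 0; i < m; ++i) {
      int j = (i + 1 == m) ? 0 : i + 1;
      out.ax.push_back(x[i]);
      out.ay.push_back(y[i]);
      out.bx.push_back(x[j]);
      out.by.push_back(y[j]);
    }
  }
}

inline double ptSegDist2(double px, double py, double ax, double ay,
                         double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / L2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

inline double orient(double ox, double oy, double ax, double ay,
                     double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

inline bool onSeg(double px, double py, double ax, double ay,
                  double bx, double by) {
  return std::min(ax, bx) <= px && px <= std::max(ax, bx) &&
         std::min(ay, by) <= py && py <= std::max(ay, by);
}

bool segsIntersect(double p1x, double p1y, double p2x, double p2y,
                   double q1x, double q1y, double q2x, double q2y) {
  double d1 = orient(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = orient(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = orient(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = orient(p1x, p1y, p2x, p2y, q2x, q2y);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  if (d1 == 0 && onSeg(p1x, p1y, q1x, q1y, q2x, q2y)) return true;
  if (d2 == 0 && onSeg(p2x, p2y, q1x, q1y, q2x, q2y)) return true;
  if (d3 == 0 && onSeg(q1x, q1y, p1x, p1y, p2x, p2y)) return true;
  if (d4 == 0 && onSeg(q2x, q2y, p1x, p1y, p2x, p2y)) return true;
  return false;
}

inline double segSegDist2(double p1x, double p1y, double p2x, double p2y,
                          double q1x, double q1y, double q2x, double q2y) {
  if (segsIntersect(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y)) return 0.0;
  double d = ptSegDist2(p1x, p1y, q1x, q1y, q2x, q2y);
  d = std::min(d, ptSegDist2(p2x, p2y, q1x, q1y, q2x, q2y));
  d = std::min(d, ptSegDist2(q1x, q1y, p1x, p1y, p2x, p2y));
  d = std::min(d, ptSegDist2(q2x, q2y, p1x, p1y, p2x, p2y));
  return d;
}

// even-odd ray cast over all boundary segments
bool pointInPatch(double px, double py, const PatchGeom &g) {
  bool inside = false;
  size_t m = g.ax.size();
  for (size_t i = 0; i < m; ++i) {
    double y1 = g.ay[i], y2 = g.by[i];
    if ((y1 > py) != (y2 > py)) {
      double xint = g.ax[i] + (py - y1) * (g.bx[i] - g.ax[i]) / (y2 - y1);
      if (px < xint) inside = !inside;
    }
  }
  return inside;
}

double minPatchDist(const PatchGeom &A, const PatchGeom &B) {
  double best2 = R_PosInf;
  for (size_t i = 0; i < A.ax.size(); ++i) {
    for (size_t j = 0; j < B.ax.size(); ++j) {
      double d2 = segSegDist2(A.ax[i], A.ay[i], A.bx[i], A.by[i],
                              B.ax[j], B.ay[j], B.bx[j], B.by[j]);
      if (d2 == 0.0) return 0.0;
      if (d2 < best2) best2 = d2;
    }
  }
  if (!A.ax.empty() && !B.ax.empty()) {
    if (pointInPatch(A.ax[0], A.ay[0], B)) return 0.0;
    if (pointInPatch(B.ax[0], B.ay[0], A)) return 0.0;
  }
  return std::sqrt(best2);
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_pair_distances(List geoms, IntegerVector ia,
                                 IntegerVector ib) {
  int n = geoms.size();
  std::vector<PatchGeom> patches(n);
  std::vector<bool> built(n, false);
  R_xlen_t m = ia.size();
  NumericVector out(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    int i = ia[k] - 1, j = ib[k] - 1;
    if (i < 0 || i >= n || j < 0 || j >= n)
      stop("pair index out of range");
    if (!built[i]) { buildPatch(geoms[i], patches[i]); built[i] = true; }
    if (!built[j]) { buildPatch(geoms[j], patches[j]); built[j] = true; }
    out[k] = minPatchDist(patches[i], patches[j]);
  }
  return out;
}
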