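#include <Rcpp.h>
using namespace Rcpp;

// Minimum distance from each point to any of a set of segments.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericVector px, NumericVector py,
                           NumericVector x0, NumericVector y0,
                           NumericVector x1, NumericVector y1) {
  int np = px.size(), ns = x0.size();
  NumericVector out(np);
  std::vector<double> dx(ns), dy(ns), l2(ns);
  for (int s = 0; s < ns; s++) {
    dx[s] = x1[s] - x0[s];
    dy[s] = y1[s] - y0[s];
    l2[s] = dx[s] * dx[s] + dy[s] * dy[s];
  }
  for (int p = 0; p < np; p++) {
    double best = R_PosInf;
    for (int s = 0; s < ns; s++) {
      double ax = px[p] - x0[s], ay = py[p] - y0[s];
      double t = l2[s] > 0 ? (ax * dx[s] + ay * dy[s]) / l2[s] : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double ex = ax - t * dx[s], ey = ay - t * dy[s];
      double d2 = ex * ex + ey * ey;
      if (d2 < best) best = d2;
    }
    out[p] = sqrt(best);
  }
  return out;
}

// Even-odd crossing test of points against a set of directed edges
// (the edges of all rings of a polygon set, concatenated).
// [[Rcpp::export]]
LogicalVector cpp_point_in_rings(NumericVector px, NumericVector py,
                                 NumericVector xi, NumericVector yi,
                                 NumericVector xj, NumericVector yj) {
  int np = px.size(), m = xi.size();
  LogicalVector out(np);
  for (int p = 0; p < np; p++) {
    bool inside = false;
    double X = px[p], Y = py[p];
    for (int k = 0; k < m; k++) {
      if ((yi[k] > Y) != (yj[k] > Y)) {
        double xc = xi[k] + (xj[k] - xi[k]) * (Y - yi[k]) / (yj[k] - yi[k]);
        if (X < xc) inside = !inside;
      }
    }
    out[p] = inside;
  }
  return out;
}

// Length along which segments of boundary A coincide with segments of
// boundary B: pairs must be anti-parallel and collinear within `tol`
// (perpendicular offset of both B endpoints from the line through A).
// Robust to hairline vertex drift between abutting polygons, unlike
// perimeter-difference identities.
// [[Rcpp::export]]
double cpp_border_overlap(NumericVector ax0, NumericVector ay0,
                          NumericVector ax1, NumericVector ay1,
                          NumericVector bx0, NumericVector by0,
                          NumericVector bx1, NumericVector by1,
                          double tol) {
  int na = ax0.size(), nb = bx0.size();
  double total = 0.0;
  for (int i = 0; i < na; i++) {
    double dax = ax1[i] - ax0[i], day = ay1[i] - ay0[i];
    double la = sqrt(dax * dax + day * day);
    if (la <= tol) continue;
    double ux = dax / la, uy = day / la;
    double alox = std::min(ax0[i], ax1[i]) - tol,
           ahix = std::max(ax0[i], ax1[i]) + tol,
           aloy = std::min(ay0[i], ay1[i]) - tol,
           ahiy = std::max(ay0[i], ay1[i]) + tol;
    for (int j = 0; j < nb; j++) {
      if (std::max(bx0[j], bx1[j]) < alox ||
          std::min(bx0[j], bx1[j]) > ahix ||
          std::max(by0[j], by1[j]) < aloy ||
          std::min(by0[j], by1[j]) > ahiy) continue;
      double dbx = bx1[j] - bx0[j], dby = by1[j] - by0[j];
      double lb = sqrt(dbx * dbx + dby * dby);
      if (lb <= tol) continue;
      if (ux * dbx + uy * dby >= 0) continue;   // not anti-parallel
      double r0x = bx0[j] - ax0[i], r0y = by0[j] - ay0[i];
      double r1x = bx1[j] - ax0[i], r1y = by1[j] - ay0[i];
      if (fabs(ux * r0y - uy * r0x) > tol) continue;  // offset of b start
      if (fabs(ux * r1y - uy * r1x) > tol) continue;  // offset of b end
      double t0 = ux * r0x + uy * r0y;
      double t1 = ux * r1x + uy * r1y;
      if (t0 > t1) std::swap(t0, t1);
      double lo = std::max(t0, 0.0), hi = std::min(t1, la);
      if (hi > lo) total += hi - lo;
    }
  }
  return total;
}
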