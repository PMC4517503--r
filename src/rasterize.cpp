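#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Scanline even-odd polygon fill over a regular grid of cell centers.
//
// px, py: polygon vertices (implicitly closed, any orientation).
// xc: column cell-center x coordinates (strictly increasing, uniform).
// yc: row cell-center y coordinates (strictly increasing, uniform).
//
// A cell center lying in the half-open span [x_enter, x_exit) of a scanline
// run is inside; edges crossing the scanline are counted with the usual
// (y_i > y) != (y_j > y) rule, so centers on horizontal edges and on the
// lower vertex of an edge are handled tie-free.
// [[Rcpp::export(name = ".raster_polygon")]]
IntegerMatrix raster_polygon(NumericVector px, NumericVector py,
                             NumericVector xc, NumericVector yc) {
  const int nr = yc.size(), nc = xc.size(), n = px.size();
  IntegerMatrix out(nr, nc);
  std::vector<double> xint;
  xint.reserve(n);
  for (int r = 0; r < nr; ++r) {
    const double y = yc[r];
    xint.clear();
    for (int i = 0, j = n - 1; i < n; j = i++) {
      if ((py[i] > y) != (py[j] > y)) {
        xint.push_back(px[i] + (y - py[i]) * (px[j] - px[i]) / (py[j] - py[i]));
      }
    }
    if (xint.empty()) continue;
    std::sort(xint.begin(), xint.end());
    for (size_t k = 0; k + 1 < xint.size(); k += 2) {
      // columns with xint[k] <= xc < xint[k + 1]
      int lo = int(std::lower_bound(xc.begin(), xc.end(), xint[k]) - xc.begin());
      int hi = int(std::lower_bound(xc.begin(), xc.end(), xint[k + 1]) - xc.begin());
      for (int c = lo; c < hi; ++c) out(r, c) = 1;
    }
  }
  return out;
}

// Minimum Euclidean distance from each query point to a closed polyline.
// [[Rcpp::export(name = ".dist_to_polyline")]]
NumericVector dist_to_polyline(NumericVector qx, NumericVector qy,
                               NumericVector px, NumericVector py) {
  const int m = qx.size(), n = px.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    double best = R_PosInf;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      const double ax = px[j], ay = py[j];
      const double dx = px[i] - ax, dy = py[i] - ay;
      const double len2 = dx * dx + dy * dy;
      double t = 0.0;
      if (len2 > 0.0) {
        t = ((qx[k] - ax) * dx + (qy[k] - ay) * dy) / len2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      }
      const double ex = ax + t * dx - qx[k], ey = ay + t * dy - qy[k];
      const double d2 = ex * ex + ey * ey;
      if (d2 < best) best = d2;
    }
    out[k] = std::sqrt(best);
  }
  return out;
}
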