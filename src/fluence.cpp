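#include <Rcpp.h>
using namespace Rcpp;

// MU-weighted aperture accumulation onto a square pixel grid at the
// isocentre plane. Pixels receive each sample's delivered MU times the
// fractional overlap of the pixel with the open aperture (area weighting in
// both x and y), summed over samples, then the caller normalises.
//
// A, B: n x 60 leaf edges (mm), gap = B - A; d: n delivered-MU increments;
// edges: 61 leaf-pair band y-edges (mm); grid centres span [-half, half]
// with `spacing` mm pitch; gaps <= closed_tol are treated as closed.
// [[Rcpp::export(name = ".fluence_accumulate")]]
NumericMatrix fluence_accumulate(NumericMatrix A, NumericMatrix B,
                                 NumericVector d, NumericVector edges,
                                 double half_extent, double spacing,
                                 double closed_tol) {
  const int n = A.nrow(), npair = A.ncol();
  const int npix = (int)std::lround(2.0 * half_extent / spacing) + 1;
  NumericMatrix out(npix, npix); // rows = y, cols = x
  const double lo = -half_extent - spacing / 2.0;
  const double hi = half_extent + spacing / 2.0;

  auto overlap = [&](double a, double b, double c0, double c1) {
    double l = std::max(a, c0), r = std::min(b, c1);
    return (r > l) ? (r - l) : 0.0;
  };

  for (int i = 0; i < n; ++i) {
    if (d[i] <= 0.0) continue;
    for (int p = 0; p < npair; ++p) {
      double a = A(i, p), b = B(i, p);
      if (b - a <= closed_tol) continue;
      double y0 = edges[p], y1 = edges[p + 1];
      if (a < lo || b > hi || y0 < lo || y1 > hi) {
        stop("aperture exceeds fluence extent at sample %d", i + 1);
      }
      int c_lo = std::max(0, (int)std::floor((a - lo) / spacing));
      int c_hi = std::min(npix - 1, (int)std::floor((b - lo) / spacing));
      int r_lo = std::max(0, (int)std::floor((y0 - lo) / spacing));
      int r_hi = std::min(npix - 1, (int)std::floor((y1 - lo) / spacing));
      for (int r = r_lo; r <= r_hi; ++r) {
        double yc = -half_extent + r * spacing;
        double fy = overlap(y0, y1, yc - spacing / 2.0, yc + spacing / 2.0) /
                    spacing;
        if (fy <= 0.0) continue;
        double w = d[i] * fy;
        for (int c = c_lo; c <= c_hi; ++c) {
          double xc = -half_extent + c * spacing;
          double fx = overlap(a, b, xc - spacing / 2.0, xc + spacing / 2.0) /
                      spacing;
          if (fx > 0.0) out(r, c) += w * fx;
        }
      }
    }
  }
  return out;
}
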