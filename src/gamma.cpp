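#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Global gamma-index search with bilinear sub-pixel interpolation of the
// evaluated map. Candidate displacements form a spacing/k sub-grid (k
// integer), so pixel-centre offsets are always candidates; offsets are
// visited in order of increasing radius and the search stops as soon as the
// distance term alone exceeds the current best gamma^2.
//
// dose_tol: absolute dose tolerance (global: % of reference max, converted
// by the caller); thresh: absolute low-dose cutoff on the reference.
// Returns gamma map with NA outside the mask.
// [[Rcpp::export(name = ".gamma_search")]]
NumericMatrix gamma_search(NumericMatrix ref, NumericMatrix eval,
                           double spacing, double dose_tol, double dist_tol,
                           double thresh, double radius, double step) {
  const int nr = ref.nrow(), nc = ref.ncol();
  if (eval.nrow() != nr || eval.ncol() != nc) {
    stop("reference and evaluated grids differ in shape");
  }
  const int k = std::max(1, (int)std::ceil(spacing / step));
  const double s = spacing / k;

  struct Off { double dx, dy, r2; };
  std::vector<Off> offs;
  const int m = (int)std::floor(radius / s);
  const double r2max = radius * radius + 1e-12;
  for (int i = -m; i <= m; ++i) {
    for (int j = -m; j <= m; ++j) {
      double dx = i * s, dy = j * s, r2 = dx * dx + dy * dy;
      if (r2 <= r2max) offs.push_back({dx, dy, r2});
    }
  }
  std::sort(offs.begin(), offs.end(),
            [](const Off& a, const Off& b) { return a.r2 < b.r2; });

  const double d2 = dist_tol * dist_tol;
  NumericMatrix out(nr, nc);

  auto interp = [&](double rr, double cc, bool& ok) -> double {
    if (rr < 0.0 || cc < 0.0 || rr > nr - 1.0 || cc > nc - 1.0) {
      ok = false;
      return 0.0;
    }
    ok = true;
    int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
    if (r0 >= nr - 1) r0 = nr - 2;
    if (c0 >= nc - 1) c0 = nc - 2;
    if (r0 < 0) r0 = 0;
    if (c0 < 0) c0 = 0;
    double fr = rr - r0, fc = cc - c0;
    return eval(r0, c0) * (1 - fr) * (1 - fc) +
           eval(r0 + 1, c0) * fr * (1 - fc) +
           eval(r0, c0 + 1) * (1 - fr) * fc +
           eval(r0 + 1, c0 + 1) * fr * fc;
  };

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double dref = ref(r, c);
      if (dref < thresh) {
        out(r, c) = NA_REAL;
        continue;
      }
      double best = R_PosInf;
      for (const Off& o : offs) {
        double dterm = o.r2 / d2;
        if (dterm >= best) break; // radius-sorted: no better candidate left
        bool ok;
        double de = interp(r + o.dy / spacing, c + o.dx / spacing, ok);
        if (!ok) continue;
        double dd = (de - dref) / dose_tol;
        double g2 = dd * dd + dterm;
        if (g2 < best) best = g2;
      }
      out(r, c) = std::sqrt(best);
    }
  }
  return out;
}
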