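#include <Rcpp.h>
using namespace Rcpp;

// Matching scores of a batch of candidate spheres against the foreground
// voxels of the binary volume. `pts` holds the physical centers (um) of the
// 1-voxels, one row per voxel; `params` one row per sphere (x, y, z, r).
// A voxel at distance d from a candidate center contributes
//   +1  if r  < d < r + dr_plus   (positive zone)
//   -1  if r - dr_minus < d < r   (negative zone)
//    0  otherwise (boundaries exactly on r, r - dr_minus, r + dr_plus).
// Comparisons use squared distances; all quantities are nonnegative so the
// strict inequalities survive squaring. Pure function of (pts, params):
// results do not depend on evaluation order.
// [[Rcpp::export]]
IntegerVector score_spheres_cpp(NumericMatrix pts, NumericMatrix params,
                                double dr_plus, double dr_minus) {
  const int n = pts.nrow(), m = params.nrow();
  IntegerVector scores(m);
  const double *px = &pts(0, 0);
  for (int j = 0; j < m; ++j) {
    const double cx = params(j, 0), cy = params(j, 1), cz = params(j, 2);
    const double r = params(j, 3);
    const double r2 = r * r;
    const double hi = r + dr_plus;
    const double hi2 = hi * hi;
    const double lo = r - dr_minus;
    const double lo2 = lo > 0 ? lo * lo : -1.0; // lo <= 0: zone reaches d = 0
    long s = 0;
    for (int i = 0; i < n; ++i) {
      const double dx = px[i] - cx;
      const double dy = px[i + n] - cy;
      const double dz = px[i + 2 * n] - cz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) {
        if (d2 < hi2) ++s;
      } else if (d2 < r2 && d2 > lo2) {
        --s;
      }
    }
    scores[j] = (int)s;
  }
  return scores;
}
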