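#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact minimal Euclidean distance (in pixels) from subpixel query points to
// the nearest TRUE pixel center of a logical mask. A point whose nearest
// integer pixel is mask-positive is "inside" and gets distance 0.
//
// Ring search: walk square rings of Chebyshev radius `rad` around the rounded
// query pixel. Any pixel on ring `rad` is at Euclidean distance >= rad - 0.71
// from the query (the query lies within half a pixel of the ring center in
// each axis), so the search may stop once best < rad - 1 (conservative).
//
// Coordinates are 1-based (row, col) with pixel centers at integers.
// [[Rcpp::export]]
NumericVector nearest_mask_dist_px(LogicalMatrix mask, NumericVector row,
                                   NumericVector col) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int n = row.size();
  if (col.size() != n) stop("row and col must have equal length");
  NumericVector out(n);
  const int maxrad = nr + nc + 2;
  for (int k = 0; k < n; ++k) {
    const double pr = row[k], pc = col[k];
    if (!R_finite(pr) || !R_finite(pc)) stop("non-finite query coordinate");
    int r0 = (int)std::lround(pr), c0 = (int)std::lround(pc);
    if (r0 >= 1 && r0 <= nr && c0 >= 1 && c0 <= nc && mask(r0 - 1, c0 - 1)) {
      out[k] = 0.0;  // centroid falls on a mask pixel
      continue;
    }
    if (r0 < 1) r0 = 1; else if (r0 > nr) r0 = nr;
    if (c0 < 1) c0 = 1; else if (c0 > nc) c0 = nc;
    double best = R_PosInf;
    for (int rad = 1; rad <= maxrad; ++rad) {
      if (best < (double)rad - 1.0) break;
      const int rlo = r0 - rad, rhi = r0 + rad;
      const int clo = c0 - rad, chi = c0 + rad;
      for (int r = std::max(1, rlo); r <= std::min(nr, rhi); ++r) {
        if (r == rlo || r == rhi) {
          for (int c = std::max(1, clo); c <= std::min(nc, chi); ++c) {
            if (mask(r - 1, c - 1)) {
              const double d = std::hypot((double)r - pr, (double)c - pc);
              if (d < best) best = d;
            }
          }
        } else {
          if (clo >= 1 && mask(r - 1, clo - 1)) {
            const double d = std::hypot((double)r - pr, (double)clo - pc);
            if (d < best) best = d;
          }
          if (chi <= nc && mask(r - 1, chi - 1)) {
            const double d = std::hypot((double)r - pr, (double)chi - pc);
            if (d < best) best = d;
          }
        }
      }
    }
    out[k] = best;  // Inf when the mask is empty; callers reject that earlier
  }
  return out;
}
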