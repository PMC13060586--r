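#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterise a truth log into a grayscale frame stack: static background +
// one filled disk per agent + i.i.d. Gaussian pixel noise, rounded and
// clipped to [0, 255].  Coordinates are 1-based with x = column, y = row.
// Uses R's RNG so frames are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector render_frames_cpp(NumericMatrix background, NumericMatrix xs,
                                NumericMatrix ys, double radius,
                                double intensity, double noise_sd) {
  int H = background.nrow(), W = background.ncol();
  int T = xs.nrow(), n_agents = xs.ncol();
  if (ys.nrow() != T || ys.ncol() != n_agents)
    stop("xs and ys must have matching dimensions");
  if (radius < 1.0) stop("blob_radius must be >= 1");
  R_xlen_t npix = (R_xlen_t)H * W;
  NumericVector out((R_xlen_t)npix * T);
  double r2 = radius * radius;
  for (int t = 0; t < T; ++t) {
    double *fr = &out[(R_xlen_t)t * npix];
    for (R_xlen_t i = 0; i < npix; ++i) fr[i] = background[i];
    for (int a = 0; a < n_agents; ++a) {
      double cx = xs(t, a), cy = ys(t, a);
      if (!R_finite(cx) || !R_finite(cy)) continue;
      int rlo = (int)std::ceil(cy - radius), rhi = (int)std::floor(cy + radius);
      if (rlo < 1) rlo = 1;
      if (rhi > H) rhi = H;
      for (int r = rlo; r <= rhi; ++r) {
        double dy = r - cy;
        double span = r2 - dy * dy;
        if (span < 0) continue;
        double dx = std::sqrt(span);
        int clo = (int)std::ceil(cx - dx), chi = (int)std::floor(cx + dx);
        if (clo < 1) clo = 1;
        if (chi > W) chi = W;
        for (int c = clo; c <= chi; ++c)
          fr[(r - 1) + (R_xlen_t)(c - 1) * H] = intensity;
      }
    }
    if (noise_sd > 0) {
      for (R_xlen_t i = 0; i < npix; ++i)
        fr[i] = fr[i] + R::norm_rand() * noise_sd;
    }
    for (R_xlen_t i = 0; i < npix; ++i) {
      double val = std::nearbyint(fr[i]);
      if (val < 0) val = 0;
      if (val > 255) val = 255;
      fr[i] = val;
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, T);
  return out;
}
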