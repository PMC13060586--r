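#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-pixel adaptive mixture-of-Gaussians background model in the
// Stauffer-Grimson style.  The update equations here are the package's
// declared contract; an independent straight-line R implementation of the
// same equations lives in the test suite and must agree bit-for-bit.
//
// Per pixel with value x and K components (w, mu, v = variance):
//  1. order components by weight, descending (stable in component index);
//  2. the background set B is the shortest prefix of that order whose
//     cumulative weight reaches T;
//  3. the pixel is background iff some component of B matches
//     (|x - mu| <= lambda * sqrt(v)), judged on the pre-update state;
//  4. the first matching component in sorted order (searching all K) is
//     updated with rate alpha; if none matches, the weakest component is
//     replaced by (mu = x, v = init_var, w = new_weight) and weights are
//     renormalised in component-index order.

struct MogPar {
  int K;
  double alpha, T, lambda, var_floor, init_var, new_weight;
};

static inline void order_desc(const double *w, int K, int *ord) {
  for (int i = 0; i < K; ++i) ord[i] = i;
  for (int i = 1; i < K; ++i) {
    int key = ord[i];
    int j = i - 1;
    while (j >= 0 && w[ord[j]] < w[key]) { ord[j + 1] = ord[j]; --j; }
    ord[j + 1] = key;
  }
}

static inline bool mog_pixel(double x, double *w, double *mu, double *v,
                             const MogPar &p) {
  int ord[16];
  order_desc(w, p.K, ord);

  double cum = 0.0;
  int nB = 0;
  for (int i = 0; i < p.K; ++i) {
    cum = cum + w[ord[i]];
    ++nB;
    if (cum >= p.T) break;
  }

  bool fg = true;
  for (int i = 0; i < nB; ++i) {
    int k = ord[i];
    if (std::abs(x - mu[k]) <= p.lambda * std::sqrt(v[k])) { fg = false; break; }
  }

  int m = -1;
  for (int i = 0; i < p.K; ++i) {
    int k = ord[i];
    if (std::abs(x - mu[k]) <= p.lambda * std::sqrt(v[k])) { m = k; break; }
  }

  if (m >= 0) {
    for (int k = 0; k < p.K; ++k) w[k] = (1.0 - p.alpha) * w[k];
    w[m] = w[m] + p.alpha;
    double d = x - mu[m];
    mu[m] = mu[m] + p.alpha * d;
    double d2 = x - mu[m];
    v[m] = (1.0 - p.alpha) * v[m] + p.alpha * (d2 * d2);
    if (v[m] < p.var_floor) v[m] = p.var_floor;
  } else {
    int k0 = ord[p.K - 1];
    mu[k0] = x;
    v[k0] = p.init_var;
    w[k0] = p.new_weight;
    double s = w[0];
    for (int k = 1; k < p.K; ++k) s = s + w[k];
    for (int k = 0; k < p.K; ++k) w[k] = w[k] / s;
  }
  return fg;
}

static MogPar as_par(int K, double alpha, double T, double lambda,
                     double var_floor, double init_var, double new_weight) {
  if (K < 1 || K > 16) stop("number of mixture components must be in 1..16");
  MogPar p;
  p.K = K; p.alpha = alpha; p.T = T; p.lambda = lambda;
  p.var_floor = var_floor; p.init_var = init_var; p.new_weight = new_weight;
  return p;
}

// [[Rcpp::export]]
List mog_segment_cpp(NumericMatrix frame, NumericVector w, NumericVector mu,
                     NumericVector v, int K, double alpha, double T,
                     double lambda, double var_floor, double init_var,
                     double new_weight) {
  MogPar p = as_par(K, alpha, T, lambda, var_floor, init_var, new_weight);
  int H = frame.nrow(), W = frame.ncol();
  if ((int)w.size() != H * W * K)
    stop("model dimensions do not match the frame");
  NumericVector w2 = clone(w), mu2 = clone(mu), v2 = clone(v);
  LogicalMatrix mask(H, W);
  int npix = H * W;
  std::vector<double> cw(p.K), cmu(p.K), cv(p.K);
  for (int i = 0; i < npix; ++i) {
    for (int k = 0; k < p.K; ++k) {
      cw[k] = w2[i + k * npix];
      cmu[k] = mu2[i + k * npix];
      cv[k] = v2[i + k * npix];
    }
    bool fg = mog_pixel(frame[i], cw.data(), cmu.data(), cv.data(), p);
    for (int k = 0; k < p.K; ++k) {
      w2[i + k * npix] = cw[k];
      mu2[i + k * npix] = cmu[k];
      v2[i + k * npix] = cv[k];
    }
    mask[i] = fg;
  }
  return List::create(_["mask"] = mask, _["w"] = w2, _["mu"] = mu2,
                      _["v"] = v2);
}

// 8-connected component labelling of a binary mask; returns blob centroids
// (x = column, y = row, 1-based) and pixel areas, filtered to
// [min_area, max_area].
static void label_mask(const int *mask, int H, int W, double min_area,
                       double max_area, std::vector<double> &bx,
                       std::vector<double> &by, std::vector<double> &ba) {
  std::vector<int> lab(H * W, 0);
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int idx = r + c * H;
      if (!mask[idx] || lab[idx]) continue;
      stack.clear();
      stack.push_back(idx);
      lab[idx] = 1;
      double sx = 0.0, sy = 0.0;
      int area = 0;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int rr = cur % H, cc = cur / H;
        sx += (cc + 1);
        sy += (rr + 1);
        ++area;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            int i2 = r2 + c2 * H;
            if (mask[i2] && !lab[i2]) { lab[i2] = 1; stack.push_back(i2); }
          }
        }
      }
      if (area >= min_area && area <= max_area) {
        bx.push_back(sx / area);
        by.push_back(sy / area);
        ba.push_back((double)area);
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame label_blobs_cpp(LogicalMatrix mask, double min_area,
                          double max_area) {
  std::vector<double> bx, by, ba;
  label_mask(LOGICAL(mask), mask.nrow(), mask.ncol(), min_area, max_area,
             bx, by, ba);
  return DataFrame::create(_["x"] = bx, _["y"] = by, _["area"] = ba);
}

// Full detection pass over a frame stack (H x W x T array): MOG
// segmentation then blob extraction per frame.  The model is initialised
// from the first frame (component 1 gets the pixel value with weight 1).
// Frames with index < burnin are processed for adaptation but reported
// with count 0 and no blobs.
// [[Rcpp::export]]
List mog_detect_cpp(NumericVector frames, int H, int W, int T, int K,
                    double alpha, double Tbg, double lambda, double var_floor,
                    double init_var, double new_weight, double min_area,
                    double max_area, int burnin) {
  MogPar p = as_par(K, alpha, Tbg, lambda, var_floor, init_var, new_weight);
  int npix = H * W;
  if ((R_xlen_t)npix * T != frames.size())
    stop("frame stack dimensions do not match H, W, T");
  // model stored interleaved per pixel ([pixel * K + k]) for locality
  std::vector<double> w((size_t)npix * p.K, 0.0),
      mu((size_t)npix * p.K, 0.0), v((size_t)npix * p.K, p.init_var);
  for (int i = 0; i < npix; ++i) {
    w[(size_t)i * p.K] = 1.0;
    mu[(size_t)i * p.K] = frames[i];
  }
  IntegerVector counts(T);
  std::vector<int> fmask(npix);
  std::vector<double> bx, by, ba;
  std::vector<int> bframe;
  for (int t = 0; t < T; ++t) {
    const double *fr = &frames[(R_xlen_t)t * npix];
    for (int i = 0; i < npix; ++i) {
      size_t off = (size_t)i * p.K;
      fmask[i] = mog_pixel(fr[i], &w[off], &mu[off], &v[off], p) ? 1 : 0;
    }
    if (t < burnin) { counts[t] = 0; continue; }
    std::vector<double> fx, fy, fa;
    label_mask(fmask.data(), H, W, min_area, max_area, fx, fy, fa);
    counts[t] = (int)fx.size();
    for (size_t b = 0; b < fx.size(); ++b) {
      bframe.push_back(t);
      bx.push_back(fx[b]);
      by.push_back(fy[b]);
      ba.push_back(fa[b]);
    }
  }
  return List::create(_["counts"] = counts, _["blob_frame"] = wrap(bframe),
                      _["blob_x"] = wrap(bx), _["blob_y"] = wrap(by),
                      _["blob_area"] = wrap(ba));
}
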