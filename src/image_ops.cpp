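// Low-level raster operations for the LCD transcription pipeline.
// Images are numeric matrices (rows = y, cols = x) with intensities in
// [0, 255]; binary images use {0, 255} with foreground = 255.
// Windowed operations replicate edge pixels; rounding is
// half-away-from-zero (all intensities are non-negative, so floor(x + .5)).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

static inline double clamp255(double v) {
  if (v < 0.0) return 0.0;
  if (v > 255.0) return 255.0;
  return v;
}

static inline int reflect_edge(int i, int n) {
  // edge replication
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// [[Rcpp::export]]
NumericMatrix bilateral_filter_cpp(NumericMatrix img, int diameter,
                                   double sigma_range, double sigma_spatial) {
  const int h = img.nrow(), w = img.ncol();
  const int r = diameter / 2;
  // spatial kernel and intensity-difference lookup table
  std::vector<double> spat((2 * r + 1) * (2 * r + 1));
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      spat[(dy + r) * (2 * r + 1) + (dx + r)] =
        std::exp(-(dy * dy + dx * dx) / (2.0 * sigma_spatial * sigma_spatial));
  std::vector<double> rangew(256);
  for (int d = 0; d < 256; ++d)
    rangew[d] = std::exp(-(double)(d * d) / (2.0 * sigma_range * sigma_range));

  // intensities are integral in [0,255]; quantize once so the range kernel
  // becomes a table lookup
  std::vector<short> I((size_t)h * w);
  for (size_t i = 0; i < I.size(); ++i) {
    double v = img[i];
    I[i] = (short)(v < 0 ? 0 : (v > 255 ? 255 : std::lround(v)));
  }
  NumericMatrix out(h, w);
  const int side = 2 * r + 1;
  for (int x = 0; x < w; ++x) {
    const bool xin = (x >= r && x < w - r);
    for (int y = 0; y < h; ++y) {
      const int c = I[(size_t)x * h + y];
      double acc = 0.0, norm = 0.0;
      if (xin && y >= r && y < h - r) {
        // interior fast path (columns are contiguous in memory)
        for (int dx = -r; dx <= r; ++dx) {
          const short* colp = I.data() + (size_t)(x + dx) * h + (y - r);
          const double* sp = spat.data() + (size_t)(dx + r) * side;
          for (int k = 0; k < side; ++k) {
            const int v = colp[k];
            const double wgt = sp[k] * rangew[v > c ? v - c : c - v];
            acc += wgt * v;
            norm += wgt;
          }
        }
      } else {
        for (int dy = -r; dy <= r; ++dy) {
          const int yy = reflect_edge(y + dy, h);
          for (int dx = -r; dx <= r; ++dx) {
            const int xx = reflect_edge(x + dx, w);
            const int v = I[(size_t)xx * h + yy];
            const double wgt = spat[(size_t)(dx + r) * side + (dy + r)]
                             * rangew[v > c ? v - c : c - v];
            acc += wgt * v;
            norm += wgt;
          }
        }
      }
      out(y, x) = clamp255(std::floor(acc / norm + 0.5));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix adaptive_threshold_cpp(NumericMatrix img, int block_size,
                                     double C, bool inverse) {
  const int h = img.nrow(), w = img.ncol();
  const int r = block_size / 2;
  // integral image over an edge-replicated padding of r on every side
  const int ph = h + 2 * r, pw = w + 2 * r;
  std::vector<double> integ((ph + 1) * (pw + 1), 0.0);
  for (int y = 0; y < ph; ++y) {
    double rowsum = 0.0;
    for (int x = 0; x < pw; ++x) {
      rowsum += img(reflect_edge(y - r, h), reflect_edge(x - r, w));
      integ[(y + 1) * (pw + 1) + (x + 1)] = integ[y * (pw + 1) + (x + 1)] + rowsum;
    }
  }
  const double n = (double)block_size * block_size;
  NumericMatrix out(h, w);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      // window [y, y+2r] x [x, x+2r] in padded coordinates
      const int y0 = y, y1 = y + 2 * r + 1, x0 = x, x1 = x + 2 * r + 1;
      const double s = integ[y1 * (pw + 1) + x1] - integ[y0 * (pw + 1) + x1]
                     - integ[y1 * (pw + 1) + x0] + integ[y0 * (pw + 1) + x0];
      const double mean = s / n;
      const double v = img(y, x);
      const bool fg = inverse ? (v < mean - C) : (v > mean + C);
      out(y, x) = fg ? 255.0 : 0.0;
    }
  }
  return out;
}

// 3x3 morphological closing (dilation then erosion) on a {0,255} image.
// Out-of-bounds neighbours are ignored (treated as absent).
// [[Rcpp::export]]
NumericMatrix close3x3_cpp(NumericMatrix bin) {
  const int h = bin.nrow(), w = bin.ncol();
  const size_t n = (size_t)h * w;
  // the square structuring element separates into a vertical then a
  // horizontal 1x3 pass for both dilation and erosion
  std::vector<unsigned char> a(n), b(n);
  for (size_t i = 0; i < n; ++i) a[i] = bin[i] != 0.0 ? 1 : 0;
  auto vpass = [&](const std::vector<unsigned char>& src,
                   std::vector<unsigned char>& dst, bool dilate) {
    for (int x = 0; x < w; ++x) {
      const unsigned char* col = src.data() + (size_t)x * h;
      unsigned char* o = dst.data() + (size_t)x * h;
      for (int y = 0; y < h; ++y) {
        unsigned char v = col[y];
        if (y > 0) v = dilate ? std::max(v, col[y - 1]) : std::min(v, col[y - 1]);
        if (y < h - 1) v = dilate ? std::max(v, col[y + 1]) : std::min(v, col[y + 1]);
        o[y] = v;
      }
    }
  };
  auto hpass = [&](const std::vector<unsigned char>& src,
                   std::vector<unsigned char>& dst, bool dilate) {
    for (int x = 0; x < w; ++x) {
      const unsigned char* c0 = src.data() + (size_t)x * h;
      const unsigned char* cl = x > 0 ? src.data() + (size_t)(x - 1) * h : nullptr;
      const unsigned char* cr = x < w - 1 ? src.data() + (size_t)(x + 1) * h : nullptr;
      unsigned char* o = dst.data() + (size_t)x * h;
      for (int y = 0; y < h; ++y) {
        unsigned char v = c0[y];
        if (cl) v = dilate ? std::max(v, cl[y]) : std::min(v, cl[y]);
        if (cr) v = dilate ? std::max(v, cr[y]) : std::min(v, cr[y]);
        o[y] = v;
      }
    }
  };
  vpass(a, b, true); hpass(b, a, true);   // dilation
  vpass(a, b, false); hpass(b, a, false); // erosion
  NumericMatrix out(h, w);
  for (size_t i = 0; i < n; ++i) out[i] = a[i] ? 255.0 : 0.0;
  return out;
}

// 8-connected components of a {0,255} image. Returns one row per
// component: x, y, w, h (0-based, half-open) and pixel count.
// [[Rcpp::export]]
DataFrame label_components_cpp(NumericMatrix bin) {
  const int h = bin.nrow(), w = bin.ncol();
  std::vector<int> lab((size_t)h * w, 0);
  std::vector<int> cx0, cy0, cx1, cy1, cn;
  int next = 0;
  std::vector<int> stack;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      if (bin(y, x) == 0.0 || lab[(size_t)y * w + x] != 0) continue;
      ++next;
      int x0 = x, x1 = x, y0 = y, y1 = y, npix = 0;
      stack.clear();
      stack.push_back(y * w + x);
      lab[(size_t)y * w + x] = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int py = p / w, px = p % w;
        ++npix;
        if (px < x0) x0 = px;
        if (px > x1) x1 = px;
        if (py < y0) y0 = py;
        if (py > y1) y1 = py;
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            const int yy = py + dy, xx = px + dx;
            if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
            const size_t q = (size_t)yy * w + xx;
            if (bin(yy, xx) != 0.0 && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(yy * w + xx);
            }
          }
      }
      cx0.push_back(x0); cy0.push_back(y0);
      cx1.push_back(x1); cy1.push_back(y1);
      cn.push_back(npix);
    }
  }
  const int k = (int)cx0.size();
  IntegerVector X(k), Y(k), W(k), H(k), N(k);
  for (int i = 0; i < k; ++i) {
    X[i] = cx0[i];
    Y[i] = cy0[i];
    W[i] = cx1[i] - cx0[i] + 1;
    H[i] = cy1[i] - cy0[i] + 1;
    N[i] = cn[i];
  }
  return DataFrame::create(_["x"] = X, _["y"] = Y, _["w"] = W, _["h"] = H,
                           _["npix"] = N);
}

// Separable Gaussian blur, edge replication; returns rounded/clamped image.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  const int h = img.nrow(), w = img.ncol();
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-(double)(i * i) / (2.0 * sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(h, w), out(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * img(y, reflect_edge(x + i, w));
      tmp(y, x) = acc;
    }
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp(reflect_edge(y + i, h), x);
      out(y, x) = clamp255(std::floor(acc + 0.5));
    }
  return out;
}

// Inverse-mapped affine warp with bilinear sampling.
// For each output pixel (x, y): source = (a11*x + a12*y + a13,
// a21*x + a22*y + a23); out-of-range samples take `fill`.
// [[Rcpp::export]]
NumericMatrix warp_affine_cpp(NumericMatrix img, NumericVector inv_map,
                              double fill) {
  const int h = img.nrow(), w = img.ncol();
  const double a11 = inv_map[0], a12 = inv_map[1], a13 = inv_map[2];
  const double a21 = inv_map[3], a22 = inv_map[4], a23 = inv_map[5];
  NumericMatrix out(h, w);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      const double sx = a11 * x + a12 * y + a13;
      const double sy = a21 * x + a22 * y + a23;
      double v;
      if (sx < 0.0 || sy < 0.0 || sx > w - 1.0 || sy > h - 1.0) {
        v = fill;
      } else {
        const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        const int x1 = std::min(x0 + 1, w - 1), y1 = std::min(y0 + 1, h - 1);
        const double fx = sx - x0, fy = sy - y0;
        v = (1 - fx) * (1 - fy) * img(y0, x0) + fx * (1 - fy) * img(y0, x1)
          + (1 - fx) * fy * img(y1, x0) + fx * fy * img(y1, x1);
      }
      out(y, x) = clamp255(std::floor(v + 0.5));
    }
  }
  return out;
}

// Bilinear resize to (out_h, out_w); pixel-centre alignment. Returns the
// unrounded interpolated surface so callers control re-binarization.
// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(NumericMatrix img, int out_h, int out_w) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double ry = (double)h / out_h, rx = (double)w / out_w;
  for (int y = 0; y < out_h; ++y) {
    double sy = (y + 0.5) * ry - 0.5;
    if (sy < 0) sy = 0;
    if (sy > h - 1) sy = h - 1;
    const int y0 = (int)std::floor(sy), y1 = std::min(y0 + 1, h - 1);
    const double fy = sy - y0;
    for (int x = 0; x < out_w; ++x) {
      double sx = (x + 0.5) * rx - 0.5;
      if (sx < 0) sx = 0;
      if (sx > w - 1) sx = w - 1;
      const int x0 = (int)std::floor(sx), x1 = std::min(x0 + 1, w - 1);
      const double fx = sx - x0;
      out(y, x) = (1 - fx) * (1 - fy) * img(y0, x0) + fx * (1 - fy) * img(y0, x1)
                + (1 - fx) * fy * img(y1, x0) + fx * fy * img(y1, x1);
    }
  }
  return out;
}
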