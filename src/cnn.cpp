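// Multi-digit seven-segment recognizer: a three-block convolutional network
// (5x5 kernels, 32/64/128 filters, batch-norm + ReLU + 2x2 max-pool per
// block) over a 180x80 binary frame, feeding three independent 11-way
// softmax heads (digits 0-9 plus a blank class). Trained by minimizing the
// summed per-head cross-entropy, i.e. maximizing log P(S|X) under head
// independence, with Adam and a best-validation-loss checkpoint.
//
// Implemented with im2col + sgemm in single precision. Feature maps are
// kept position-major ((H*W*B) x C) so patch extraction reduces to
// contiguous row copies and batch-norm statistics to column reductions.
// All randomness (parameter init, epoch shuffling) is drawn from R's RNG
// so set.seed() governs reproducibility.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

// architecture constants (fixed by the model definition)
static const int H0 = 80, W0 = 180;          // input frame, rows x cols
static const int HW0 = H0 * W0;              // 14400
static const int C1 = 32, C2 = 64, C3 = 128; // filters per block
static const int K = 5, KK = K * K, PAD = 2; // kernel
static const int H1 = 40, W1 = 90, HW1 = H1 * W1;   // after pool 1
static const int H2 = 20, W2 = 45, HW2 = H2 * W2;   // after pool 2
static const int H3 = 10, W3 = 22, HW3 = H3 * W3;   // after pool 3 (45 -> 22)
static const int FLAT = C3 * HW3;            // 28160
static const int NCLASS = 11, NHEAD = 3, NLOGIT = NCLASS * NHEAD;
static const float BN_EPS = 1e-5f, BN_MOM = 0.1f;

struct Net {
  fmat W1c, W2c, W3c;        // conv weights: (C_in*25) x C_out
  fvec g1, b1, rm1, rv1;     // batch-norm: gain, bias, running mean/var
  fvec g2, b2, rm2, rv2;
  fvec g3, b3, rm3, rv3;
  fmat Wh;                   // heads: 33 x FLAT
  fvec bh;                   // 33
};

static fmat as_fmat(SEXP s) {
  NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.memptr());
  return out;
}
static fvec as_fvec(SEXP s) {
  NumericVector v(s);
  fvec out(v.size());
  std::copy(v.begin(), v.end(), out.memptr());
  return out;
}
static NumericMatrix to_rmat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
static NumericVector to_rvec(const fvec& v) {
  NumericVector out(v.n_elem);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

static Net net_from_list(List p) {
  Net n;
  n.W1c = as_fmat(p["W1"]); n.W2c = as_fmat(p["W2"]); n.W3c = as_fmat(p["W3"]);
  n.g1 = as_fvec(p["gamma1"]); n.b1 = as_fvec(p["beta1"]);
  n.rm1 = as_fvec(p["rmean1"]); n.rv1 = as_fvec(p["rvar1"]);
  n.g2 = as_fvec(p["gamma2"]); n.b2 = as_fvec(p["beta2"]);
  n.rm2 = as_fvec(p["rmean2"]); n.rv2 = as_fvec(p["rvar2"]);
  n.g3 = as_fvec(p["gamma3"]); n.b3 = as_fvec(p["beta3"]);
  n.rm3 = as_fvec(p["rmean3"]); n.rv3 = as_fvec(p["rvar3"]);
  n.Wh = as_fmat(p["Wh"]); n.bh = as_fvec(p["bh"]);
  if ((int)n.W1c.n_rows != KK || (int)n.W1c.n_cols != C1 ||
      (int)n.W2c.n_rows != C1 * KK || (int)n.W2c.n_cols != C2 ||
      (int)n.W3c.n_rows != C2 * KK || (int)n.W3c.n_cols != C3 ||
      (int)n.Wh.n_rows != NLOGIT || (int)n.Wh.n_cols != FLAT)
    stop("malformed parameter shapes");
  return n;
}
static List net_to_list(const Net& n) {
  return List::create(
    _["W1"] = to_rmat(n.W1c), _["W2"] = to_rmat(n.W2c), _["W3"] = to_rmat(n.W3c),
    _["gamma1"] = to_rvec(n.g1), _["beta1"] = to_rvec(n.b1),
    _["rmean1"] = to_rvec(n.rm1), _["rvar1"] = to_rvec(n.rv1),
    _["gamma2"] = to_rvec(n.g2), _["beta2"] = to_rvec(n.b2),
    _["rmean2"] = to_rvec(n.rm2), _["rvar2"] = to_rvec(n.rv2),
    _["gamma3"] = to_rvec(n.g3), _["beta3"] = to_rvec(n.b3),
    _["rmean3"] = to_rvec(n.rm3), _["rvar3"] = to_rvec(n.rv3),
    _["Wh"] = to_rmat(n.Wh), _["bh"] = to_rvec(n.bh));
}

// [[Rcpp::export]]
List cnn_init_cpp() {
  // He-normal for conv weights, Glorot-uniform for the heads; draws come
  // from R's RNG (caller seeds)
  RNGScope scope;
  Net n;
  auto he = [](int rows, int cols, int fan_in) {
    fmat w(rows, cols);
    const double sd = std::sqrt(2.0 / fan_in);
    for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = (float)(norm_rand() * sd);
    return w;
  };
  n.W1c = he(KK, C1, KK);
  n.W2c = he(C1 * KK, C2, C1 * KK);
  n.W3c = he(C2 * KK, C3, C2 * KK);
  const double lim = std::sqrt(6.0 / (FLAT + NLOGIT));
  n.Wh.set_size(NLOGIT, FLAT);
  for (arma::uword i = 0; i < n.Wh.n_elem; ++i)
    n.Wh(i) = (float)((unif_rand() * 2.0 - 1.0) * lim);
  n.bh.zeros(NLOGIT);
  n.g1.ones(C1); n.b1.zeros(C1); n.rm1.zeros(C1); n.rv1.ones(C1);
  n.g2.ones(C2); n.b2.zeros(C2); n.rm2.zeros(C2); n.rv2.ones(C2);
  n.g3.ones(C3); n.b3.zeros(C3); n.rm3.zeros(C3); n.rv3.ones(C3);
  return net_to_list(n);
}

// im2col for one image held position-major: channel plane c of the input
// starts at in + c*chan_stride and is H*W contiguous floats. Output column
// c*25 + ky*5 + kx holds, at row y*W + x, the input value at
// (y + ky - 2, x + kx - 2) or zero outside the image. Each (column, y)
// pair is one contiguous run, so the copy vectorizes.
static void im2col(const float* in, size_t chan_stride, int C, int H, int W,
                   fmat& out) {
  for (int c = 0; c < C; ++c) {
    const float* plane = in + (size_t)c * chan_stride;
    for (int ky = 0; ky < K; ++ky) {
      const int dy = ky - PAD;
      for (int kx = 0; kx < K; ++kx) {
        const int dx = kx - PAD;
        float* o = out.colptr(c * KK + ky * K + kx);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        for (int y = 0; y < H; ++y) {
          const int sy = y + dy;
          float* orow = o + (size_t)y * W;
          if (sy < 0 || sy >= H) {
            std::memset(orow, 0, sizeof(float) * W);
            continue;
          }
          if (x0 > 0) std::memset(orow, 0, sizeof(float) * x0);
          if (x1 > x0)
            std::memcpy(orow + x0, plane + (size_t)sy * W + x0 + dx,
                        sizeof(float) * (x1 - x0));
          if (x1 < W) std::memset(orow + x1, 0, sizeof(float) * (W - x1));
        }
      }
    }
  }
}

// scatter-add transpose of im2col (input gradients); dX planes are assumed
// pre-zeroed by the caller
static void col2im(const fmat& dcol, float* dX, size_t chan_stride,
                   int C, int H, int W) {
  for (int c = 0; c < C; ++c) {
    float* plane = dX + (size_t)c * chan_stride;
    for (int ky = 0; ky < K; ++ky) {
      const int dy = ky - PAD;
      for (int kx = 0; kx < K; ++kx) {
        const int dx = kx - PAD;
        const float* s = dcol.colptr(c * KK + ky * K + kx);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        for (int y = 0; y < H; ++y) {
          const int sy = y + dy;
          if (sy < 0 || sy >= H || x1 <= x0) continue;
          const float* srow = s + (size_t)y * W + x0;
          float* drow = plane + (size_t)sy * W + x0 + dx;
          for (int i = 0; i < x1 - x0; ++i) drow[i] += srow[i];
        }
      }
    }
  }
}

// batch convolution: IN is (HW*B) x C_in (image b in rows [b*HW, (b+1)*HW)),
// Wt is (C_in*25) x C_out, Z gets (HW*B) x C_out
static void conv_fwd(const fmat& IN, int C_in, int H, int W, int B,
                     const fmat& Wt, fmat& Z, fmat& colbuf, fmat& zbuf) {
  const int HW = H * W;
  const int C_out = Wt.n_cols;
  Z.set_size((size_t)HW * B, C_out);
  colbuf.set_size(HW, (size_t)C_in * KK);
  for (int b = 0; b < B; ++b) {
    im2col(IN.memptr() + (size_t)b * HW, IN.n_rows, C_in, H, W, colbuf);
    zbuf = colbuf * Wt;
    for (int c = 0; c < C_out; ++c)
      std::memcpy(Z.colptr(c) + (size_t)b * HW, zbuf.colptr(c),
                  sizeof(float) * HW);
  }
}

// batch-norm + ReLU forward over a (N x C) map; training mode computes
// batch statistics and updates running averages, inference uses them
static void bn_relu_fwd(const fmat& Z, fvec& g, fvec& b, fvec& rm, fvec& rv,
                        bool train, fvec& mu, fvec& istd, fmat& A) {
  const int C = Z.n_cols;
  const size_t N = Z.n_rows;
  mu.set_size(C); istd.set_size(C);
  A.set_size(N, C);
  for (int c = 0; c < C; ++c) {
    const float* z = Z.colptr(c);
    float m, is;
    if (train) {
      double s = 0.0;
      for (size_t i = 0; i < N; ++i) s += z[i];
      m = (float)(s / N);
      double v = 0.0;
      for (size_t i = 0; i < N; ++i) {
        const double d = z[i] - m;
        v += d * d;
      }
      const float var = (float)(v / N);
      is = 1.0f / std::sqrt(var + BN_EPS);
      rm(c) = (1.0f - BN_MOM) * rm(c) + BN_MOM * m;
      rv(c) = (1.0f - BN_MOM) * rv(c) + BN_MOM * var;
    } else {
      m = rm(c);
      is = 1.0f / std::sqrt(rv(c) + BN_EPS);
    }
    mu(c) = m; istd(c) = is;
    const float gc = g(c) * is, bc = b(c) - g(c) * is * m;
    float* a = A.colptr(c);
    for (size_t i = 0; i < N; ++i) {
      const float y = gc * z[i] + bc;
      a[i] = y > 0.0f ? y : 0.0f;
    }
  }
}

// gradient through ReLU + batch-norm; overwrites dA with dZ
static void bn_relu_bwd(const fmat& Z, const fmat& A, const fvec& g,
                        const fvec& mu, const fvec& istd,
                        fmat& dA, fvec& dg, fvec& db) {
  const int C = Z.n_cols;
  const size_t N = Z.n_rows;
  dg.set_size(C); db.set_size(C);
  for (int c = 0; c < C; ++c) {
    const float* z = Z.colptr(c);
    const float* a = A.colptr(c);
    float* d = dA.colptr(c);
    const float m = mu(c), is = istd(c), gc = g(c);
    double s1 = 0.0, s2 = 0.0, sb = 0.0;
    for (size_t i = 0; i < N; ++i) {
      const float dy = a[i] > 0.0f ? d[i] : 0.0f;
      const float xh = (z[i] - m) * is;
      d[i] = dy;
      sb += dy;
      s1 += dy;
      s2 += (double)dy * xh;
    }
    db(c) = (float)sb;
    dg(c) = (float)s2;
    const float k1 = (float)(s1 / N), k2 = (float)(s2 / N);
    for (size_t i = 0; i < N; ++i) {
      const float xh = (z[i] - m) * is;
      d[i] = gc * is * (d[i] - k1 - xh * k2);
    }
  }
}

// 2x2 stride-2 max-pool; A is (HW*B) x C, P gets (HoWo*B) x C and idx the
// argmax source rows
static void pool_fwd(const fmat& A, int H, int W, int Ho, int Wo, int B,
                     fmat& P, arma::umat& idx) {
  const int C = A.n_cols, HW = H * W, HWo = Ho * Wo;
  P.set_size((size_t)HWo * B, C);
  idx.set_size((size_t)HWo * B, C);
  for (int c = 0; c < C; ++c) {
    const float* a = A.colptr(c);
    float* p = P.colptr(c);
    arma::uword* ix = idx.colptr(c);
    for (int b = 0; b < B; ++b) {
      const size_t in0 = (size_t)b * HW, out0 = (size_t)b * HWo;
      for (int y = 0; y < Ho; ++y) {
        const size_t r0 = in0 + (size_t)(2 * y) * W;
        size_t o = out0 + (size_t)y * Wo;
        for (int x = 0; x < Wo; ++x, ++o) {
          size_t best = r0 + 2 * x;
          float v = a[best];
          if (a[best + 1] > v) { v = a[best + 1]; best = r0 + 2 * x + 1; }
          if (a[r0 + W + 2 * x] > v) { v = a[r0 + W + 2 * x]; best = r0 + W + 2 * x; }
          if (a[r0 + W + 2 * x + 1] > v) { v = a[r0 + W + 2 * x + 1]; best = r0 + W + 2 * x + 1; }
          p[o] = v;
          ix[o] = best;
        }
      }
    }
  }
}

static void pool_bwd(const fmat& dP, const arma::umat& idx, size_t in_rows,
                     fmat& dA) {
  dA.zeros(in_rows, dP.n_cols);
  for (arma::uword c = 0; c < dP.n_cols; ++c) {
    const float* d = dP.colptr(c);
    const arma::uword* ix = idx.colptr(c);
    float* o = dA.colptr(c);
    for (arma::uword i = 0; i < dP.n_rows; ++i) o[ix[i]] += d[i];
  }
}

// gather a batch of frames (rows of X, 0/1 ints) into an (HW0*B) x 1 map
static void gather_batch(const IntegerMatrix& X, const std::vector<int>& ids,
                         fmat& x0) {
  const int B = (int)ids.size();
  const int n = X.nrow();
  x0.set_size((size_t)HW0 * B, 1);
  const int* xp = INTEGER(X);
  for (int b = 0; b < B; ++b) {
    float* dst = x0.memptr() + (size_t)b * HW0;
    const int* src = xp + ids[b];  // column-major: stride n between pixels
    for (int p = 0; p < HW0; ++p) dst[p] = (float)src[(size_t)p * n];
  }
}

struct FwdCache {
  fmat x0, Z1, A1, P1, Z2, A2, P2, Z3, A3, P3;
  arma::umat i1, i2, i3;
  fvec mu1, is1, mu2, is2, mu3, is3;
  fmat flat, logits, probs;
  fmat colbuf, zbuf;
};

static void forward(Net& net, const IntegerMatrix& X, const std::vector<int>& ids,
                    bool train, FwdCache& f) {
  const int B = (int)ids.size();
  gather_batch(X, ids, f.x0);
  conv_fwd(f.x0, 1, H0, W0, B, net.W1c, f.Z1, f.colbuf, f.zbuf);
  bn_relu_fwd(f.Z1, net.g1, net.b1, net.rm1, net.rv1, train, f.mu1, f.is1, f.A1);
  pool_fwd(f.A1, H0, W0, H1, W1, B, f.P1, f.i1);
  conv_fwd(f.P1, C1, H1, W1, B, net.W2c, f.Z2, f.colbuf, f.zbuf);
  bn_relu_fwd(f.Z2, net.g2, net.b2, net.rm2, net.rv2, train, f.mu2, f.is2, f.A2);
  pool_fwd(f.A2, H1, W1, H2, W2, B, f.P2, f.i2);
  conv_fwd(f.P2, C2, H2, W2, B, net.W3c, f.Z3, f.colbuf, f.zbuf);
  bn_relu_fwd(f.Z3, net.g3, net.b3, net.rm3, net.rv3, train, f.mu3, f.is3, f.A3);
  pool_fwd(f.A3, H2, W2, H3, W3, B, f.P3, f.i3);
  // flatten (channel-major per image) for the heads
  f.flat.set_size(FLAT, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C3; ++c)
      std::memcpy(f.flat.colptr(b) + (size_t)c * HW3,
                  f.P3.colptr(c) + (size_t)b * HW3, sizeof(float) * HW3);
  f.logits = net.Wh * f.flat;
  f.logits.each_col() += net.bh;
  // per-head softmax
  f.probs.set_size(NLOGIT, B);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < NHEAD; ++h) {
      const int o = h * NCLASS;
      float mx = f.logits(o, b);
      for (int k = 1; k < NCLASS; ++k) mx = std::max(mx, f.logits(o + k, b));
      float s = 0.0f;
      for (int k = 0; k < NCLASS; ++k) {
        const float e = std::exp(f.logits(o + k, b) - mx);
        f.probs(o + k, b) = e;
        s += e;
      }
      for (int k = 0; k < NCLASS; ++k) f.probs(o + k, b) /= s;
    }
  }
}

static double batch_loss(const fmat& probs, const IntegerMatrix& Y,
                         const std::vector<int>& ids) {
  double loss = 0.0;
  for (size_t b = 0; b < ids.size(); ++b)
    for (int h = 0; h < NHEAD; ++h) {
      const float p = probs(h * NCLASS + Y(ids[b], h), b);
      loss -= std::log(std::max(p, 1e-12f));
    }
  return loss / ids.size();
}

struct Grads {
  fmat dW1, dW2, dW3, dWh;
  fvec dg1, db1, dg2, db2, dg3, db3, dbh;
};

// conv backward helper: accumulates dWt and (optionally) the input
// gradient dIN from the output gradient dZ
static void conv_bwd(const fmat& IN, int C_in, int H, int W, int B,
                     const fmat& Wt, const fmat& dZ, fmat& dWt, fmat* dIN,
                     fmat& colbuf, fmat& dzbuf, fmat& dcolbuf) {
  const int HW = H * W;
  const int C_out = Wt.n_cols;
  dWt.zeros(arma::size(Wt));
  if (dIN) dIN->zeros((size_t)HW * B, C_in);
  colbuf.set_size(HW, (size_t)C_in * KK);
  dzbuf.set_size(HW, C_out);
  for (int b = 0; b < B; ++b) {
    im2col(IN.memptr() + (size_t)b * HW, IN.n_rows, C_in, H, W, colbuf);
    for (int c = 0; c < C_out; ++c)
      std::memcpy(dzbuf.colptr(c), dZ.colptr(c) + (size_t)b * HW,
                  sizeof(float) * HW);
    dWt += colbuf.t() * dzbuf;
    if (dIN) {
      dcolbuf = dzbuf * Wt.t();
      col2im(dcolbuf, dIN->memptr() + (size_t)b * HW, dIN->n_rows,
             C_in, H, W);
    }
  }
}

static void backward(Net& net, const IntegerMatrix& Y,
                     const std::vector<int>& ids, FwdCache& f, Grads& g) {
  const int B = (int)ids.size();
  fmat dlog = f.probs;
  for (int b = 0; b < B; ++b)
    for (int h = 0; h < NHEAD; ++h)
      dlog(h * NCLASS + Y(ids[b], h), b) -= 1.0f;
  dlog /= (float)B;
  g.dWh = dlog * f.flat.t();
  g.dbh = arma::sum(dlog, 1);
  fmat dflat = net.Wh.t() * dlog;  // FLAT x B
  fmat dP3((size_t)HW3 * B, C3);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C3; ++c)
      std::memcpy(dP3.colptr(c) + (size_t)b * HW3,
                  dflat.colptr(b) + (size_t)c * HW3, sizeof(float) * HW3);

  fmat dA3, dP2, dA2, dP1, dA1;
  fmat dzbuf, dcolbuf;
  pool_bwd(dP3, f.i3, (size_t)HW2 * B, dA3);
  bn_relu_bwd(f.Z3, f.A3, net.g3, f.mu3, f.is3, dA3, g.dg3, g.db3);
  conv_bwd(f.P2, C2, H2, W2, B, net.W3c, dA3, g.dW3, &dP2,
           f.colbuf, dzbuf, dcolbuf);
  pool_bwd(dP2, f.i2, (size_t)HW1 * B, dA2);
  bn_relu_bwd(f.Z2, f.A2, net.g2, f.mu2, f.is2, dA2, g.dg2, g.db2);
  conv_bwd(f.P1, C1, H1, W1, B, net.W2c, dA2, g.dW2, &dP1,
           f.colbuf, dzbuf, dcolbuf);
  pool_bwd(dP1, f.i1, (size_t)HW0 * B, dA1);
  bn_relu_bwd(f.Z1, f.A1, net.g1, f.mu1, f.is1, dA1, g.dg1, g.db1);
  conv_bwd(f.x0, 1, H0, W0, B, net.W1c, dA1, g.dW1, nullptr,
           f.colbuf, dzbuf, dcolbuf);
}

struct Adam {
  std::vector<fmat> m_m, v_m;
  std::vector<fvec> m_v, v_v;
  long t = 0;
  float lr, b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;

  void init(const std::vector<fmat*>& mats, const std::vector<fvec*>& vecs,
            float lr_) {
    lr = lr_;
    for (auto* p : mats) {
      m_m.emplace_back(arma::size(*p), arma::fill::zeros);
      v_m.emplace_back(arma::size(*p), arma::fill::zeros);
    }
    for (auto* p : vecs) {
      m_v.emplace_back(p->n_elem, arma::fill::zeros);
      v_v.emplace_back(p->n_elem, arma::fill::zeros);
    }
  }
  void step(std::vector<fmat*>& mats, std::vector<fmat*>& gmats,
            std::vector<fvec*>& vecs, std::vector<fvec*>& gvecs) {
    ++t;
    // global-norm gradient clipping stabilizes the first Adam steps
    const float clip = 5.0f;
    double sq = 0.0;
    for (auto* g : gmats) sq += arma::dot(*g, *g);
    for (auto* g : gvecs) sq += arma::dot(*g, *g);
    const double norm = std::sqrt(sq);
    if (norm > clip) {
      const float s = (float)(clip / norm);
      for (auto* g : gmats) *g *= s;
      for (auto* g : gvecs) *g *= s;
    }
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < mats.size(); ++i) {
      m_m[i] = b1 * m_m[i] + (1 - b1) * (*gmats[i]);
      v_m[i] = b2 * v_m[i] + (1 - b2) * arma::square(*gmats[i]);
      *mats[i] -= lr * (m_m[i] / c1) / (arma::sqrt(v_m[i] / c2) + eps);
    }
    for (size_t i = 0; i < vecs.size(); ++i) {
      m_v[i] = b1 * m_v[i] + (1 - b1) * (*gvecs[i]);
      v_v[i] = b2 * v_v[i] + (1 - b2) * arma::square(*gvecs[i]);
      *vecs[i] -= lr * (m_v[i] / c1) / (arma::sqrt(v_v[i] / c2) + eps);
    }
  }
};

static double eval_loss_acc(Net& net, const IntegerMatrix& X,
                            const IntegerMatrix& Y,
                            const std::vector<int>& ids, int batch,
                            double* acc_out) {
  FwdCache f;
  double loss = 0.0;
  int correct = 0;
  size_t done = 0;
  while (done < ids.size()) {
    const size_t b0 = done, b1 = std::min(done + (size_t)batch, ids.size());
    std::vector<int> chunk(ids.begin() + b0, ids.begin() + b1);
    forward(net, X, chunk, false, f);
    loss += batch_loss(f.probs, Y, chunk) * chunk.size();
    for (size_t b = 0; b < chunk.size(); ++b) {
      bool ok = true;
      for (int h = 0; h < NHEAD; ++h) {
        int arg = 0;
        for (int k = 1; k < NCLASS; ++k)
          if (f.probs(h * NCLASS + k, b) > f.probs(h * NCLASS + arg, b)) arg = k;
        if (arg != Y(chunk[b], h)) { ok = false; break; }
      }
      if (ok) ++correct;
    }
    done = b1;
  }
  if (acc_out) *acc_out = (double)correct / ids.size();
  return loss / ids.size();
}

// [[Rcpp::export]]
List cnn_train_cpp(List params, IntegerMatrix X, IntegerMatrix Y,
                   IntegerVector train_idx, IntegerVector val_idx,
                   int epochs, int batch, double lr, bool verbose) {
  if (X.ncol() != HW0) stop("frames must be %d pixels", HW0);
  if (Y.ncol() != NHEAD) stop("labels must have 3 slots");
  RNGScope scope;
  Net net = net_from_list(params);
  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());

  std::vector<fmat*> mats = { &net.W1c, &net.W2c, &net.W3c, &net.Wh };
  std::vector<fvec*> vecs = { &net.g1, &net.b1, &net.g2, &net.b2,
                              &net.g3, &net.b3, &net.bh };
  Adam opt;
  opt.init(mats, vecs, (float)lr);

  FwdCache f;
  Grads g;
  NumericVector h_train(epochs), h_val(epochs), h_acc(epochs);
  double best_val = R_PosInf;
  int best_epoch = 0;
  Net best = net;

  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates shuffle from R's RNG
    for (int i = (int)tr.size() - 1; i > 0; --i) {
      const int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(tr[i], tr[j]);
    }
    double ep_loss = 0.0;
    size_t seen = 0, done = 0;
    while (done < tr.size()) {
      const size_t b1 = std::min(done + (size_t)batch, tr.size());
      if (b1 - done < 2) break;  // batch-norm needs >= 2 samples
      std::vector<int> chunk(tr.begin() + done, tr.begin() + b1);
      forward(net, X, chunk, true, f);
      ep_loss += batch_loss(f.probs, Y, chunk) * chunk.size();
      seen += chunk.size();
      backward(net, Y, chunk, f, g);
      std::vector<fmat*> gm = { &g.dW1, &g.dW2, &g.dW3, &g.dWh };
      std::vector<fvec*> gv = { &g.dg1, &g.db1, &g.dg2, &g.db2,
                                &g.dg3, &g.db3, &g.dbh };
      opt.step(mats, gm, vecs, gv);
      done = b1;
      Rcpp::checkUserInterrupt();
    }
    double vacc = 0.0;
    const double vloss = va.empty() ? ep_loss / seen
      : eval_loss_acc(net, X, Y, va, batch, &vacc);
    h_train[e] = ep_loss / seen;
    h_val[e] = vloss;
    h_acc[e] = vacc;
    if (vloss < best_val) {
      best_val = vloss;
      best_epoch = e + 1;
      best = net;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (e + 1) << "/" << epochs
                  << "  train loss " << h_train[e]
                  << "  val loss " << vloss
                  << "  val seq acc " << vacc << "\n";
  }
  return List::create(
    _["params"] = net_to_list(best),
    _["history"] = DataFrame::create(_["epoch"] = seq_len(epochs),
                                     _["train_loss"] = h_train,
                                     _["val_loss"] = h_val,
                                     _["val_seq_acc"] = h_acc),
    _["best_epoch"] = best_epoch,
    _["best_val_loss"] = best_val);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List params, IntegerMatrix X, int batch = 64) {
  if (X.ncol() != HW0) stop("frames must be %d pixels", HW0);
  Net net = net_from_list(params);
  const int n = X.nrow();
  NumericMatrix out(n, NLOGIT);
  FwdCache f;
  int done = 0;
  while (done < n) {
    const int b1 = std::min(done + batch, n);
    std::vector<int> chunk;
    for (int i = done; i < b1; ++i) chunk.push_back(i);
    forward(net, X, chunk, false, f);
    for (size_t b = 0; b < chunk.size(); ++b)
      for (int k = 0; k < NLOGIT; ++k) out(chunk[b], k) = f.probs(k, b);
    done = b1;
  }
  return out;
}

// loss and analytic parameter gradients for one (training-mode) batch —
// exposed for finite-difference gradient verification in the test suite
// [[Rcpp::export]]
List cnn_loss_grad_cpp(List params, IntegerMatrix X, IntegerMatrix Y,
                       IntegerVector idx) {
  Net net = net_from_list(params);
  std::vector<int> ids(idx.begin(), idx.end());
  FwdCache f;
  Grads g;
  forward(net, X, ids, true, f);
  const double loss = batch_loss(f.probs, Y, ids);
  backward(net, Y, ids, f, g);
  return List::create(
    _["loss"] = loss,
    _["dW1"] = to_rmat(g.dW1), _["dW2"] = to_rmat(g.dW2),
    _["dW3"] = to_rmat(g.dW3), _["dWh"] = to_rmat(g.dWh),
    _["dgamma1"] = to_rvec(g.dg1), _["dbeta1"] = to_rvec(g.db1),
    _["dgamma2"] = to_rvec(g.dg2), _["dbeta2"] = to_rvec(g.db2),
    _["dgamma3"] = to_rvec(g.dg3), _["dbeta3"] = to_rvec(g.db3),
    _["dbh"] = to_rvec(g.dbh));
}
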