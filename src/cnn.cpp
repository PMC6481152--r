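// Compact CNN engine for the detector/segmentator networks.
//
// Fixed architecture family: six 3x3 stride-1 convolutions (zero padding in
// "same" mode, none in "valid" mode), 2x2 max-pooling (floor) after conv 1
// and conv 2, then FC-64 and FC-K. Each conv block runs conv -> ReLU ->
// batch-norm (-> pool); the FC-64 block runs affine -> ReLU -> batch-norm ->
// inverted dropout. Batch-norm normalizes over batch x spatial positions per
// channel.
//
// Data layout: a layer's activations are one (C x h*w*B) matrix — one column
// per pixel, images consecutive, pixels column-major within an image. Every
// convolution is then a single GEMM against im2col columns ordered
// (kernel-offset-major, channel-minor), which keeps single-threaded BLAS
// efficient for both minibatch training and high-volume per-pixel inference.
// Heavy tensors are single precision (parameters and results cross the R
// boundary as doubles); gradients are verified against finite differences
// in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;


static inline void relu_inplace(arma::fmat& Z) {
  float* p = Z.memptr();
  const size_t n = Z.n_elem;
  for (size_t k = 0; k < n; ++k) if (p[k] < 0) p[k] = 0;
}

// zero the entries of dZ where the stored (post-ReLU) activation is <= 0
static inline void relu_mask(arma::fmat& dZ, const arma::fmat& A) {
  float* d = dZ.memptr();
  const float* a = A.memptr();
  const size_t n = dZ.n_elem;
  for (size_t k = 0; k < n; ++k) if (a[k] <= 0) d[k] = 0;
}

// cols(k*C + c, (b-b0)*ho*wo + j*ho + i) =
//   A(c, b*h*w + (j-pad+kj)*h + (i-pad+ki)) with k = kj*3 + ki; out-of-image
// taps are zero ("same" mode only). Operates on the image sub-range
// [b0, b1) so callers can keep the working set cache-resident.
static void im2col_range(const arma::fmat& A, int h, int w, int b0, int b1,
                         int pad, arma::fmat& cols) {
  const int C = A.n_rows;
  const int ho = h + 2 * pad - 2, wo = w + 2 * pad - 2;
  if (pad > 0) cols.zeros();
  for (int b = b0; b < b1; ++b) {
    const size_t src0 = (size_t)b * h * w, dst0 = (size_t)(b - b0) * ho * wo;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        float* dst = cols.colptr(dst0 + (size_t)j * ho + i);
        for (int kj = 0; kj < 3; ++kj) {
          const int cc = j - pad + kj;
          if (cc < 0 || cc >= w) continue;
          for (int ki = 0; ki < 3; ++ki) {
            const int r = i - pad + ki;
            if (r < 0 || r >= h) continue;
            float* d = dst + (size_t)(kj * 3 + ki) * C;
            const float* s = A.colptr(src0 + (size_t)cc * h + r);
            for (int c = 0; c < C; ++c) d[c] = s[c];
          }
        }
      }
    }
  }
}

// fused ReLU + batch-norm (inference form): z <- max(z, 0) * a + v, with
// a = gamma / sqrt(var + eps) and v = beta - mean * a precomputed per channel
static void relu_bn_inplace(arma::fmat& Z, const arma::fvec& a,
                            const arma::fvec& v) {
  const int C = Z.n_rows;
  const size_t n = Z.n_cols;
  for (size_t col = 0; col < n; ++col) {
    float* z = Z.colptr(col);
    for (int c = 0; c < C; ++c) {
      const float x = z[c] > 0 ? z[c] : 0.0f;
      z[c] = x * a[c] + v[c];
    }
  }
}

// conv sub-batch size: keeps the im2col working set within typical L2/L3
static int conv_chunk(int B) { return std::min(B, 32); }

// Z = W * im2col(A) + b, ReLU, over the whole batch in cache-sized chunks.
static arma::fmat conv_forward(const arma::fmat& A, const arma::fmat& W,
                              const arma::fvec& b, int h, int w, int B,
                              int pad, int& ho, int& wo) {
  const int C = A.n_rows;
  ho = h + 2 * pad - 2;
  wo = w + 2 * pad - 2;
  const size_t npix = (size_t)ho * wo;
  arma::fmat Z(W.n_rows, npix * B);
  const int chunk = conv_chunk(B);
  arma::fmat cols;
  for (int b0 = 0; b0 < B; b0 += chunk) {
    const int b1 = std::min(B, b0 + chunk);
    if ((int)cols.n_cols != (int)(npix * (b1 - b0))) {
      cols.set_size((size_t)9 * C, npix * (b1 - b0));
    }
    im2col_range(A, h, w, b0, b1, pad, cols);
    Z.cols(npix * b0, npix * b1 - 1) = W * cols;
  }
  Z.each_col() += b;
  relu_inplace(Z);
  return Z;
}

// dW = dZ * im2col(A)^T, db = rowsum(dZ), dA = col2im(W^T dZ), chunked like
// the forward pass; dA is skipped when request_dA is false (first layer).
static void conv_backward(const arma::fmat& A, const arma::fmat& W,
                          const arma::fmat& dZ, int h, int w, int B, int pad,
                          bool request_dA, arma::fmat& dW, arma::fvec& db,
                          arma::fmat& dA) {
  const int C = A.n_rows;
  const int ho = h + 2 * pad - 2, wo = w + 2 * pad - 2;
  const size_t npix = (size_t)ho * wo;
  dW.zeros(W.n_rows, W.n_cols);
  db = sum(dZ, 1);
  if (request_dA) dA.zeros(C, (size_t)h * w * B);
  const int chunk = conv_chunk(B);
  arma::fmat cols;
  for (int b0 = 0; b0 < B; b0 += chunk) {
    const int b1 = std::min(B, b0 + chunk);
    if ((int)cols.n_cols != (int)(npix * (b1 - b0))) {
      cols.set_size((size_t)9 * C, npix * (b1 - b0));
    }
    im2col_range(A, h, w, b0, b1, pad, cols);
    const arma::fmat dZc = dZ.cols(npix * b0, npix * b1 - 1);
    dW += dZc * cols.t();
    if (request_dA) {
      arma::fmat dcols = W.t() * dZc;
      // scatter back into dA over images [b0, b1)
      for (int b = b0; b < b1; ++b) {
        const size_t src0 = (size_t)(b - b0) * npix, dst0 = (size_t)b * h * w;
        for (int j = 0; j < wo; ++j) {
          for (int i = 0; i < ho; ++i) {
            const float* src = dcols.colptr(src0 + (size_t)j * ho + i);
            for (int kj = 0; kj < 3; ++kj) {
              const int cc = j - pad + kj;
              if (cc < 0 || cc >= w) continue;
              for (int ki = 0; ki < 3; ++ki) {
                const int r = i - pad + ki;
                if (r < 0 || r >= h) continue;
                float* dst = dA.colptr(dst0 + (size_t)cc * h + r);
                const float* s = src + (size_t)(kj * 3 + ki) * C;
                for (int c = 0; c < C; ++c) dst[c] += s[c];
              }
            }
          }
        }
      }
    }
  }
}

// 2x2 max pool, stride 2, floor on odd sides; first maximum wins on ties.
// arg(c, out_col) stores the source column of the per-channel maximum.
static arma::fmat pool_batch(const arma::fmat& A, int h, int w, int B,
                            arma::umat& arg) {
  const int C = A.n_rows, h2 = h / 2, w2 = w / 2;
  arma::fmat P(C, (size_t)h2 * w2 * B);
  arg.set_size(C, (size_t)h2 * w2 * B);
  for (int b = 0; b < B; ++b) {
    const size_t src0 = (size_t)b * h * w, dst0 = (size_t)b * h2 * w2;
    for (int j = 0; j < w2; ++j) {
      for (int i = 0; i < h2; ++i) {
        const size_t dst = dst0 + (size_t)j * h2 + i;
        const size_t s00 = src0 + (size_t)(2 * j) * h + 2 * i;
        const size_t cand[4] = {s00, s00 + 1, s00 + h, s00 + h + 1};
        const float* p0 = A.colptr(cand[0]);
        const float* p1 = A.colptr(cand[1]);
        const float* p2 = A.colptr(cand[2]);
        const float* p3 = A.colptr(cand[3]);
        float* q = P.colptr(dst);
        uword* a = arg.colptr(dst);
        for (int c = 0; c < C; ++c) {
          float best = p0[c];
          int bi = 0;
          if (p1[c] > best) { best = p1[c]; bi = 1; }
          if (p2[c] > best) { best = p2[c]; bi = 2; }
          if (p3[c] > best) { best = p3[c]; bi = 3; }
          q[c] = best;
          a[c] = cand[bi];
        }
      }
    }
  }
  return P;
}

// engine-internal single precision: parameters arrive as R doubles and are
// converted once per call; all heavy tensors are float for bandwidth
struct Params {
  std::vector<fmat> Wc;
  std::vector<fvec> bc, gc, betac;
  fmat Wf1, Wf2;
  fvec bf1, gf1, betaf1, bf2;
};

static fmat f32m(SEXP x) { return conv_to<fmat>::from(as<mat>(x)); }
static fvec f32v(SEXP x) { return conv_to<fvec>::from(as<vec>(x)); }

static Params parse_params(const List& params) {
  Params P;
  List conv = params["conv"];
  for (int l = 0; l < 6; ++l) {
    List cl = conv[l];
    P.Wc.push_back(f32m(cl["W"]));
    P.bc.push_back(f32v(cl["b"]));
    P.gc.push_back(f32v(cl["gamma"]));
    P.betac.push_back(f32v(cl["beta"]));
  }
  List f1 = params["fc1"], f2 = params["fc2"];
  P.Wf1 = f32m(f1["W"]); P.bf1 = f32v(f1["b"]);
  P.gf1 = f32v(f1["gamma"]); P.betaf1 = f32v(f1["beta"]);
  P.Wf2 = f32m(f2["W"]); P.bf2 = f32v(f2["b"]);
  return P;
}

static arma::fmat input_to_fmat(const arma::cube& X) {
  const int N = X.n_rows, B = X.n_slices;
  arma::fmat A(1, (size_t)N * N * B);
  const double* src = X.memptr();
  float* dst = A.memptr();
  for (size_t k = 0; k < A.n_elem; ++k) dst[k] = (float)src[k];
  return A;
}

static arma::mat softmax_cols(const arma::fmat& Zf) {
  arma::mat Z = conv_to<mat>::from(Zf);
  rowvec zmax = max(Z, 0);
  Z.each_row() -= zmax;
  Z = exp(Z);
  rowvec zs = sum(Z, 0);
  Z.each_row() /= zs;
  return Z;
}

static arma::mat d64(const arma::fmat& x) { return conv_to<mat>::from(x); }
static arma::vec d64v(const arma::fvec& x) { return conv_to<vec>::from(x); }

// Forward + backward over one minibatch; returns loss, accuracy, gradients
// for every learnable parameter and the per-layer batch statistics needed to
// update batch-norm running averages.
// [[Rcpp::export]]
List cpp_net_grad(List params, const arma::cube& X, const arma::mat& Y,
                  int pad, const arma::mat& dropmask, double bn_eps) {
  Params P = parse_params(params);
  const int B = X.n_slices;

  std::vector<fmat> Xs(7), As(6);
  std::vector<fvec> mus(6), vars(6), sds(6);
  std::vector<umat> args(2);
  std::vector<int> hs(7), ws(7);

  Xs[0] = input_to_fmat(X);
  hs[0] = X.n_rows; ws[0] = X.n_cols;

  for (int l = 0; l < 6; ++l) {
    int ho, wo;
    fmat Z = conv_forward(Xs[l], P.Wc[l], P.bc[l], hs[l], ws[l], B, pad,
                          ho, wo);
    As[l] = Z;
    // mean/variance accumulated in double for stability, stored as float
    vec acc1(Z.n_rows, fill::zeros), acc2(Z.n_rows, fill::zeros);
    for (size_t col = 0; col < Z.n_cols; ++col) {
      const float* z = Z.colptr(col);
      for (uword c = 0; c < Z.n_rows; ++c) {
        acc1(c) += z[c];
        acc2(c) += (double)z[c] * z[c];
      }
    }
    const double m = (double)Z.n_cols;
    mus[l] = conv_to<fvec>::from(acc1 / m);
    vars[l] = conv_to<fvec>::from(
        clamp(acc2 / m - square(acc1 / m), 0.0, datum::inf));
    sds[l] = sqrt(vars[l] + (float)bn_eps);
    fmat U = Z.each_col() - mus[l];
    U.each_col() /= sds[l];
    U.each_col() %= P.gc[l];
    U.each_col() += P.betac[l];
    if (l < 2) {
      Xs[l + 1] = pool_batch(U, ho, wo, B, args[l]);
      hs[l + 1] = ho / 2; ws[l + 1] = wo / 2;
    } else {
      Xs[l + 1] = U;
      hs[l + 1] = ho; ws[l + 1] = wo;
    }
  }

  // fully connected head; flatten is a pure reshape in this layout
  const int flat = Xs[6].n_rows * hs[6] * ws[6];
  fmat V = reshape(Xs[6], flat, B);
  fmat Z1 = P.Wf1 * V;
  Z1.each_col() += P.bf1;
  fmat A1 = Z1;
  relu_inplace(A1);
  fvec mu1 = mean(A1, 1);
  fvec var1 = clamp(mean(square(A1), 1) - square(mu1), 0.0f,
                    std::numeric_limits<float>::infinity());
  fvec sd1 = sqrt(var1 + (float)bn_eps);
  fmat XH1 = A1.each_col() - mu1;
  XH1.each_col() /= sd1;
  fmat U1 = XH1.each_col() % P.gf1;
  U1.each_col() += P.betaf1;
  fmat drop = conv_to<fmat>::from(dropmask);
  fmat D1 = U1 % drop;
  fmat Z2 = P.Wf2 * D1;
  Z2.each_col() += P.bf2;
  mat Pr = softmax_cols(Z2);

  const double loss = -accu(Y % log(Pr + 1e-300)) / B;
  uvec pred = index_max(Pr, 0).t(), truth = index_max(Y, 0).t();
  const double acc = (double)accu(pred == truth) / B;

  // backward
  fmat dZ2 = conv_to<fmat>::from((Pr - Y) / B);
  fmat dWf2 = dZ2 * D1.t();
  fvec dbf2 = sum(dZ2, 1);
  fmat dU1 = (P.Wf2.t() * dZ2) % drop;
  fvec dgf1 = sum(dU1 % XH1, 1), dbetaf1 = sum(dU1, 1);
  fmat dXH = dU1.each_col() % P.gf1;
  fvec m1 = mean(dXH, 1), m2 = mean(dXH % XH1, 1);
  fmat dA1 = dXH;
  dA1.each_col() -= m1;
  dA1 -= XH1.each_col() % m2;
  dA1.each_col() /= sd1;
  fmat dZ1 = dA1;
  relu_mask(dZ1, Z1);
  fmat dWf1 = dZ1 * V.t();
  fvec dbf1 = sum(dZ1, 1);
  fmat dX = reshape(P.Wf1.t() * dZ1, Xs[6].n_rows, (size_t)hs[6] * ws[6] * B);

  std::vector<fmat> dWc(6);
  std::vector<fvec> dbc(6), dgc(6), dbetac(6);
  for (int l = 5; l >= 0; --l) {
    fmat dU;
    if (l < 2) {
      // scatter pooled gradients back to the pre-pool positions
      dU.zeros(As[l].n_rows, As[l].n_cols);
      const umat& ar = args[l];
      for (size_t col = 0; col < dX.n_cols; ++col) {
        const float* src = dX.colptr(col);
        const uword* a = ar.colptr(col);
        for (uword c = 0; c < dX.n_rows; ++c) dU(c, a[c]) += src[c];
      }
    } else {
      dU = dX;
    }
    fmat XH = As[l].each_col() - mus[l];
    XH.each_col() /= sds[l];
    dgc[l] = sum(dU % XH, 1);
    dbetac[l] = sum(dU, 1);
    fmat dxh = dU.each_col() % P.gc[l];
    fvec c1 = mean(dxh, 1), c2 = mean(dxh % XH, 1);
    fmat dZ = dxh;
    dZ.each_col() -= c1;
    dZ -= XH.each_col() % c2;
    dZ.each_col() /= sds[l];
    relu_mask(dZ, As[l]);
    fmat dA;
    conv_backward(Xs[l], P.Wc[l], dZ, hs[l], ws[l], B, pad, l > 0,
                  dWc[l], dbc[l], dA);
    if (l > 0) dX = std::move(dA);
  }

  List gconv(6), bn_batch(7);
  for (int l = 0; l < 6; ++l) {
    gconv[l] = List::create(_["W"] = d64(dWc[l]), _["b"] = d64v(dbc[l]),
                            _["gamma"] = d64v(dgc[l]),
                            _["beta"] = d64v(dbetac[l]));
    bn_batch[l] = List::create(_["mean"] = d64v(mus[l]),
                               _["var"] = d64v(vars[l]));
  }
  bn_batch[6] = List::create(_["mean"] = d64v(mu1), _["var"] = d64v(var1));
  List grads = List::create(
      _["conv"] = gconv,
      _["fc1"] = List::create(_["W"] = d64(dWf1), _["b"] = d64v(dbf1),
                              _["gamma"] = d64v(dgf1),
                              _["beta"] = d64v(dbetaf1)),
      _["fc2"] = List::create(_["W"] = d64(dWf2), _["b"] = d64v(dbf2)));
  return List::create(_["loss"] = loss, _["acc"] = acc, _["grads"] = grads,
                      _["bn_batch"] = bn_batch);
}

// Inference forward pass using batch-norm running statistics; no dropout.
// Returns class posteriors (softmax over the K = 2 scores) and the spatial
// side of the last convolutional feature map.
// [[Rcpp::export]]
List cpp_net_predict(List params, List bn_stats, const arma::cube& X,
                     int pad, double bn_eps) {
  Params P = parse_params(params);
  const int B = X.n_slices;
  fmat A = input_to_fmat(X);
  int h = X.n_rows, w = X.n_cols;
  for (int l = 0; l < 6; ++l) {
    int ho, wo;
    fmat Z = conv_forward(A, P.Wc[l], P.bc[l], h, w, B, pad, ho, wo);
    List st = bn_stats[l];
    fvec rm = f32v(st["mean"]), rv = f32v(st["var"]);
    fvec a = P.gc[l] / sqrt(rv + (float)bn_eps);
    fvec v = P.betac[l] - rm % a;
    relu_bn_inplace(Z, a, v);
    if (l < 2) {
      umat arg;
      A = pool_batch(Z, ho, wo, B, arg);
      h = ho / 2; w = wo / 2;
    } else {
      A = Z;
      h = ho; w = wo;
    }
  }
  const int feat_side = h;
  fmat V = reshape(A, A.n_rows * h * w, B);
  fmat Z1 = P.Wf1 * V;
  Z1.each_col() += P.bf1;
  List st = bn_stats[6];
  fvec rm = f32v(st["mean"]), rv = f32v(st["var"]);
  fvec a = P.gf1 / sqrt(rv + (float)bn_eps);
  fvec v = P.betaf1 - rm % a;
  relu_bn_inplace(Z1, a, v);
  fmat Z2 = P.Wf2 * Z1;
  Z2.each_col() += P.bf2;
  return List::create(_["prob"] = softmax_cols(Z2),
                      _["feat_side"] = feat_side);
}

// Extract N x N windows centred at (rows, cols) (1-based, in unpadded image
// coordinates) from an image already reflect-padded by (N-1)/2 on every side.
// [[Rcpp::export]]
arma::cube cpp_extract_patches(const arma::mat& padded,
                               const arma::ivec& rows, const arma::ivec& cols,
                               int N) {
  const int n = rows.n_elem;
  arma::cube out(N, N, n);
  for (int k = 0; k < n; ++k) {
    // centre (r, c) in original coords maps to top-left (r-1, c-1) in padded
    out.slice(k) = padded.submat(rows(k) - 1, cols(k) - 1,
                                 rows(k) + N - 2, cols(k) + N - 2);
  }
  return out;
}

// Connected-component labelling of a binary mask (4- or 8-connectivity),
// flood fill; labels assigned in raster-scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask,
                                   int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<std::pair<int, int>> off = {{-1, 0}, {1, 0}, {0, -1}, {0, 1}};
  if (connectivity == 8) {
    off.push_back({-1, -1});
    off.push_back({-1, 1});
    off.push_back({1, -1});
    off.push_back({1, 1});
  }
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (auto [dr, dc] : off) {
          const int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}
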