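// 3D convolutional denoiser: fused forward/backward passes.
//
// Feature maps are stored channel-major, [C x Nvox], with voxel linear index
// v = y + H*(x + W*z) (matches R's column-major array layout for [H,W,D]).
// The hidden convolutions are "same" zero-padded, realized as im2col + GEMM
// so the heavy lifting lands in BLAS; the single-channel decoder head is
// evaluated by shift-accumulation, which keeps its working set in cache
// instead of materializing a taps*K x Nvox column matrix. Arithmetic is
// single precision (standard for CNN training); parameters and gradients
// cross the R boundary as doubles.
//
// Architecture (fixed residual encoder-bottleneck-decoder with a skip
// connection; the noise estimate is high-frequency, so the decoder head
// must see the full-resolution encoder features as well as the pooled
// context):
//   conv1 (1->K, ReLU) -> maxpool (ph,pw,pd) -> conv2 (K->K, ReLU,
//   bottleneck) -> nearest upsample; head conv3 ([A1 ; up(A2)] 2K -> 1,
//   linear) = noise estimate r;  denoised = input - r
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef arma::fmat FMat;
typedef arma::fvec FVec;

// Fill col [taps*Cin x Nvox] from F [Cin x Nvox]. Entries for out-of-range
// taps are never touched: callers zero col once per batch (the zero pattern
// is shape-dependent, not data-dependent).
static void im2col3d(const FMat& F, FMat& col,
                     int H, int W, int D, int kh, int kw, int kd) {
  const int Cin = F.n_rows;
  const int rh = kh / 2, rw = kw / 2, rd = kd / 2;
  int t = 0;
  for (int tz = -rd; tz <= rd; ++tz)
    for (int tx = -rw; tx <= rw; ++tx)
      for (int ty = -rh; ty <= rh; ++ty, ++t) {
        for (int z = 0; z < D; ++z) {
          const int sz = z + tz;
          if (sz < 0 || sz >= D) continue;
          for (int x = 0; x < W; ++x) {
            const int sx = x + tx;
            if (sx < 0 || sx >= W) continue;
            const int y0 = std::max(0, -ty), y1 = std::min(H, H - ty);
            for (int y = y0; y < y1; ++y) {
              const int v = y + H * (x + W * z);
              const int s = (y + ty) + H * (sx + W * sz);
              std::memcpy(col.colptr(v) + Cin * t, F.colptr(s),
                          Cin * sizeof(float));
            }
          }
        }
      }
}

// Scatter-add transpose of im2col3d: dF += "unfolded" dcol.
static void col2im3d_add(const FMat& dcol, FMat& dF,
                         int H, int W, int D, int kh, int kw, int kd) {
  const int Cin = dF.n_rows;
  const int rh = kh / 2, rw = kw / 2, rd = kd / 2;
  int t = 0;
  for (int tz = -rd; tz <= rd; ++tz)
    for (int tx = -rw; tx <= rw; ++tx)
      for (int ty = -rh; ty <= rh; ++ty, ++t) {
        for (int z = 0; z < D; ++z) {
          const int sz = z + tz;
          if (sz < 0 || sz >= D) continue;
          for (int x = 0; x < W; ++x) {
            const int sx = x + tx;
            if (sx < 0 || sx >= W) continue;
            const int y0 = std::max(0, -ty), y1 = std::min(H, H - ty);
            for (int y = y0; y < y1; ++y) {
              const int v = y + H * (x + W * z);
              const int s = (y + ty) + H * (sx + W * sz);
              float* dst = dF.colptr(s);
              const float* src = dcol.colptr(v) + Cin * t;
              for (int c = 0; c < Cin; ++c) dst[c] += src[c];
            }
          }
        }
      }
}

static void maxpool_fwd(const FMat& F, FMat& out, arma::umat& idx,
                        int H, int W, int D, int ph, int pw, int pd) {
  const int K = F.n_rows;
  const int Ho = H / ph, Wo = W / pw, Do = D / pd;
  for (int z = 0; z < Do; ++z)
    for (int x = 0; x < Wo; ++x)
      for (int y = 0; y < Ho; ++y) {
        const int vo = y + Ho * (x + Wo * z);
        float* po = out.colptr(vo);
        arma::uword* pi = idx.colptr(vo);
        bool first = true;
        for (int bz = 0; bz < pd; ++bz)
          for (int bx = 0; bx < pw; ++bx)
            for (int by = 0; by < ph; ++by) {
              const int s = (y * ph + by) +
                            H * ((x * pw + bx) + W * (z * pd + bz));
              const float* ps = F.colptr(s);
              if (first) {
                for (int k = 0; k < K; ++k) { po[k] = ps[k]; pi[k] = s; }
                first = false;
              } else {
                for (int k = 0; k < K; ++k)
                  if (ps[k] > po[k]) { po[k] = ps[k]; pi[k] = s; }
              }
            }
      }
}

static void maxpool_bwd(const FMat& dout, const arma::umat& idx, FMat& dF) {
  const int K = dout.n_rows;
  dF.zeros();
  for (arma::uword vo = 0; vo < dout.n_cols; ++vo) {
    const float* pd = dout.colptr(vo);
    const arma::uword* pi = idx.colptr(vo);
    for (int k = 0; k < K; ++k) dF(k, pi[k]) += pd[k];
  }
}

static void upsample_fwd(const FMat& Fh, FMat& out,
                         int H, int W, int D, int ph, int pw, int pd) {
  const int Ho = H / ph, Wo = W / pw;
  for (int z = 0; z < D; ++z)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        const int v = y + H * (x + W * z);
        const int s = (y / ph) + Ho * ((x / pw) + Wo * (z / pd));
        out.col(v) = Fh.col(s);
      }
}

static void upsample_bwd(const FMat& dout, FMat& dFh,
                         int H, int W, int D, int ph, int pw, int pd) {
  const int Ho = H / ph, Wo = W / pw;
  dFh.zeros();
  for (int z = 0; z < D; ++z)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        const int v = y + H * (x + W * z);
        const int s = (y / ph) + Ho * ((x / pw) + Wo * (z / pd));
        dFh.col(s) += dout.col(v);
      }
}

struct NetShape {
  int H, W, D, K, kh, kw, kd, ph, pw, pd;
  int N, Hh, Wh, Dh, Nh, taps1, taps2, taps3;
};

static NetShape net_shape(const IntegerVector& dims, int K,
                          const IntegerVector& kernel,
                          const IntegerVector& pool) {
  NetShape s;
  s.H = dims[0]; s.W = dims[1]; s.D = dims[2]; s.K = K;
  s.kh = kernel[0]; s.kw = kernel[1]; s.kd = kernel[2];
  s.ph = pool[0]; s.pw = pool[1]; s.pd = pool[2];
  if (s.H % s.ph || s.W % s.pw || s.D % s.pd)
    stop("patch dims must be divisible by pool dims");
  s.N = s.H * s.W * s.D;
  s.Hh = s.H / s.ph; s.Wh = s.W / s.pw; s.Dh = s.D / s.pd;
  s.Nh = s.Hh * s.Wh * s.Dh;
  s.taps1 = s.kh * s.kw * s.kd;        // Cin = 1
  s.taps2 = s.taps1 * s.K;             // Cin = K
  s.taps3 = s.taps1 * 2 * s.K;         // head input: [A1 ; up(A2)]
  return s;
}

struct Params {
  FMat W1, W2;
  FVec b1, b2, W3;   // W3 flattened [taps2]
  float b3;
  Params(const List& p)
      : W1(as<arma::mat>(p["W1"]).n_rows, as<arma::mat>(p["W1"]).n_cols) {
    W1 = arma::conv_to<FMat>::from(as<arma::mat>(p["W1"]));
    W2 = arma::conv_to<FMat>::from(as<arma::mat>(p["W2"]));
    b1 = arma::conv_to<FVec>::from(as<arma::vec>(p["b1"]));
    b2 = arma::conv_to<FVec>::from(as<arma::vec>(p["b2"]));
    arma::mat w3 = as<arma::mat>(p["W3"]);
    W3 = arma::conv_to<FVec>::from(arma::vectorise(w3));
    b3 = (float)as<arma::vec>(p["b3"])(0);
  }
};

struct Workspace {
  FMat F0, col1, A1, P, col2, A2, U, S, R3;
  arma::umat pidx;
  Workspace(const NetShape& s)
      : F0(1, s.N), col1(s.taps1, s.N), A1(s.K, s.N), P(s.K, s.Nh),
        col2(s.taps2, s.Nh), A2(s.K, s.Nh), U(s.K, s.N), S(2 * s.K, s.N),
        R3(1, s.N), pidx(s.K, s.Nh) {
    col1.zeros();   // boundary-tap entries stay zero across items
    col2.zeros();
  }
};

// Decoder head: single-output "same" convolution by shift-accumulation
// over the stacked features S = [A1 ; up(A2)] (2K channels).
// R3[v] = b3 + sum_t dot(W3[t-block], S[:, src(v,t)])
static void head_fwd(const FMat& S, const FVec& W3, float b3, FMat& R3,
                     const NetShape& s) {
  R3.fill(b3);
  const int rh = s.kh / 2, rw = s.kw / 2, rd = s.kd / 2;
  const int C = 2 * s.K;
  float* out = R3.memptr();
  int t = 0;
  for (int tz = -rd; tz <= rd; ++tz)
    for (int tx = -rw; tx <= rw; ++tx)
      for (int ty = -rh; ty <= rh; ++ty, ++t) {
        const float* wt = W3.memptr() + C * t;
        for (int z = 0; z < s.D; ++z) {
          const int sz = z + tz;
          if (sz < 0 || sz >= s.D) continue;
          for (int x = 0; x < s.W; ++x) {
            const int sx = x + tx;
            if (sx < 0 || sx >= s.W) continue;
            const int y0 = std::max(0, -ty), y1 = std::min(s.H, s.H - ty);
            for (int y = y0; y < y1; ++y) {
              const int v = y + s.H * (x + s.W * z);
              const float* u = S.colptr((y + ty) + s.H * (sx + s.W * sz));
              float acc = 0;
              for (int c = 0; c < C; ++c) acc += wt[c] * u[c];
              out[v] += acc;
            }
          }
        }
      }
}

static void head_bwd(const FMat& S, const FVec& W3, const FMat& dR3,
                     FVec& gW3, float& gb3, FMat& dS, const NetShape& s) {
  const int rh = s.kh / 2, rw = s.kw / 2, rd = s.kd / 2;
  const int C = 2 * s.K;
  const float* dr = dR3.memptr();
  gb3 += arma::accu(dR3);
  dS.zeros();
  int t = 0;
  for (int tz = -rd; tz <= rd; ++tz)
    for (int tx = -rw; tx <= rw; ++tx)
      for (int ty = -rh; ty <= rh; ++ty, ++t) {
        const float* wt = W3.memptr() + C * t;
        float* gw = gW3.memptr() + C * t;
        for (int z = 0; z < s.D; ++z) {
          const int sz = z + tz;
          if (sz < 0 || sz >= s.D) continue;
          for (int x = 0; x < s.W; ++x) {
            const int sx = x + tx;
            if (sx < 0 || sx >= s.W) continue;
            const int y0 = std::max(0, -ty), y1 = std::min(s.H, s.H - ty);
            for (int y = y0; y < y1; ++y) {
              const int v = y + s.H * (x + s.W * z);
              const int sv = (y + ty) + s.H * (sx + s.W * sz);
              const float g = dr[v];
              const float* u = S.colptr(sv);
              float* du = dS.colptr(sv);
              for (int c = 0; c < C; ++c) {
                gw[c] += g * u[c];
                du[c] += g * wt[c];
              }
            }
          }
        }
      }
}

// Forward pass for one item; x points at N doubles; prediction
// (input - residual) goes to pred (N floats).
static void forward_one(const double* x, const NetShape& s, const Params& pp,
                        Workspace& ws, double* pred) {
  for (int i = 0; i < s.N; ++i) ws.F0(0, i) = (float)x[i];
  im2col3d(ws.F0, ws.col1, s.H, s.W, s.D, s.kh, s.kw, s.kd);
  ws.A1 = pp.W1 * ws.col1;
  ws.A1.each_col() += pp.b1;
  ws.A1.clamp(0.0f, std::numeric_limits<float>::infinity());
  maxpool_fwd(ws.A1, ws.P, ws.pidx, s.H, s.W, s.D, s.ph, s.pw, s.pd);
  im2col3d(ws.P, ws.col2, s.Hh, s.Wh, s.Dh, s.kh, s.kw, s.kd);
  ws.A2 = pp.W2 * ws.col2;
  ws.A2.each_col() += pp.b2;
  ws.A2.clamp(0.0f, std::numeric_limits<float>::infinity());
  upsample_fwd(ws.A2, ws.U, s.H, s.W, s.D, s.ph, s.pw, s.pd);
  ws.S.rows(0, s.K - 1) = ws.A1;             // skip: full-res features
  ws.S.rows(s.K, 2 * s.K - 1) = ws.U;
  head_fwd(ws.S, pp.W3, pp.b3, ws.R3, s);
  // residual subtraction in double: a zero head is the exact identity
  for (int i = 0; i < s.N; ++i) pred[i] = x[i] - (double)ws.R3(0, i);
}

struct Grads {
  FMat gW1, gW2;
  FVec gb1, gb2, gW3;
  float gb3 = 0;
  Grads(const NetShape& s)
      : gW1(s.K, s.taps1, arma::fill::zeros),
        gW2(s.K, s.taps2, arma::fill::zeros),
        gb1(s.K, arma::fill::zeros), gb2(s.K, arma::fill::zeros),
        gW3(s.taps3, arma::fill::zeros) {}
  List as_list() const {
    return List::create(
        _["W1"] = arma::conv_to<arma::mat>::from(gW1),
        _["b1"] = arma::conv_to<arma::vec>::from(gb1),
        _["W2"] = arma::conv_to<arma::mat>::from(gW2),
        _["b2"] = arma::conv_to<arma::vec>::from(gb2),
        _["W3"] = arma::conv_to<arma::mat>::from(
            FMat(gW3.memptr(), 1, gW3.n_elem)),
        _["b3"] = NumericVector::create((double)gb3));
  }
};

// Backward pass from dpred (gradient w.r.t. the denoised output).
static void backward_one(const NetShape& s, const Params& pp, Workspace& ws,
                         const FMat& dpred, Grads& g) {
  FMat dR3 = -dpred;                       // denoised = x - r
  FMat dS(2 * s.K, s.N);
  head_bwd(ws.S, pp.W3, dR3, g.gW3, g.gb3, dS, s);
  FMat dA2(s.K, s.Nh);
  upsample_bwd(dS.rows(s.K, 2 * s.K - 1), dA2, s.H, s.W, s.D, s.ph, s.pw,
               s.pd);
  dA2 %= arma::conv_to<FMat>::from(ws.A2 > 0);
  g.gW2 += dA2 * ws.col2.t();
  g.gb2 += arma::sum(dA2, 1);
  FMat dcol2 = pp.W2.t() * dA2;            // [taps2 x Nh]
  FMat dP(s.K, s.Nh, arma::fill::zeros);
  col2im3d_add(dcol2, dP, s.Hh, s.Wh, s.Dh, s.kh, s.kw, s.kd);
  FMat dA1(s.K, s.N);
  maxpool_bwd(dP, ws.pidx, dA1);
  dA1 += dS.rows(0, s.K - 1);              // skip-connection gradient
  dA1 %= arma::conv_to<FMat>::from(ws.A1 > 0);
  g.gW1 += dA1 * ws.col1.t();              // first layer: no dX needed
  g.gb1 += arma::sum(dA1, 1);
}

// [[Rcpp::export]]
NumericVector cpp_cnn_predict(NumericVector x, List params, IntegerVector dims,
                              int K, IntegerVector kernel, IntegerVector pool,
                              int batch) {
  NetShape s = net_shape(dims, K, kernel, pool);
  Params pp(params);
  Workspace ws(s);
  NumericVector out(x.size());
  for (int b = 0; b < batch; ++b)
    forward_one(&x[0] + (size_t)b * s.N, s, pp, ws,
                &out[0] + (size_t)b * s.N);
  out.attr("dim") = IntegerVector::create(s.H, s.W, s.D, batch);
  return out;
}

// Gradient of mean |vertical first-difference mismatch| w.r.t. pred,
// accumulated into dpred, scaled by w. Returns the raw edge loss.
static double edge_loss_grad(const double* pred, const double* target,
                             const NetShape& s, float w, FMat& dpred) {
  const int M = (s.H - 1) * s.W * s.D;
  double loss = 0.0;
  float* dp = dpred.memptr();
  for (int z = 0; z < s.D; ++z)
    for (int x = 0; x < s.W; ++x) {
      const int base = s.H * (x + s.W * z);
      for (int y = 0; y < s.H - 1; ++y) {
        const double d = (pred[base + y + 1] - pred[base + y]) -
                         (target[base + y + 1] - target[base + y]);
        loss += std::fabs(d);
        const float g = (float)((d > 0) - (d < 0));
        dp[base + y + 1] += w * g / M;
        dp[base + y] -= w * g / M;
      }
    }
  return loss / M;
}

// One training batch: forward, objective alpha*L1 + beta*edge, backward.
// x, y are [H,W,D,B] arrays (noisy input, clean target). Returns parameter
// gradients (objective averaged over the batch) and batch-mean diagnostics.
// [[Rcpp::export]]
List cpp_cnn_train_batch(NumericVector x, NumericVector y, List params,
                         IntegerVector dims, int K, IntegerVector kernel,
                         IntegerVector pool, int batch, double alpha,
                         double beta, double frr_tol) {
  NetShape s = net_shape(dims, K, kernel, pool);
  Params pp(params);
  Workspace ws(s);
  Grads g(s);
  std::vector<double> pred(s.N);
  FMat dpred(1, s.N);
  double l1 = 0, edge = 0, mse = 0, frr = 0;
  for (int b = 0; b < batch; ++b) {
    const double* xb = &x[0] + (size_t)b * s.N;
    const double* yb = &y[0] + (size_t)b * s.N;
    forward_one(xb, s, pp, ws, pred.data());
    dpred.zeros();
    double l1b = 0, mseb = 0, frrb = 0;
    for (int i = 0; i < s.N; ++i) {
      const double e = pred[i] - yb[i];
      l1b += std::fabs(e);
      mseb += e * e;
      if (std::fabs(e) > frr_tol) frrb += 1.0;
      dpred(0, i) = (float)(alpha * ((e > 0) - (e < 0)) / s.N);
    }
    const double edgeb = edge_loss_grad(pred.data(), yb, s, (float)beta,
                                        dpred);
    dpred /= (float)batch;
    backward_one(s, pp, ws, dpred, g);
    l1 += l1b / s.N; mse += mseb / s.N; frr += frrb / s.N; edge += edgeb;
  }
  l1 /= batch; edge /= batch; mse /= batch; frr /= batch;
  return List::create(_["grads"] = g.as_list(), _["l1"] = l1,
                      _["edge"] = edge, _["mse"] = mse, _["frr"] = frr,
                      _["loss"] = alpha * l1 + beta * edge);
}

// Backward pass with an externally supplied dpred (used by the adversarial
// option, whose generator gradient is assembled in R). Recomputes the
// forward intermediates.
// [[Rcpp::export]]
List cpp_cnn_backprop(NumericVector x, NumericVector dpred_in, List params,
                      IntegerVector dims, int K, IntegerVector kernel,
                      IntegerVector pool, int batch) {
  NetShape s = net_shape(dims, K, kernel, pool);
  Params pp(params);
  Workspace ws(s);
  Grads g(s);
  std::vector<double> pred(s.N);
  FMat dpred(1, s.N);
  for (int b = 0; b < batch; ++b) {
    forward_one(&x[0] + (size_t)b * s.N, s, pp, ws, pred.data());
    const double* dd = &dpred_in[0] + (size_t)b * s.N;
    for (int i = 0; i < s.N; ++i) dpred(0, i) = (float)dd[i];
    backward_one(s, pp, ws, dpred, g);
  }
  return g.as_list();
}

// Standalone 3D max pooling over a [X,Y,Z,K] feature array (public op).
// [[Rcpp::export]]
NumericVector cpp_maxpool_op(NumericVector f, IntegerVector dims,
                             IntegerVector pool) {
  const int H = dims[0], W = dims[1], D = dims[2], K = dims[3];
  const int ph = pool[0], pw = pool[1], pd = pool[2];
  if (H % ph || W % pw || D % pd)
    stop("feature dims not divisible by pool dims");
  const int Ho = H / ph, Wo = W / pw, Do = D / pd;
  NumericVector out(Ho * Wo * Do * K);
  for (int k = 0; k < K; ++k) {
    const double* src = &f[0] + (size_t)k * H * W * D;
    double* dst = &out[0] + (size_t)k * Ho * Wo * Do;
    for (int z = 0; z < Do; ++z)
      for (int x = 0; x < Wo; ++x)
        for (int y = 0; y < Ho; ++y) {
          double m = -std::numeric_limits<double>::infinity();
          for (int bz = 0; bz < pd; ++bz)
            for (int bx = 0; bx < pw; ++bx)
              for (int by = 0; by < ph; ++by) {
                const double v = src[(y * ph + by) +
                                     H * ((x * pw + bx) + W * (z * pd + bz))];
                if (v > m) m = v;
              }
          dst[y + Ho * (x + Wo * z)] = m;
        }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Do, K);
  return out;
}
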