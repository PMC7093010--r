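// Convolution kernels for the multitask phenotyping network.
//
// Batches are stored as (C*H*W) x N matrices, one image per column, with
// element index c*H*W + y*W + x (channel-major, then row-major spatial).
// Convolutions are expressed as im2col followed by a single BLAS gemm per
// batch, which is what makes CPU training of the small backbone feasible.
// The training-path forward returns its im2col matrix so the backward pass
// can reuse it, and ReLU is fused into the kernels to avoid extra copies.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col_one(const double* x, double* col,
                       int C, int H, int W, int k, int stride, int pad,
                       int oH, int oW) {
  const int K = C * k * k;
  for (int oy = 0; oy < oH; oy++) {
    for (int ox = 0; ox < oW; ox++) {
      double* cp = col + (size_t)(oy * oW + ox) * K;
      int r = 0;
      for (int c = 0; c < C; c++) {
        const double* xc = x + (size_t)c * H * W;
        for (int ky = 0; ky < k; ky++) {
          const int y = oy * stride - pad + ky;
          for (int kx = 0; kx < k; kx++, r++) {
            const int xx = ox * stride - pad + kx;
            cp[r] = (y >= 0 && y < H && xx >= 0 && xx < W)
              ? xc[(size_t)y * W + xx] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const double* col, double* x,
                       int C, int H, int W, int k, int stride, int pad,
                       int oH, int oW) {
  const int K = C * k * k;
  for (int oy = 0; oy < oH; oy++) {
    for (int ox = 0; ox < oW; ox++) {
      const double* cp = col + (size_t)(oy * oW + ox) * K;
      int r = 0;
      for (int c = 0; c < C; c++) {
        double* xc = x + (size_t)c * H * W;
        for (int ky = 0; ky < k; ky++) {
          const int y = oy * stride - pad + ky;
          for (int kx = 0; kx < k; kx++, r++) {
            const int xx = ox * stride - pad + kx;
            if (y >= 0 && y < H && xx >= 0 && xx < W)
              xc[(size_t)y * W + xx] += cp[r];
          }
        }
      }
    }
  }
}

// Rearrange gemm output (F x N*P) to batch layout (F*P x N), applying ReLU
// when requested.
static mat to_batch_layout(const mat& out, int F, int P, int N, bool relu) {
  mat Y(F * P, N);
  for (int n = 0; n < N; n++) {
    const double* src = out.colptr((size_t)n * P); // block F x P, col-major
    double* dst = Y.colptr(n);
    for (int p = 0; p < P; p++)
      for (int f = 0; f < F; f++) {
        double v = src[(size_t)p * F + f];
        if (relu && v < 0) v = 0;
        dst[(size_t)f * P + p] = v;
      }
  }
  return Y;
}

// Inference-path forward: X is (C*H*W) x N, Wt is F x (C*k*k); returns
// (F*oH*oW) x N with output index f*oH*oW + pos.
// [[Rcpp::export]]
arma::mat conv2d_forward_cpp(const arma::mat& X, const arma::mat& Wt,
                             const arma::vec& b,
                             int C, int H, int W, int k, int stride, int pad,
                             bool relu = false) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  const int P = oH * oW;
  const int K = C * k * k;
  const int N = X.n_cols;
  mat cols(K, (size_t)P * N);
  for (int n = 0; n < N; n++)
    im2col_one(X.colptr(n), cols.colptr((size_t)n * P), C, H, W, k, stride, pad, oH, oW);
  mat out = Wt * cols;
  out.each_col() += b;
  return to_batch_layout(out, Wt.n_rows, P, N, relu);
}

// Training-path forward: additionally returns the im2col matrix for reuse
// by the backward pass.
// [[Rcpp::export]]
Rcpp::List conv2d_forward_train_cpp(const arma::mat& X, const arma::mat& Wt,
                                    const arma::vec& b,
                                    int C, int H, int W, int k, int stride,
                                    int pad, bool relu = true) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  const int P = oH * oW;
  const int K = C * k * k;
  const int N = X.n_cols;
  mat cols(K, (size_t)P * N);
  for (int n = 0; n < N; n++)
    im2col_one(X.colptr(n), cols.colptr((size_t)n * P), C, H, W, k, stride, pad, oH, oW);
  mat out = Wt * cols;
  out.each_col() += b;
  return Rcpp::List::create(
    Rcpp::Named("out") = to_batch_layout(out, Wt.n_rows, P, N, relu),
    Rcpp::Named("cols") = cols);
}

// Backward pass. `act` is the post-ReLU forward output (batch layout) and
// dA the gradient w.r.t. it; the ReLU mask is act > 0. `cols` is the
// cached im2col matrix from the forward pass. Returns dX (batch layout),
// dW and db.
// [[Rcpp::export]]
Rcpp::List conv2d_backward_cpp(const arma::mat& cols, const arma::mat& Wt,
                               const arma::mat& act, const arma::mat& dA,
                               int C, int H, int W, int k, int stride,
                               int pad, bool relu = true) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  const int P = oH * oW;
  const int F = Wt.n_rows;
  const int N = dA.n_cols;

  // batch layout -> gemm layout (F x N*P), fusing the ReLU mask
  mat dOut(F, (size_t)P * N);
  for (int n = 0; n < N; n++) {
    const double* da = dA.colptr(n);
    const double* ac = act.colptr(n);
    double* dst = dOut.colptr((size_t)n * P);
    for (int p = 0; p < P; p++)
      for (int f = 0; f < F; f++) {
        double v = da[(size_t)f * P + p];
        if (relu && ac[(size_t)f * P + p] <= 0) v = 0;
        dst[(size_t)p * F + f] = v;
      }
  }

  mat dW = dOut * cols.t();
  vec db = sum(dOut, 1);
  mat dcols = Wt.t() * dOut;
  mat dX(C * H * W, N, fill::zeros);
  for (int n = 0; n < N; n++)
    col2im_one(dcols.colptr((size_t)n * P), dX.colptr(n), C, H, W, k, stride, pad, oH, oW);

  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Fused in-place Adam update; p, m and v are modified directly (the
// training loop detaches its parameter copies first). `corr` is the
// bias-correction factor sqrt(1 - b2^t) / (1 - b1^t).
// [[Rcpp::export]]
void adam_step_cpp(Rcpp::NumericVector p, Rcpp::NumericVector m,
                   Rcpp::NumericVector v, const Rcpp::NumericVector& g,
                   double lr, double b1, double b2, double eps,
                   double corr) {
  const R_xlen_t n = p.size();
  double* pp = p.begin();
  double* pm = m.begin();
  double* pv = v.begin();
  const double* pg = g.begin();
  for (R_xlen_t i = 0; i < n; i++) {
    pm[i] = b1 * pm[i] + (1 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1 - b2) * pg[i] * pg[i];
    pp[i] -= lr * corr * pm[i] / (std::sqrt(pv[i]) + eps);
  }
}

// ---- Float32 fused conv stack -------------------------------------------
//
// The full stride-2 convolution stack is evaluated in single precision in
// one call, holding the im2col matrices and activations in a C++ cache
// (external pointer) between the forward and backward passes. Gradients
// are returned in double precision for the Adam step.

struct ConvStackCache {
  std::vector<fmat> cols;   // per layer im2col
  std::vector<fmat> acts;   // per layer post-ReLU output (batch layout)
  std::vector<int> Hs;      // input spatial side per layer
  std::vector<int> Cs;      // input channels per layer
  int N;
};

static void im2col_one_f(const float* x, float* col,
                         int C, int H, int W, int k, int stride, int pad,
                         int oH, int oW) {
  const int K = C * k * k;
  for (int oy = 0; oy < oH; oy++)
    for (int ox = 0; ox < oW; ox++) {
      float* cp = col + (size_t)(oy * oW + ox) * K;
      int r = 0;
      for (int c = 0; c < C; c++) {
        const float* xc = x + (size_t)c * H * W;
        for (int ky = 0; ky < k; ky++) {
          const int y = oy * stride - pad + ky;
          for (int kx = 0; kx < k; kx++, r++) {
            const int xx = ox * stride - pad + kx;
            cp[r] = (y >= 0 && y < H && xx >= 0 && xx < W)
              ? xc[(size_t)y * W + xx] : 0.0f;
          }
        }
      }
    }
}

static void col2im_one_f(const float* col, float* x,
                         int C, int H, int W, int k, int stride, int pad,
                         int oH, int oW) {
  const int K = C * k * k;
  for (int oy = 0; oy < oH; oy++)
    for (int ox = 0; ox < oW; ox++) {
      const float* cp = col + (size_t)(oy * oW + ox) * K;
      int r = 0;
      for (int c = 0; c < C; c++) {
        float* xc = x + (size_t)c * H * W;
        for (int ky = 0; ky < k; ky++) {
          const int y = oy * stride - pad + ky;
          for (int kx = 0; kx < k; kx++, r++) {
            const int xx = ox * stride - pad + kx;
            if (y >= 0 && y < H && xx >= 0 && xx < W)
              xc[(size_t)y * W + xx] += cp[r];
          }
        }
      }
    }
}

// Forward through all stride-2 conv layers (kernel 3, pad 1, ReLU).
// Returns the final activation in batch layout (double) plus the cache.
// [[Rcpp::export]]
Rcpp::List conv_stack_forward_cpp(const arma::mat& X, Rcpp::List Ws,
                                  Rcpp::List bs, int S) {
  const int L = Ws.size();
  ConvStackCache* cache = new ConvStackCache();
  cache->N = X.n_cols;
  const int N = cache->N;
  fmat A = conv_to<fmat>::from(X);
  int H = S, C = 3;
  for (int l = 0; l < L; l++) {
    fmat Wt = conv_to<fmat>::from(Rcpp::as<arma::mat>(Ws[l]));
    fvec b = conv_to<fvec>::from(Rcpp::as<arma::vec>(bs[l]));
    const int k = 3, stride = 2, pad = 1;
    const int oH = (H + 2 * pad - k) / stride + 1;
    const int P = oH * oH;
    const int K = C * k * k;
    const int F = Wt.n_rows;
    fmat cols(K, (size_t)P * N);
    for (int n = 0; n < N; n++)
      im2col_one_f(A.colptr(n), cols.colptr((size_t)n * P), C, H, H, k, stride, pad, oH, oH);
    fmat out = Wt * cols;
    out.each_col() += b;
    fmat Y(F * P, N);
    for (int n = 0; n < N; n++) {
      const float* src = out.colptr((size_t)n * P);
      float* dst = Y.colptr(n);
      for (int p = 0; p < P; p++)
        for (int f = 0; f < F; f++) {
          float v = src[(size_t)p * F + f];
          dst[(size_t)f * P + p] = v > 0 ? v : 0.0f;
        }
    }
    cache->cols.push_back(std::move(cols));
    cache->Hs.push_back(H);
    cache->Cs.push_back(C);
    cache->acts.push_back(Y);
    A = std::move(Y);
    H = oH;
    C = F;
  }
  Rcpp::XPtr<ConvStackCache> ptr(cache, true);
  return Rcpp::List::create(
    Rcpp::Named("out") = conv_to<mat>::from(cache->acts.back()),
    Rcpp::Named("cache") = ptr);
}

// Backward through the stack; dA is the gradient w.r.t. the final
// activation (batch layout, double). Returns per-layer dW and db. The
// gradient w.r.t. the network input is not needed and not computed.
// [[Rcpp::export]]
Rcpp::List conv_stack_backward_cpp(SEXP cachePtr, Rcpp::List Ws,
                                   const arma::mat& dA_top) {
  Rcpp::XPtr<ConvStackCache> cache(cachePtr);
  const int L = Ws.size();
  const int N = cache->N;
  fmat dA = conv_to<fmat>::from(dA_top);
  Rcpp::List dWs(L), dbs(L);
  for (int l = L - 1; l >= 0; l--) {
    fmat Wt = conv_to<fmat>::from(Rcpp::as<arma::mat>(Ws[l]));
    const int k = 3, stride = 2, pad = 1;
    const int H = cache->Hs[l];
    const int C = cache->Cs[l];
    const int oH = (H + 2 * pad - k) / stride + 1;
    const int P = oH * oH;
    const int F = Wt.n_rows;
    const fmat& act = cache->acts[l];
    fmat dOut(F, (size_t)P * N);
    for (int n = 0; n < N; n++) {
      const float* da = dA.colptr(n);
      const float* ac = act.colptr(n);
      float* dst = dOut.colptr((size_t)n * P);
      for (int p = 0; p < P; p++)
        for (int f = 0; f < F; f++) {
          float v = da[(size_t)f * P + p];
          if (ac[(size_t)f * P + p] <= 0.0f) v = 0.0f;
          dst[(size_t)p * F + f] = v;
        }
    }
    fmat dW = dOut * cache->cols[l].t();
    fvec db = sum(dOut, 1);
    dWs[l] = conv_to<mat>::from(dW);
    dbs[l] = conv_to<vec>::from(db);
    if (l > 0) {
      fmat dcols = Wt.t() * dOut;
      fmat dX(C * H * H, N, fill::zeros);
      for (int n = 0; n < N; n++)
        col2im_one_f(dcols.colptr((size_t)n * P), dX.colptr(n), C, H, H, k, stride, pad, oH, oH);
      dA = std::move(dX);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dWs,
                            Rcpp::Named("db") = dbs);
}
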