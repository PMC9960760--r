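// Minimal convolution / pooling kernels for the dual-encoder segmentation
// network. Layout everywhere: activations are H x W x C x N double arrays
// (R column-major), conv weights are K x K x Cin x Cout, stride 1,
// zero "same" padding of (K-1)/2. im2col + BLAS gemm via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill the (H*W) x (K*K*Cin) patch matrix for one image.
// Row index = i + H*j (pixel, column-major); col index = ki + K*kj + K*K*ci,
// matching the column-major reshape of a K x K x Cin x Cout weight array.
static void im2col(const double* x, int H, int W, int C, int K,
                   arma::mat& M) {
  const int P = (K - 1) / 2;
  M.zeros();
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (std::size_t)ci * H * W;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int col = ki + K * kj + K * K * ci;
        double* Mcol = M.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - P;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, P - ki);
          const int i1 = std::min(H, H + P - ki);
          const double* src = xc + (std::size_t)sj * H + (i0 + ki - P);
          double* dst = Mcol + (std::size_t)j * H + i0;
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
}

// Scatter a (H*W) x (K*K*Cin) gradient matrix back onto the input image.
static void col2im(const arma::mat& M, int H, int W, int C, int K,
                   double* dx) {
  const int P = (K - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (std::size_t)ci * H * W;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int col = ki + K * kj + K * K * ci;
        const double* Mcol = M.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - P;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, P - ki);
          const int i1 = std::min(H, H + P - ki);
          double* dst = xc + (std::size_t)sj * H + (i0 + ki - P);
          const double* src = Mcol + (std::size_t)j * H + i0;
          for (int t = 0; t < i1 - i0; ++t) dst[t] += src[t];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: weight Cin (%d) != input channels (%d)", (int)wd[2], C);

  arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, Cout, false, true);
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat M(H * W, K * K * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, K, M);
    arma::mat Y(y.begin() + (std::size_t)n * H * W * Cout, H * W, Cout,
                false, true);
    Y = M * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];

  arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)K * K * C * Cout);
  dw.attr("dim") = IntegerVector::create(K, K, C, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K * K * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);

  arma::mat M(H * W, K * K * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, K, M);
    arma::mat dY(const_cast<double*>(dy.begin()) + (std::size_t)n * H * W * Cout,
                 H * W, Cout, false, true);
    dWm += M.t() * dY;
    dbv += arma::sum(dY, 0).t();
    arma::mat dM = dY * Wm.t();
    col2im(dM, H, W, C, K, dx.begin() + (std::size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based linear
// indices of the argmax into the input array (for the R-side backward).
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx((R_xlen_t)Ho * Wo * C * N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = x.begin();
  double* py = y.begin();
  double* pi = idx.begin();
  std::size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t base = ((std::size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          std::size_t k0 = base + (std::size_t)(2 * j) * H + 2 * i;
          std::size_t best = k0;
          double v = px[k0];
          const std::size_t cand[3] = {k0 + 1, k0 + H, k0 + H + 1};
          for (int t = 0; t < 3; ++t)
            if (px[cand[t]] > v) { v = px[cand[t]]; best = cand[t]; }
          py[o] = v;
          pi[o] = (double)(best + 1);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}
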