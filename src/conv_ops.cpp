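#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Convolution layers are computed by the shift-and-add decomposition: for a
// kernel offset (a, b) the whole image is shifted once (zero padding outside
// the frame) and a single F x C weight slab multiplies the shifted pixel
// matrix.  This turns an H x W "same" convolution into kh*kw BLAS gemm calls
// and avoids the memory blow-up of im2col for large kernels.
//
// Layouts (R column-major):
//   activations: dim c(H, W, C, N)  -- each channel image contiguous
//   weights:     dim c(F, C, kh, kw) -- F x C slab contiguous per (a, b)
// Cross-correlation convention: out(i,j,f) = b_f +
//   sum_{c,a,b} w(f,c,a,b) * x(i + a - ph, j + b - pw)

static void shift_image(const arma::mat& X, arma::mat& S,
                        int H, int W, int C, int a, int b) {
  S.zeros();
  int i0 = std::max(0, -a), i1 = std::min(H, H - a);
  int j0 = std::max(0, -b), j1 = std::min(W, W - b);
  if (i0 >= i1 || j0 >= j1) return;
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* sc = S.colptr(c);
    for (int j = j0; j < j1; ++j) {
      std::memcpy(sc + (size_t)j * H + i0,
                  xc + (size_t)(j + b) * H + (i0 + a),
                  sizeof(double) * (size_t)(i1 - i0));
    }
  }
}

// adjoint of shift_image: Xg(i+a, j+b) += Sg(i, j)
static void shift_add(const arma::mat& Sg, arma::mat& Xg,
                      int H, int W, int C, int a, int b) {
  int i0 = std::max(0, -a), i1 = std::min(H, H - a);
  int j0 = std::max(0, -b), j1 = std::min(W, W - b);
  if (i0 >= i1 || j0 >= j1) return;
  for (int c = 0; c < C; ++c) {
    const double* sg = Sg.colptr(c);
    double* xg = Xg.colptr(c);
    for (int j = j0; j < j1; ++j) {
      const double* src = sg + (size_t)j * H + i0;
      double* dst = xg + (size_t)(j + b) * H + (i0 + a);
      for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (xd.size() != 4 || wd.size() != 4)
    stop("x must be (H,W,C,N) and w must be (F,C,kh,kw)");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int F = wd[0], Cw = wd[1], kh = wd[2], kw = wd[3];
  if (Cw != C) stop("channel mismatch between x and w");
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernel sizes must be odd");
  if (b.size() != F) stop("bias length must equal number of filters");
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  size_t HW = (size_t)H * W;
  NumericVector out((size_t)H * W * F * N);
  out.attr("dim") = IntegerVector::create(H, W, F, N);
  arma::mat S(HW, C);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(&x[0]) + (size_t)n * HW * C,
                HW, C, false);
    arma::mat O(&out[0] + (size_t)n * HW * F, HW, F, false, true);
    for (int f = 0; f < F; ++f) O.col(f).fill(b[f]);
    for (int bj = 0; bj < kw; ++bj) {
      for (int ai = 0; ai < kh; ++ai) {
        shift_image(X, S, H, W, C, ai - ph, bj - pw);
        arma::mat Wab(const_cast<double*>(&w[0]) +
                        ((size_t)ai + (size_t)bj * kh) * F * C,
                      F, C, false);
        O += S * Wab.t();
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w,
                         NumericVector dout) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int F = wd[0], kh = wd[2], kw = wd[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  size_t HW = (size_t)H * W;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((size_t)F * C * kh * kw);
  dw.attr("dim") = IntegerVector::create(F, C, kh, kw);
  NumericVector db(F);
  arma::mat S(HW, C), G(HW, C);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(&x[0]) + (size_t)n * HW * C,
                HW, C, false);
    arma::mat D(const_cast<double*>(&dout[0]) + (size_t)n * HW * F,
                HW, F, false);
    arma::mat DX(&dx[0] + (size_t)n * HW * C, HW, C, false, true);
    for (int f = 0; f < F; ++f) db[f] += arma::accu(D.col(f));
    for (int bj = 0; bj < kw; ++bj) {
      for (int ai = 0; ai < kh; ++ai) {
        int a = ai - ph, bb = bj - pw;
        arma::mat Wab(const_cast<double*>(&w[0]) +
                        ((size_t)ai + (size_t)bj * kh) * F * C,
                      F, C, false);
        arma::mat DW(&dw[0] + ((size_t)ai + (size_t)bj * kh) * F * C,
                     F, C, false, true);
        shift_image(X, S, H, W, C, a, bb);
        DW += D.t() * S;
        G = D * Wab;  // HW x C gradient wrt shifted image
        shift_add(G, DX, H, W, C, a, bb);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int p) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % p != 0 || W % p != 0) stop("pool size must divide both dimensions");
  int Ho = H / p, Wo = W / p;
  size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  NumericVector out(HWo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(HWo * C * N);  // 0-based linear index into sample slice
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xs = &x[0] + (size_t)n * HW * C;
    double* os = &out[0] + (size_t)n * HWo * C;
    int* is = &idx[0] + (size_t)n * HWo * C;
    for (int c = 0; c < C; ++c) {
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dj = 0; dj < p; ++dj) {
            for (int di = 0; di < p; ++di) {
              size_t lin = (size_t)c * HW + (size_t)(jo * p + dj) * H +
                           (io * p + di);
              double v = xs[lin];
              if (v > best) { best = v; bidx = lin; }
            }
          }
          size_t olin = (size_t)c * HWo + (size_t)jo * Ho + io;
          os[olin] = best;
          is[olin] = (int)bidx;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(IntegerVector idx, NumericVector dout,
                                   int H, int W) {
  IntegerVector od = dout.attr("dim");
  int Ho = od[0], Wo = od[1], C = od[2], N = od[3];
  size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  NumericVector dx(HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    const double* ds = &dout[0] + (size_t)n * HWo * C;
    const int* is = &idx[0] + (size_t)n * HWo * C;
    double* xs = &dx[0] + (size_t)n * HW * C;
    for (size_t k = 0; k < HWo * C; ++k) xs[is[k]] += ds[k];
  }
  return dx;
}
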