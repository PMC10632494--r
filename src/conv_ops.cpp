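// Stride-1 same-padding convolution and 2x2 max-pooling kernels for the
// small-CNN engine. Layout follows R column-major arrays (H, W, C, N);
// conv kernels are stored as matrices of shape (Cout, k*k*Cin) with row
// index r = ki + k*(kj + k*c).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_same(const double* x, int H, int W, int C, int k,
                        arma::mat& cols) {
  const int pad = (k - 1) / 2;
  // cols: (k*k*C) x (H*W)
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * (kj + k * c);
        double* col = cols.memptr() + r;  // stride = cols.n_rows
        const int nr = cols.n_rows;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) col[(size_t)(i + H * j) * nr] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - pad;
            col[(size_t)(i + H * j) * nr] =
                (si < 0 || si >= H) ? 0.0 : xcol[si];
          }
        }
      }
    }
  }
}

static void col2im_same(const arma::mat& cols, int H, int W, int C, int k,
                        double* dx) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * (kj + k * c);
        const double* col = cols.memptr() + r;
        const int nr = cols.n_rows;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          double* xcol = xc + (size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - pad;
            if (si >= 0 && si < H)
              xcol[si] += col[(size_t)(i + H * j) * nr];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, const arma::mat& Wmat,
                             const arma::vec& bias, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = Wmat.n_rows;
  if ((int)Wmat.n_cols != k * k * C)
    stop("kernel matrix has %d columns; expected k*k*C = %d",
         (int)Wmat.n_cols, k * k * C);
  NumericVector out(
      (R_xlen_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat cols(k * k * C, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    arma::mat o = Wmat * cols;             // (Cout x H*W)
    o.each_col() += bias;
    // transpose scatter: out(i,j,co,n) = o(co, i + H*j)
    double* op = out.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* orow = o.memptr() + co;
      double* oc = op + (size_t)co * H * W;
      for (size_t px = 0; px < (size_t)H * W; ++px)
        oc[px] = orow[px * Cout];
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward(NumericVector x, const arma::mat& Wmat, NumericVector dy,
                     int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = Wmat.n_rows;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = d;
  arma::mat dW(Cout, k * k * C, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(k * k * C, (size_t)H * W);
  arma::mat dym(Cout, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    const double* dyp = dy.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* dc = dyp + (size_t)co * H * W;
      double* drow = dym.memptr() + co;
      for (size_t px = 0; px < (size_t)H * W; ++px)
        drow[px * Cout] = dc[px];
    }
    dW += dym * cols.t();
    db += arma::sum(dym, 1);
    arma::mat dcols = Wmat.t() * dym;
    col2im_same(dcols, H, W, C, k, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);  // 0-based index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      const size_t obase = ((size_t)n * C + c) * Ho * Wo;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = -HUGE_VAL;
          size_t bestix = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const size_t ix =
                  base + (size_t)(2 * jo + dj) * H + (2 * io + di);
              if (xp[ix] > best) { best = xp[ix]; bestix = ix; }
            }
          }
          yp[obase + (size_t)jo * Ho + io] = best;
          ip[obase + (size_t)jo * Ho + io] = (int)bestix;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx,
                                IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  const R_xlen_t m = dy.size();
  for (R_xlen_t t = 0; t < m; ++t) dxp[ip[t]] += dyp[t];
  return dx;
}
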