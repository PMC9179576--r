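// Minimal conv-net primitives for the small CNN backbone.
// Layout convention: image batches are R arrays with dim (H, W, C, N),
// column-major. Conv weights are (9*C_in) x C_out matrices whose rows are
// ordered c-major, then kernel column offset dj, then kernel row offset di
// (all 3x3, stride 1, zero padding 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  SEXP dim = x.attr("dim");
  if (Rf_isNull(dim)) stop("expected a 4-d array (H, W, C, N)");
  IntegerVector d(dim);
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// col(p, q) = x(i + di - 1, j + dj - 1, c) with p = i + j*H and
// q = c*9 + dj*3 + di; out-of-range taps stay 0 (caller zeroes col).
static void im2col3(const arma::cube& xc, arma::mat& col) {
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int q = c * 9 + dj * 3 + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - 1;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, 1 - di);
          const int i1 = std::min(H, H + 1 - di);
          for (int i = i0; i < i1; ++i) {
            col(i + j * H, q) = xc(i + di - 1, sj, c);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3x3_forward(NumericVector x, const arma::mat& weight,
                              const arma::vec& bias) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int F = weight.n_cols;
  if ((int)weight.n_rows != 9 * C)
    stop("weight must have 9 * n_channels rows");
  if ((int)bias.n_elem != F) stop("bias length must match weight columns");

  NumericVector y((R_xlen_t)H * W * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  arma::mat col(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    arma::cube xc(x.begin() + (R_xlen_t)n * H * W * C, H, W, C, false, true);
    col.zeros();
    im2col3(xc, col);
    arma::mat ym = col * weight;  // (H*W) x F
    ym.each_row() += bias.t();
    std::copy(ym.begin(), ym.end(), y.begin() + (R_xlen_t)n * H * W * F);
  }
  return y;
}

// [[Rcpp::export]]
List conv3x3_backward(NumericVector x, const arma::mat& weight,
                      NumericVector gy) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int F = weight.n_cols;
  if ((int)weight.n_rows != 9 * C)
    stop("weight must have 9 * n_channels rows");

  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat gW(9 * C, F, arma::fill::zeros);
  arma::vec gb(F, arma::fill::zeros);
  arma::mat col(H * W, 9 * C);

  for (int n = 0; n < N; ++n) {
    arma::cube xc(x.begin() + (R_xlen_t)n * H * W * C, H, W, C, false, true);
    col.zeros();
    im2col3(xc, col);
    arma::mat gym(gy.begin() + (R_xlen_t)n * H * W * F, H * W, F, false, true);
    gW += col.t() * gym;
    gb += arma::sum(gym, 0).t();
    arma::mat gcol = gym * weight.t();  // (H*W) x (9*C), scatter back
    arma::cube gxc(gx.begin() + (R_xlen_t)n * H * W * C, H, W, C, false, true);
    for (int c = 0; c < C; ++c) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int q = c * 9 + dj * 3 + di;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - 1;
            if (sj < 0 || sj >= W) continue;
            const int i0 = std::max(0, 1 - di);
            const int i1 = std::min(H, H + 1 - di);
            for (int i = i0; i < i1; ++i) {
              gxc(i + di - 1, sj, c) += gcol(i + j * H, q);
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values plus the 0-based linear
// index (into x) of each block argmax, for the backward pass.
// [[Rcpp::export]]
List maxpool2_forward(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 != 0 || W % 2 != 0) stop("maxpool2 requires even height and width");
  const int Ho = H / 2, Wo = W / 2;

  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);

  R_xlen_t k = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base_cn = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = R_NegInf;
          R_xlen_t best_idx = -1;
          for (int b = 0; b < 2; ++b) {
            for (int a = 0; a < 2; ++a) {
              const R_xlen_t idx =
                  base_cn + (2 * io + a) + (R_xlen_t)H * (2 * jo + b);
              const double v = x[idx];
              if (v > best) { best = v; best_idx = idx; }
            }
          }
          y[k] = best;
          arg[k] = (int)best_idx;
          ++k;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward(IntegerVector argmax, NumericVector gy,
                                IntegerVector xdim) {
  if (xdim.size() != 4) stop("xdim must have length 4");
  R_xlen_t total = 1;
  for (int d = 0; d < 4; ++d) total *= xdim[d];
  NumericVector gx(total);
  gx.attr("dim") = xdim;
  const R_xlen_t K = gy.size();
  if (argmax.size() != K) stop("argmax and gy must have equal length");
  for (R_xlen_t k = 0; k < K; ++k) gx[argmax[k]] += gy[k];
  return gx;
}
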