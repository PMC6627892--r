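// Minimal convolution / pooling kernels for the fixture CNN.
//
// Convolutions are "same"-padded, stride 1, square kernels, realized as
// im2col + BLAS matrix products. Layout conventions (column-major, 0-based):
//   activations: arma::cube (H, W, C)
//   weights:     arma::mat (k*k*Cin) x Cout, row index dx + k*dy + k*k*c
//                (matches R's column-major flattening of a k x k x Cin x Cout
//                array)
//   im2col:      (H*W) x (k*k*Cin), row index i + H*j for output pixel (i, j)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  arma::mat out(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int col = c * k * k + dy * k + dx;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dy - p;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + dx - p;
            if (ii < 0 || ii >= H) continue;
            out(i + H * j, col) = sl(ii, jj);
          }
        }
      }
    }
  }
  return out;
}

static arma::cube col2im3(const arma::mat& cols, int H, int W, int C, int k) {
  const int p = k / 2;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& sl = out.slice(c);
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int col = c * k * k + dy * k + dx;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dy - p;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + dx - p;
            if (ii < 0 || ii >= H) continue;
            sl(ii, jj) += cols(i + H * j, col);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat y = im2col3(x, k) * w;
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.col(c), H, W);
  return out;
}

// [[Rcpp::export]]
List conv2d_backward(const arma::cube& x, const arma::mat& w,
                     const arma::cube& gy, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat gymat(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    gymat.col(c) = arma::vectorise(gy.slice(c));
  arma::mat xcol = im2col3(x, k);
  arma::mat gw = xcol.t() * gymat;
  arma::vec gb = arma::sum(gymat, 0).t();
  arma::cube gx = col2im3(gymat * w.t(), H, W, C, k);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  arma::cube y(H2, W2, C);
  arma::umat idx(H2 * W2, C);  // absolute within-slice linear index of argmax
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        int bi = 2 * i, bj = 2 * j;
        double best = sl(bi, bj);
        int besti = bi, bestj = bj;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = sl(bi + di, bj + dj);
            if (v > best) { best = v; besti = bi + di; bestj = bj + dj; }
          }
        y(i, j, c) = best;
        idx(i + H2 * j, c) = besti + H * bestj;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::umat& idx, const arma::cube& gy,
                             int H, int W) {
  const int C = gy.n_slices;
  const int H2 = gy.n_rows, W2 = gy.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& sl = gx.slice(c);
    const arma::mat& g = gy.slice(c);
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i)
        sl(idx(i + H2 * j, c)) += g(i, j);
  }
  return gx;
}
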