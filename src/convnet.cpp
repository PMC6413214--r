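// Minimal CNN primitives for the hourglass network: 3x3 same-padding
// convolution via im2col + GEMM, 2x2 max pooling with argmax indices, and
// index-driven max unpooling. Tensors are arma::cube [H, W, C].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a 3x3 window with zero padding: (9*Cin) x (H*W)
static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(9 * C, H * W, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& sl = x.slice(c);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        uword row = c * 9 + (ky + 1) * 3 + (kx + 1);
        // destination pixel (i, j) reads source (i + ky, j + kx)
        uword i0 = ky < 0 ? 1 : 0, i1 = ky > 0 ? H - 1 : H;
        uword j0 = kx < 0 ? 1 : 0, j1 = kx > 0 ? W - 1 : W;
        for (uword j = j0; j < j1; ++j) {
          const double* src = sl.colptr(j + kx) + (i0 + ky);
          double* dst = out.colptr(j * H + i0) + row;
          for (uword i = i0; i < i1; ++i) {
            *dst = *src++;
            dst += 9 * C;
          }
        }
      }
    }
  }
  return out;
}

// scatter-add of a (9*Cin) x (H*W) column matrix back to an H x W x Cin cube
static cube col2im3(const mat& cols, uword H, uword W, uword C) {
  cube out(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& sl = out.slice(c);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        uword row = c * 9 + (ky + 1) * 3 + (kx + 1);
        uword i0 = ky < 0 ? 1 : 0, i1 = ky > 0 ? H - 1 : H;
        uword j0 = kx < 0 ? 1 : 0, j1 = kx > 0 ? W - 1 : W;
        for (uword j = j0; j < j1; ++j) {
          double* dst = sl.colptr(j + kx) + (i0 + ky);
          const double* src = cols.colptr(j * H + i0) + row;
          for (uword i = i0; i < i1; ++i) {
            *dst++ += *src;
            src += 9 * C;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube conv3x3_forward(const arma::cube& x, const arma::mat& wmat,
                           const arma::vec& bias) {
  const uword H = x.n_rows, W = x.n_cols;
  const uword Cout = wmat.n_cols;
  mat cols = im2col3(x);           // (9*Cin) x (H*W)
  mat y = wmat.t() * cols;         // Cout x (H*W)
  y.each_col() += bias;
  cube out(H, W, Cout);
  for (uword c = 0; c < Cout; ++c) {
    out.slice(c) = reshape(y.row(c), H, W);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv3x3_backward(const arma::cube& x, const arma::mat& wmat,
                            const arma::cube& gy) {
  const uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const uword Cout = gy.n_slices;
  mat g(Cout, H * W);
  for (uword c = 0; c < Cout; ++c) {
    g.row(c) = vectorise(gy.slice(c)).t();
  }
  mat cols = im2col3(x);
  mat gw = cols * g.t();           // (9*Cin) x Cout
  vec gb = sum(g, 1);
  mat gcols = wmat * g;            // (9*Cin) x (H*W)
  cube gx = col2im3(gcols, H, W, Cin);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List maxpool2(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword h = H / 2, w = W / 2;
  cube y(h, w, C);
  ucube idx(h, w, C); // linear index (row + col*H) of the max within a slice
  for (uword c = 0; c < C; ++c) {
    const mat& sl = x.slice(c);
    for (uword j = 0; j < w; ++j) {
      for (uword i = 0; i < h; ++i) {
        uword bi = 2 * i, bj = 2 * j;
        double best = sl(bi, bj);
        uword bidx = bi + bj * H;
        if (sl(bi + 1, bj) > best) { best = sl(bi + 1, bj); bidx = bi + 1 + bj * H; }
        if (sl(bi, bj + 1) > best) { best = sl(bi, bj + 1); bidx = bi + (bj + 1) * H; }
        if (sl(bi + 1, bj + 1) > best) { best = sl(bi + 1, bj + 1); bidx = bi + 1 + (bj + 1) * H; }
        y(i, j, c) = best;
        idx(i, j, c) = bidx;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::ucube& idx, const arma::cube& gy,
                             int H, int W) {
  const uword C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& sl = gx.slice(c);
    const mat& g = gy.slice(c);
    const umat& id = idx.slice(c);
    for (uword j = 0; j < g.n_cols; ++j) {
      for (uword i = 0; i < g.n_rows; ++i) {
        sl(id(i, j)) += g(i, j);
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube maxunpool2(const arma::cube& x, const arma::ucube& idx,
                      int H, int W) {
  const uword C = x.n_slices;
  cube out(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& sl = out.slice(c);
    const mat& v = x.slice(c);
    const umat& id = idx.slice(c);
    for (uword j = 0; j < v.n_cols; ++j) {
      for (uword i = 0; i < v.n_rows; ++i) {
        sl(id(i, j)) = v(i, j);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube maxunpool2_backward(const arma::cube& gy, const arma::ucube& idx) {
  const uword h = idx.n_rows, w = idx.n_cols, C = idx.n_slices;
  cube gx(h, w, C);
  for (uword c = 0; c < C; ++c) {
    mat& sl = gx.slice(c);
    const mat& g = gy.slice(c);
    const umat& id = idx.slice(c);
    for (uword j = 0; j < w; ++j) {
      for (uword i = 0; i < h; ++i) {
        sl(i, j) = g(id(i, j));
      }
    }
  }
  return gx;
}
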