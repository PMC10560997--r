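// Minimal convolutional primitives: im2col + GEMM forward, explicit backward.
// Tensors are R arrays H x W x C (column-major), mapped onto arma::cube
// (n_rows = H, n_cols = W, n_slices = C). Convolutions are 'same' (stride 1,
// zero padding (k-1)/2); pooling is 2x2 max with stride 2.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  arma::mat out(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int col = c * k * k + dw * k + dh;
        double* o = out.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw - p;
          if (sw < 0 || sw >= W) {
            for (int h = 0; h < H; ++h) o[w * H + h] = 0.0;
            continue;
          }
          const double* s = sl.colptr(sw);
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh - p;
            o[w * H + h] = (sh < 0 || sh >= H) ? 0.0 : s[sh];
          }
        }
      }
    }
  }
  return out;
}

// scatter-add of a (H*W) x (k*k*C) patch-gradient matrix back to an image
static arma::cube col2im(const arma::mat& g, const int H, const int W,
                         const int C, const int k) {
  const int p = (k - 1) / 2;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& sl = out.slice(c);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int col = c * k * k + dw * k + dh;
        const double* gc = g.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw - p;
          if (sw < 0 || sw >= W) continue;
          double* s = sl.colptr(sw);
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh - p;
            if (sh >= 0 && sh < H) s[sh] += gc[w * H + h];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, const int k) {
  const int H = x.n_rows, Wd = x.n_cols, Cout = W.n_cols;
  arma::mat y = im2col(x, k) * W;
  y.each_row() += b.t();
  arma::cube out(y.memptr(), H, Wd, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube& x, const arma::mat& W, const arma::cube& gy,
                   const int k) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices, Cout = W.n_cols;
  const arma::mat P = im2col(x, k);
  const arma::mat G(const_cast<double*>(gy.memptr()), H * Wd, Cout, false, true);
  arma::mat gW = P.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::cube gx = col2im(G * W.t(), H, Wd, C, k);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C); // linear index within slice of the argmax
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double best = sl(2 * h, 2 * w);
        unsigned bi = 2 * h + (2 * w) * H;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const double v = sl(2 * h + dh, 2 * w + dw);
            if (v > best) { best = v; bi = (2 * h + dh) + (2 * w + dw) * H; }
          }
        y(h, w, c) = best;
        idx(h, w, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::ucube& idx, const arma::cube& gy,
                          const int H, const int W) {
  const int C = gy.n_slices, Ho = gy.n_rows, Wo = gy.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* s = gx.slice(c).memptr();
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        s[idx(h, w, c)] += gy(h, w, c);
  }
  return gx;
}
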