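// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 2-D convolution layers for the desk-scale CNN backbone, im2col formulation.
// Feature tensors are arma::cube with dimensions (H, W, C).

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Unfold X (H x W x C) into a (C*kh*kw) x (outH*outW) patch matrix.
static arma::mat im2col(const arma::cube& X, int kh, int kw, int stride,
                        int pad) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int oH = out_dim(H, kh, stride, pad);
  const int oW = out_dim(W, kw, stride, pad);
  arma::mat cols(C * kh * kw, oH * oW, arma::fill::zeros);
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const int col = ow * oH + oh;
      const int h0 = oh * stride - pad;
      const int w0 = ow * stride - pad;
      int row = 0;
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i, ++row) {
            const int hh = h0 + i, ww = w0 + j;
            if (hh >= 0 && hh < H && ww >= 0 && ww < W)
              cols(row, col) = X(hh, ww, c);
          }
    }
  }
  return cols;
}

// Fold a patch-gradient matrix back onto the input tensor (adjoint of im2col).
static arma::cube col2im(const arma::mat& cols, int H, int W, int C, int kh,
                         int kw, int stride, int pad) {
  const int oH = out_dim(H, kh, stride, pad);
  const int oW = out_dim(W, kw, stride, pad);
  arma::cube dX(H, W, C, arma::fill::zeros);
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const int col = ow * oH + oh;
      const int h0 = oh * stride - pad;
      const int w0 = ow * stride - pad;
      int row = 0;
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i, ++row) {
            const int hh = h0 + i, ww = w0 + j;
            if (hh >= 0 && hh < H && ww >= 0 && ww < W)
              dX(hh, ww, c) += cols(row, col);
          }
    }
  }
  return dX;
}

// Forward pass: Y(:,:,o) = sum_c W_o * X_c + b_o, ReLU applied by the caller.
// Wmat is (outC) x (C*kh*kw). Returns the output tensor and the patch matrix
// needed by the backward pass.
// [[Rcpp::export]]
List conv2d_forward_cpp(const arma::cube& X, const arma::mat& Wmat,
                        const arma::vec& b, int kh, int kw, int stride,
                        int pad) {
  const int H = X.n_rows, W = X.n_cols;
  const int oH = out_dim(H, kh, stride, pad);
  const int oW = out_dim(W, kw, stride, pad);
  const int oC = Wmat.n_rows;
  arma::mat cols = im2col(X, kh, kw, stride, pad);
  arma::mat Ymat = Wmat * cols;          // oC x (oH*oW)
  Ymat.each_col() += b;
  arma::cube Y(oH, oW, oC);
  for (int o = 0; o < oC; ++o)
    Y.slice(o) = arma::reshape(Ymat.row(o), oH, oW);
  return List::create(_["out"] = Y, _["cols"] = cols);
}

// Backward pass given dL/dY; returns dL/dX, dL/dW, dL/db.
// [[Rcpp::export]]
List conv2d_backward_cpp(const arma::cube& dY, const arma::mat& cols,
                         const arma::mat& Wmat, int H, int W, int C, int kh,
                         int kw, int stride, int pad) {
  const int oH = dY.n_rows, oW = dY.n_cols, oC = dY.n_slices;
  arma::mat dYmat(oC, oH * oW);
  for (int o = 0; o < oC; ++o)
    dYmat.row(o) = arma::vectorise(dY.slice(o)).t();
  arma::mat dW = dYmat * cols.t();
  arma::vec db = arma::sum(dYmat, 1);
  arma::mat dcols = Wmat.t() * dYmat;
  arma::cube dX = col2im(dcols, H, W, C, kh, kw, stride, pad);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
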