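// 1-D convolution kernels for the multi-scale residual network.
// Layout convention: activation tensors are cubes (channels, time, batch);
// a branch weight is a dense matrix (out_channels_branch, in_channels * K)
// so that forward is a single GEMM against the im2col matrix per record.
// Kernels are odd-length and padded "same": pad = (K - 1) / 2 on both sides,
// giving T_out = T for stride 1 and ceil(T / 2) for stride 2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_len(int T, int K, int stride) {
  int pad = (K - 1) / 2;
  return (T + 2 * pad - K) / stride + 1;
}

// im2col for one record: x_slice (C_in, T) -> (C_in * K, T_out)
static void im2col(const mat& xs, int K, int stride, mat& col) {
  const int C = xs.n_rows, T = xs.n_cols;
  const int pad = (K - 1) / 2;
  const int To = out_len(T, K, stride);
  col.zeros(C * K, To);
  for (int t = 0; t < To; ++t) {
    int start = t * stride - pad;
    for (int k = 0; k < K; ++k) {
      int src = start + k;
      if (src >= 0 && src < T)
        col.submat(k * C, t, (k + 1) * C - 1, t) = xs.col(src);
    }
  }
}

// col2im accumulation: grad on the im2col matrix -> grad on the input slice
static void col2im_add(const mat& gcol, int K, int stride, mat& gx) {
  const int C = gx.n_rows, T = gx.n_cols;
  const int pad = (K - 1) / 2;
  const int To = gcol.n_cols;
  for (int t = 0; t < To; ++t) {
    int start = t * stride - pad;
    for (int k = 0; k < K; ++k) {
      int src = start + k;
      if (src >= 0 && src < T)
        gx.col(src) += gcol.submat(k * C, t, (k + 1) * C - 1, t);
    }
  }
}

// Multi-scale convolution forward: four parallel branches with kernel
// lengths `kernels`, outputs concatenated channel-wise.
// weights[i]: (C_out_i, C_in * K_i). Returns cube (sum C_out_i, T_out, B).
// [[Rcpp::export]]
arma::cube msconv_forward(const arma::cube& x, const Rcpp::List& weights,
                          const arma::ivec& kernels, int stride) {
  const int T = x.n_cols, B = x.n_slices;
  const int nb = kernels.n_elem;
  std::vector<mat> W(nb);
  int Cout = 0;
  for (int i = 0; i < nb; ++i) {
    W[i] = Rcpp::as<mat>(weights[i]);
    Cout += W[i].n_rows;
  }
  const int To = out_len(T, kernels[0], stride);
  cube y(Cout, To, B);
  mat col;
  for (int b = 0; b < B; ++b) {
    int row0 = 0;
    for (int i = 0; i < nb; ++i) {
      im2col(x.slice(b), kernels[i], stride, col);
      y.slice(b).rows(row0, row0 + W[i].n_rows - 1) = W[i] * col;
      row0 += W[i].n_rows;
    }
  }
  return y;
}

// Backward pass: returns gradients w.r.t. the input cube and each branch
// weight, given the gradient on the concatenated output.
// [[Rcpp::export]]
Rcpp::List msconv_backward(const arma::cube& x, const Rcpp::List& weights,
                           const arma::ivec& kernels, int stride,
                           const arma::cube& gout) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int nb = kernels.n_elem;
  std::vector<mat> W(nb), gW(nb);
  for (int i = 0; i < nb; ++i) {
    W[i] = Rcpp::as<mat>(weights[i]);
    gW[i].zeros(W[i].n_rows, W[i].n_cols);
  }
  cube gx(C, T, B, fill::zeros);
  mat col, gcol, gxs(C, T);
  for (int b = 0; b < B; ++b) {
    int row0 = 0;
    gxs.zeros();
    for (int i = 0; i < nb; ++i) {
      im2col(x.slice(b), kernels[i], stride, col);
      mat g = gout.slice(b).rows(row0, row0 + W[i].n_rows - 1);
      gW[i] += g * col.t();
      gcol = W[i].t() * g;
      col2im_add(gcol, kernels[i], stride, gxs);
      row0 += W[i].n_rows;
    }
    gx.slice(b) = gxs;
  }
  Rcpp::List out(nb);
  for (int i = 0; i < nb; ++i) out[i] = gW[i];
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = out);
}
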