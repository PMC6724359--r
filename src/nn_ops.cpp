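// 1-D convolution and pooling kernels for the network engine.
// Tensors are arma::cube with dimensions (length, channels, batch).
// Convolutions use "same" padding: L_out = ceil(L / stride).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static uvec gather_rows(int Lout, int stride, int j) {
  uvec rows(Lout);
  for (int t = 0; t < Lout; ++t) rows[t] = t * stride + j;
  return rows;
}

static mat im2col1d(const mat& X, int k, int stride, int Lout, int pad_left) {
  // X: (L, Cin) -> (Lout, k*Cin), column block j holds input offset j
  const int L = X.n_rows, Cin = X.n_cols;
  const int Lp = (Lout - 1) * stride + k;
  mat P(Lp, Cin, fill::zeros);
  P.rows(pad_left, pad_left + L - 1) = X;
  mat cols(Lout, k * Cin);
  for (int j = 0; j < k; ++j)
    cols.cols(j * Cin, (j + 1) * Cin - 1) = P.rows(gather_rows(Lout, stride, j));
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int stride) {
  const int L = x.n_rows, N = x.n_slices;
  const int Cout = W.n_cols;
  const int Cin = x.n_cols;
  const int k = W.n_rows / Cin;
  const int Lout = (L + stride - 1) / stride;
  const int total_pad = std::max(0, (Lout - 1) * stride + k - L);
  const int pad_left = total_pad / 2;
  cube out(Lout, Cout, N);
  for (int n = 0; n < N; ++n) {
    mat cols = im2col1d(x.slice(n), k, stride, Lout, pad_left);
    mat y = cols * W;
    y.each_row() += b.t();
    out.slice(n) = y;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& dy, int stride) {
  const int L = x.n_rows, N = x.n_slices;
  const int Cin = x.n_cols;
  const int k = W.n_rows / Cin;
  const int Lout = dy.n_rows;
  const int total_pad = std::max(0, (Lout - 1) * stride + k - L);
  const int pad_left = total_pad / 2;
  cube dx(L, Cin, N, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_cols, fill::zeros);
  const int Lp = (Lout - 1) * stride + k;
  for (int n = 0; n < N; ++n) {
    mat cols = im2col1d(x.slice(n), k, stride, Lout, pad_left);
    const mat& dyn = dy.slice(n);
    dW += cols.t() * dyn;
    db += sum(dyn, 0).t();
    mat dcols = dyn * W.t();  // (Lout, k*Cin)
    mat dP(Lp, Cin, fill::zeros);
    for (int j = 0; j < k; ++j)
      dP.rows(gather_rows(Lout, stride, j)) +=
        dcols.cols(j * Cin, (j + 1) * Cin - 1);
    dx.slice(n) = dP.rows(pad_left, pad_left + L - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// max pooling, width 2 stride 2 (L must be even)
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int Lo = L / 2;
  cube out(Lo, C, N);
  ucube arg(Lo, C, N);  // 0 or 1: offset of the winner
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < Lo; ++t) {
        double a = x(2 * t, c, n), b = x(2 * t + 1, c, n);
        if (a >= b) { out(t, c, n) = a; arg(t, c, n) = 0; }
        else        { out(t, c, n) = b; arg(t, c, n) = 1; }
      }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("arg") = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::ucube& arg, const arma::cube& dy) {
  const int Lo = dy.n_rows, C = dy.n_cols, N = dy.n_slices;
  cube dx(2 * Lo, C, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < Lo; ++t)
        dx(2 * t + arg(t, c, n), c, n) = dy(t, c, n);
  return dx;
}

// batch normalization over (length, batch) per channel
// [[Rcpp::export]]
Rcpp::List cpp_bn_fwd(const arma::cube& x, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& mu,
                      const arma::vec& var_, double eps) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  cube y(L, C, N);
  vec inv = 1.0 / sqrt(var_ + eps);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      y.slice(n).col(c) = (x.slice(n).col(c) - mu[c]) * (inv[c] * gamma[c])
                          + beta[c];
  return Rcpp::List::create(Rcpp::Named("out") = y,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_stats(const arma::cube& x) {
  const int C = x.n_cols, N = x.n_slices;
  vec mu(C, fill::zeros), m2(C, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      mu[c] += accu(x.slice(n).col(c));
      m2[c] += dot(x.slice(n).col(c), x.slice(n).col(c));
    }
  const double m = double(x.n_rows) * N;
  mu /= m;
  vec var_ = m2 / m - mu % mu;
  return Rcpp::List::create(Rcpp::Named("mu") = mu,
                            Rcpp::Named("var") = var_);
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_bwd(const arma::cube& x, const arma::vec& mu,
                      const arma::vec& inv, const arma::vec& gamma,
                      const arma::cube& dy) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const double m = double(L) * N;
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  vec s_dxhat(C, fill::zeros), s_dxhat_xhat(C, fill::zeros);
  // first pass: reductions
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      vec xhat = (x.slice(n).col(c) - mu[c]) * inv[c];
      const vec& d = dy.slice(n).col(c);
      dbeta[c] += accu(d);
      dgamma[c] += dot(d, xhat);
    }
  s_dxhat = gamma % dbeta;          // sum of dxhat
  s_dxhat_xhat = gamma % dgamma;    // sum of dxhat * xhat
  cube dx(L, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      vec xhat = (x.slice(n).col(c) - mu[c]) * inv[c];
      const vec& d = dy.slice(n).col(c);
      dx.slice(n).col(c) = inv[c] * (gamma[c] * d - s_dxhat[c] / m
                                     - xhat * (s_dxhat_xhat[c] / m));
    }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
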