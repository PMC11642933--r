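// Hot numerical kernels for the additive time-series networks.
// Layout contract (see R/nn.R): activations for a batch are (T*B) x C
// matrices with row index t + (b-1)*T, so each window's T timepoints are
// contiguous. Convolution weights hold all k taps side by side:
// W is C_in x (k*C_out), tap j occupying columns (j-1)*C_out .. j*C_out-1,
// with time offset d_j = j - 1 - (k-1)/2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// 'same' zero-padded 1-D convolution over window blocks.
// [[Rcpp::export(rng = false)]]
arma::mat conv1d_fwd_cpp(const arma::mat& X, const arma::mat& W,
                         const arma::vec& b, const int T, const int B,
                         const int k) {
  const int C_out = W.n_cols / k;
  const int h = (k - 1) / 2;
  mat P = X * W;                       // (T*B) x (k*C_out), one BLAS call
  mat y(T * B, C_out);
  y.each_row() = b.t();
  for (int j = 0; j < k; ++j) {
    const int d = j - h;               // source offset: y[t] += P[t+d]
    const int t_lo = std::max(0, -d);  // 0-based valid dst range
    const int t_hi = std::min(T - 1, T - 1 - d);
    if (t_lo > t_hi) continue;
    const int len = t_hi - t_lo + 1;
    for (int w = 0; w < B; ++w) {
      const int base = w * T;
      y.rows(base + t_lo, base + t_lo + len - 1) +=
        P.submat(base + t_lo + d, j * C_out,
                 base + t_lo + d + len - 1, (j + 1) * C_out - 1);
    }
  }
  return y;
}

// Backward pass of the convolution: dW, db, dX from dY and the cached
// layer input X.
// [[Rcpp::export(rng = false)]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& dY, const arma::mat& X,
                          const arma::mat& W, const int T, const int B,
                          const int k) {
  const int C_out = W.n_cols / k;
  const int h = (k - 1) / 2;
  mat Q(T * B, W.n_cols, fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int d = j - h;
    const int t_lo = std::max(0, -d);
    const int t_hi = std::min(T - 1, T - 1 - d);
    if (t_lo > t_hi) continue;
    const int len = t_hi - t_lo + 1;
    for (int w = 0; w < B; ++w) {
      const int base = w * T;
      Q.submat(base + t_lo + d, j * C_out,
               base + t_lo + d + len - 1, (j + 1) * C_out - 1) =
        dY.rows(base + t_lo, base + t_lo + len - 1);
    }
  }
  mat dW = X.t() * Q;
  mat dX = Q * W.t();
  rowvec db = sum(dY, 0);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

// Batch normalization forward. Returns the normalized output, the caches
// needed for backprop, and updated running statistics (unbiased variance,
// as is conventional for the running estimate). Column-wise (per-channel)
// loops keep every pass contiguous in memory.
// [[Rcpp::export(rng = false)]]
Rcpp::List bn_fwd_cpp(const arma::mat& x, const arma::vec& g,
                      const arma::vec& bet, const arma::vec& run_mean,
                      const arma::vec& run_var, const bool training,
                      const double momentum, const double eps) {
  const uword N = x.n_rows, C = x.n_cols;
  vec new_mean = run_mean, new_var = run_var;
  mat xhat(N, C), y(N, C);
  vec invstd(C);
  const double nfac = N > 1 ? double(N) / double(N - 1) : 1.0;
  for (uword c = 0; c < C; ++c) {
    double mu, v;
    if (training) {
      mu = mean(x.col(c));
      v = 0.0;
      const double* p = x.colptr(c);
      for (uword i = 0; i < N; ++i) { const double d = p[i] - mu; v += d * d; }
      v /= N;
      new_mean(c) = (1 - momentum) * run_mean(c) + momentum * mu;
      new_var(c) = (1 - momentum) * run_var(c) + momentum * v * nfac;
    } else {
      mu = run_mean(c);
      v = run_var(c);
    }
    const double is = 1.0 / std::sqrt(v + eps);
    invstd(c) = is;
    const double gc = g(c), bc = bet(c);
    const double* p = x.colptr(c);
    double* ph = xhat.colptr(c);
    double* py = y.colptr(c);
    for (uword i = 0; i < N; ++i) {
      ph[i] = (p[i] - mu) * is;
      py[i] = ph[i] * gc + bc;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("invstd") = invstd,
                            Rcpp::Named("mean") = new_mean,
                            Rcpp::Named("var") = new_var);
}

// Batch normalization backward (training mode propagates through the
// batch statistics; evaluation mode is a fixed affine map).
// [[Rcpp::export(rng = false)]]
Rcpp::List bn_bwd_cpp(const arma::mat& dy, const arma::mat& xhat,
                      const arma::vec& invstd, const arma::vec& g,
                      const bool training) {
  const uword N = dy.n_rows, C = dy.n_cols;
  vec dg(C), dbet(C);
  mat dx(N, C);
  for (uword c = 0; c < C; ++c) {
    const double* pdy = dy.colptr(c);
    const double* ph = xhat.colptr(c);
    double* pdx = dx.colptr(c);
    double s1 = 0.0, s2 = 0.0;
    for (uword i = 0; i < N; ++i) { s1 += pdy[i]; s2 += pdy[i] * ph[i]; }
    dg(c) = s2;
    dbet(c) = s1;
    const double gc = g(c), is = invstd(c);
    if (training) {
      const double m1 = gc * s1 / N, m2 = gc * s2 / N;
      for (uword i = 0; i < N; ++i)
        pdx[i] = (pdy[i] * gc - m1 - ph[i] * m2) * is;
    } else {
      for (uword i = 0; i < N; ++i) pdx[i] = pdy[i] * gc * is;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dg") = dg,
                            Rcpp::Named("dbet") = dbet);
}
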