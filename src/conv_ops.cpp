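// Minimal 1D conv / max-pool kernels for the block CNN.
// Layout conventions (fixed across the package):
//   feature maps : cube [L, C, N]          (length x channels x batch)
//   conv weights : cube [K, C_in, C_out]   (kernel x in-channels x filters)
// Stride is 1 and padding 0 throughout (the only configuration the
// architecture uses); pooling is non-overlapping with a trailing remainder
// dropped (floor semantics).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// im2col: [C_in*K, L_out*N]; row index c*K + k, column n*L_out + t
static mat im2col(const cube& X, const uword K) {
  const uword L = X.n_rows, C = X.n_cols, N = X.n_slices;
  const uword Lout = L - K + 1;
  mat Xc(C * K, Lout * N);
  for (uword n = 0; n < N; ++n)
    for (uword c = 0; c < C; ++c)
      for (uword k = 0; k < K; ++k)
        for (uword t = 0; t < Lout; ++t)
          Xc(c * K + k, n * Lout + t) = X(t + k, c, n);
  return Xc;
}

static mat flatten_weights(const cube& W) {
  const uword K = W.n_rows, C = W.n_cols, O = W.n_slices;
  mat Wm(O, C * K);
  for (uword o = 0; o < O; ++o)
    for (uword c = 0; c < C; ++c)
      for (uword k = 0; k < K; ++k)
        Wm(o, c * K + k) = W(k, c, o);
  return Wm;
}

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& X, const arma::cube& W,
                          const arma::vec& b) {
  const uword K = W.n_rows, O = W.n_slices, N = X.n_slices;
  const uword Lout = X.n_rows - K + 1;
  mat Y = flatten_weights(W) * im2col(X, K);  // [O, Lout*N]
  Y.each_col() += b;
  cube out(Lout, O, N);
  for (uword n = 0; n < N; ++n)
    out.slice(n) = Y.cols(n * Lout, (n + 1) * Lout - 1).t();
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::cube& X, const arma::cube& W,
                          const arma::cube& dY) {
  const uword K = W.n_rows, C = W.n_cols, O = W.n_slices;
  const uword L = X.n_rows, N = X.n_slices, Lout = dY.n_rows;
  mat dYm(O, Lout * N);
  for (uword n = 0; n < N; ++n)
    dYm.cols(n * Lout, (n + 1) * Lout - 1) = dY.slice(n).t();
  mat Xc = im2col(X, K);
  vec db = sum(dYm, 1);
  mat dWm = dYm * Xc.t();                    // [O, C*K]
  cube dW(K, C, O);
  for (uword o = 0; o < O; ++o)
    for (uword c = 0; c < C; ++c)
      for (uword k = 0; k < K; ++k)
        dW(k, c, o) = dWm(o, c * K + k);
  mat dXc = flatten_weights(W).t() * dYm;    // [C*K, Lout*N]
  cube dX(L, C, N, fill::zeros);
  for (uword n = 0; n < N; ++n)
    for (uword c = 0; c < C; ++c)
      for (uword k = 0; k < K; ++k)
        for (uword t = 0; t < Lout; ++t)
          dX(t + k, c, n) += dXc(c * K + k, n * Lout + t);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// input-gradient only (used by the relevance backward pass)
// [[Rcpp::export]]
arma::cube conv1d_bwd_input_cpp(const arma::cube& W, const arma::cube& dY,
                                const int L_in) {
  const uword K = W.n_rows, C = W.n_cols, O = W.n_slices;
  const uword N = dY.n_slices, Lout = dY.n_rows;
  mat dYm(O, Lout * N);
  for (uword n = 0; n < N; ++n)
    dYm.cols(n * Lout, (n + 1) * Lout - 1) = dY.slice(n).t();
  mat dXc = flatten_weights(W).t() * dYm;
  cube dX((uword)L_in, C, N, fill::zeros);
  for (uword n = 0; n < N; ++n)
    for (uword c = 0; c < C; ++c)
      for (uword k = 0; k < K; ++k)
        for (uword t = 0; t < Lout; ++t)
          dX(t + k, c, n) += dXc(c * K + k, n * Lout + t);
  return dX;
}

// [[Rcpp::export]]
Rcpp::List maxpool1d_fwd_cpp(const arma::cube& X, const int window) {
  const uword w = (uword)window;
  const uword L = X.n_rows, C = X.n_cols, N = X.n_slices;
  const uword Lout = L / w;
  cube out(Lout, C, N);
  // absolute 1-based input positions of the (first) maximum per window
  arma::ucube amax(Lout, C, N);
  for (uword n = 0; n < N; ++n)
    for (uword c = 0; c < C; ++c)
      for (uword t = 0; t < Lout; ++t) {
        uword best = t * w;
        double bv = X(best, c, n);
        for (uword k = 1; k < w; ++k)
          if (X(t * w + k, c, n) > bv) { bv = X(t * w + k, c, n); best = t * w + k; }
        out(t, c, n) = bv;
        amax(t, c, n) = best + 1;
      }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export]]
arma::cube maxpool1d_bwd_cpp(const arma::ucube& argmax, const arma::cube& dY,
                             const int L_in) {
  const uword C = dY.n_cols, N = dY.n_slices, Lout = dY.n_rows;
  cube dX((uword)L_in, C, N, fill::zeros);
  for (uword n = 0; n < N; ++n)
    for (uword c = 0; c < C; ++c)
      for (uword t = 0; t < Lout; ++t)
        dX(argmax(t, c, n) - 1, c, n) += dY(t, c, n);
  return dX;
}
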