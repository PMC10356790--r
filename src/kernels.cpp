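// Compute kernels for the 3D conv machinery. Feature maps are
// [n_positions, channels] matrices; `idx` is the 1-based im2col index
// matrix [n_out, k^3] of flat input spatial positions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// forward convolution: returns output [n_out, cout] and the patch matrix
// P [n_out, k3*cin] (cached for the weight gradient)
// [[Rcpp::export]]
List cpp_conv_fwd(const arma::mat& x, const arma::imat& idx,
                  const arma::mat& W, const arma::vec& b) {
  const arma::uword n_out = idx.n_rows, k3 = idx.n_cols, cin = x.n_cols;
  arma::mat P(n_out, k3 * cin);
  for (arma::uword c = 0; c < cin; ++c) {
    const double* col = x.colptr(c);
    for (arma::uword t = 0; t < k3; ++t) {
      double* dst = P.colptr(c * k3 + t);
      const arma::sword* ip = idx.colptr(t);
      for (arma::uword r = 0; r < n_out; ++r) dst[r] = col[ip[r] - 1];
    }
  }
  arma::mat out = P * W;
  out.each_row() += b.t();
  return List::create(_["out"] = out, _["P"] = P);
}

// backward convolution: weight/bias gradients and (optionally) the input
// gradient via the scatter adjoint of im2col
// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& g, const arma::mat& P,
                  const arma::imat& idx, const arma::mat& W,
                  int n_in, int cin, bool need_dx) {
  arma::mat dW = P.t() * g;
  arma::vec db = arma::sum(g, 0).t();
  arma::mat dX;
  if (need_dx) {
    const arma::uword n_out = idx.n_rows, k3 = idx.n_cols;
    arma::mat dP = g * W.t();
    dX.zeros(n_in, cin);
    for (arma::uword c = 0; c < (arma::uword)cin; ++c) {
      double* dst = dX.colptr(c);
      for (arma::uword t = 0; t < k3; ++t) {
        const double* src = dP.colptr(c * k3 + t);
        const arma::sword* ip = idx.colptr(t);
        for (arma::uword r = 0; r < n_out; ++r) dst[ip[r] - 1] += src[r];
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX,
                      _["have_dx"] = need_dx);
}

// max pooling over the window index matrix; returns pooled values and the
// winning tap per output/channel (1-based)
// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::mat& x, const arma::imat& idx) {
  const arma::uword n_out = idx.n_rows, k3 = idx.n_cols, nc = x.n_cols;
  arma::mat out(n_out, nc);
  arma::imat tap(n_out, nc);
  for (arma::uword c = 0; c < nc; ++c) {
    const double* col = x.colptr(c);
    double* o = out.colptr(c);
    arma::sword* tp = tap.colptr(c);
    for (arma::uword r = 0; r < n_out; ++r) {
      double best = col[idx(r, 0) - 1];
      arma::uword bt = 0;
      for (arma::uword t = 1; t < k3; ++t) {
        double v = col[idx(r, t) - 1];
        if (v > best) { best = v; bt = t; }
      }
      o[r] = best;
      tp[r] = (arma::sword)bt + 1;
    }
  }
  return List::create(_["out"] = out, _["tap"] = tap);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& g, const arma::imat& tap,
                          const arma::imat& idx, int n_in) {
  const arma::uword n_out = idx.n_rows, nc = g.n_cols;
  arma::mat dX(n_in, nc, arma::fill::zeros);
  for (arma::uword c = 0; c < nc; ++c) {
    const double* gc = g.colptr(c);
    const arma::sword* tp = tap.colptr(c);
    double* dst = dX.colptr(c);
    for (arma::uword r = 0; r < n_out; ++r)
      dst[idx(r, tp[r] - 1) - 1] += gc[r];
  }
  return dX;
}

// instance normalization forward: per-channel standardization over the
// spatial dimension, then affine (gamma, beta)
// [[Rcpp::export]]
List cpp_instnorm_fwd(const arma::mat& x, const arma::vec& gamma,
                      const arma::vec& beta, double eps) {
  const arma::uword n = x.n_rows, nc = x.n_cols;
  arma::mat xhat(n, nc), out(n, nc);
  arma::vec istd(nc);
  for (arma::uword c = 0; c < nc; ++c) {
    const double* col = x.colptr(c);
    double mu = 0;
    for (arma::uword r = 0; r < n; ++r) mu += col[r];
    mu /= n;
    double v = 0;
    for (arma::uword r = 0; r < n; ++r) {
      double d = col[r] - mu;
      v += d * d;
    }
    v /= n;
    double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    double* xh = xhat.colptr(c);
    double* o = out.colptr(c);
    for (arma::uword r = 0; r < n; ++r) {
      xh[r] = (col[r] - mu) * is;
      o[r] = xh[r] * gamma[c] + beta[c];
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_instnorm_bwd(const arma::mat& g, const arma::mat& xhat,
                      const arma::vec& istd, const arma::vec& gamma) {
  const arma::uword n = g.n_rows, nc = g.n_cols;
  arma::mat dX(n, nc);
  arma::vec dgamma(nc), dbeta(nc);
  for (arma::uword c = 0; c < nc; ++c) {
    const double* gc = g.colptr(c);
    const double* xh = xhat.colptr(c);
    double sg = 0, sgx = 0;
    for (arma::uword r = 0; r < n; ++r) {
      sg += gc[r];
      sgx += gc[r] * xh[r];
    }
    dbeta[c] = sg;
    dgamma[c] = sgx;
    double m1 = gamma[c] * sg / n, m2 = gamma[c] * sgx / n;
    double* dx = dX.colptr(c);
    for (arma::uword r = 0; r < n; ++r)
      dx[r] = (gamma[c] * gc[r] - m1 - xh[r] * m2) * istd[c];
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
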