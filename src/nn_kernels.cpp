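#include <Rcpp.h>
using namespace Rcpp;

// Fused single-pass kernels for the network's elementwise layers. Each
// replaces several whole-matrix R operations (and their temporaries) on the
// training hot path.

// y = (x - mean[col]) * inv[col] * gamma[col] + beta[col]; also returns xhat
// [[Rcpp::export]]
List cpp_bn_apply(NumericMatrix X, NumericVector mean, NumericVector inv,
                  NumericVector gamma, NumericVector beta, bool want_xhat) {
  const R_xlen_t n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p);
  NumericMatrix xhat = want_xhat ? NumericMatrix(n, p) : NumericMatrix(0, 0);
  for (R_xlen_t j = 0; j < p; ++j) {
    const double m = mean[j], iv = inv[j], g = gamma[j], b = beta[j];
    const double *xc = &X(0, j);
    double *oc = &out(0, j);
    if (want_xhat) {
      double *hc = &xhat(0, j);
      for (R_xlen_t i = 0; i < n; ++i) {
        const double h = (xc[i] - m) * iv;
        hc[i] = h;
        oc[i] = h * g + b;
      }
    } else {
      for (R_xlen_t i = 0; i < n; ++i)
        oc[i] = (xc[i] - m) * iv * g + b;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// batch-norm backward: given dY, xhat, gamma, inv -> dX, dgamma, dbeta
// [[Rcpp::export]]
List cpp_bn_backward(NumericMatrix dY, NumericMatrix xhat,
                     NumericVector gamma, NumericVector inv) {
  const R_xlen_t n = dY.nrow(), p = dY.ncol();
  NumericMatrix dX(n, p);
  NumericVector dgamma(p), dbeta(p);
  for (R_xlen_t j = 0; j < p; ++j) {
    const double *dc = &dY(0, j);
    const double *hc = &xhat(0, j);
    double s1 = 0.0, s2 = 0.0; // sum(dxhat), sum(dxhat * xhat)
    for (R_xlen_t i = 0; i < n; ++i) {
      s1 += dc[i];
      s2 += dc[i] * hc[i];
    }
    dbeta[j] = s1;
    dgamma[j] = s2;
    const double g = gamma[j];
    const double c = inv[j] * g / n;
    double *xc = &dX(0, j);
    for (R_xlen_t i = 0; i < n; ++i)
      xc[i] = c * (n * dc[i] - s1 - hc[i] * s2);
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// inference-mode batch-norm input gradient: dY * gamma[col] * inv[col]
// [[Rcpp::export]]
NumericMatrix cpp_scale_cols(NumericMatrix dY, NumericVector s) {
  const R_xlen_t n = dY.nrow(), p = dY.ncol();
  NumericMatrix out(n, p);
  for (R_xlen_t j = 0; j < p; ++j) {
    const double v = s[j];
    const double *dc = &dY(0, j);
    double *oc = &out(0, j);
    for (R_xlen_t i = 0; i < n; ++i) oc[i] = dc[i] * v;
  }
  return out;
}

// y = x + b[col]
// [[Rcpp::export]]
NumericMatrix cpp_add_cols(NumericMatrix X, NumericVector b) {
  const R_xlen_t n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p);
  for (R_xlen_t j = 0; j < p; ++j) {
    const double v = b[j];
    const double *xc = &X(0, j);
    double *oc = &out(0, j);
    for (R_xlen_t i = 0; i < n; ++i) oc[i] = xc[i] + v;
  }
  return out;
}

// SiLU forward: out = x * sigmoid(x); also returns sigmoid(x) for backward
// [[Rcpp::export]]
List cpp_silu(NumericMatrix X, bool want_sig) {
  const R_xlen_t N = X.size();
  NumericMatrix out(X.nrow(), X.ncol());
  NumericMatrix sig = want_sig ? NumericMatrix(X.nrow(), X.ncol())
                               : NumericMatrix(0, 0);
  const double *x = X.begin();
  double *o = out.begin();
  if (want_sig) {
    double *s = sig.begin();
    for (R_xlen_t i = 0; i < N; ++i) {
      const double sv = 1.0 / (1.0 + std::exp(-x[i]));
      s[i] = sv;
      o[i] = x[i] * sv;
    }
  } else {
    for (R_xlen_t i = 0; i < N; ++i)
      o[i] = x[i] / (1.0 + std::exp(-x[i]));
  }
  return List::create(_["out"] = out, _["sig"] = sig);
}

// SiLU backward: dY * s * (1 + x * (1 - s))
// [[Rcpp::export]]
NumericMatrix cpp_silu_grad(NumericMatrix X, NumericMatrix S,
                            NumericMatrix dY) {
  const R_xlen_t N = X.size();
  NumericMatrix out(X.nrow(), X.ncol());
  const double *x = X.begin(), *s = S.begin(), *d = dY.begin();
  double *o = out.begin();
  for (R_xlen_t i = 0; i < N; ++i)
    o[i] = d[i] * s[i] * (1.0 + x[i] * (1.0 - s[i]));
  return out;
}

// inverted dropout using R's RNG stream: out = x * mask, mask in {0, 1/keep}
// [[Rcpp::export]]
List cpp_dropout(NumericMatrix X, double keep) {
  const R_xlen_t N = X.size();
  NumericMatrix out(X.nrow(), X.ncol());
  NumericMatrix mask(X.nrow(), X.ncol());
  const double *x = X.begin();
  double *o = out.begin(), *m = mask.begin();
  const double scale = 1.0 / keep;
  GetRNGstate();
  for (R_xlen_t i = 0; i < N; ++i) {
    const double mv = (unif_rand() < keep) ? scale : 0.0;
    m[i] = mv;
    o[i] = x[i] * mv;
  }
  PutRNGstate();
  return List::create(_["out"] = out, _["mask"] = mask);
}

// elementwise product (dropout backward and friends)
// [[Rcpp::export]]
NumericMatrix cpp_mul(NumericMatrix A, NumericMatrix B) {
  const R_xlen_t N = A.size();
  NumericMatrix out(A.nrow(), A.ncol());
  const double *a = A.begin(), *b = B.begin();
  double *o = out.begin();
  for (R_xlen_t i = 0; i < N; ++i) o[i] = a[i] * b[i];
  return out;
}

// column means and biased column variances in one pass
// [[Rcpp::export]]
List cpp_col_meanvar(NumericMatrix X) {
  const R_xlen_t n = X.nrow(), p = X.ncol();
  NumericVector mean(p), var(p);
  for (R_xlen_t j = 0; j < p; ++j) {
    const double *xc = &X(0, j);
    double s = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) s += xc[i];
    const double m = s / n;
    double v = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double d = xc[i] - m;
      v += d * d;
    }
    mean[j] = m;
    var[j] = v / n;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}
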