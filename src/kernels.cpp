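// Hot inner kernels of the conv-net engine: same-padding 1-D convolutions
// (dense and depthwise), their backward passes, and the GeLU nonlinearity.
// Activations are [channels, time, batch] cubes; dense convolutions reduce
// to per-tap BLAS products on column ranges.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& x, const arma::cube& W,
                          const arma::vec& b) {
  const int Cout = W.n_rows, L = x.n_cols, N = x.n_slices, k = W.n_slices;
  const int ctr = (k + 1) / 2; // 1-based center
  cube y(Cout, L, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    mat& ys = y.slice(n);
    const mat& xs = x.slice(n);
    for (int j = 0; j < k; ++j) {
      const int o = j + 1 - ctr;
      const int t0 = std::max(0, -o), t1 = L - 1 - std::max(0, o);
      if (t1 < t0) continue;
      ys.cols(t0, t1) += W.slice(j) * xs.cols(t0 + o, t1 + o);
    }
    ys.each_col() += b;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& dy, const arma::cube& x,
                          const arma::cube& W) {
  const int L = x.n_cols, N = x.n_slices, k = W.n_slices;
  const int ctr = (k + 1) / 2;
  cube dW(size(W), fill::zeros);
  cube dx(size(x), fill::zeros);
  vec db(W.n_rows, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const mat& dys = dy.slice(n);
    const mat& xs = x.slice(n);
    db += sum(dys, 1);
    for (int j = 0; j < k; ++j) {
      const int o = j + 1 - ctr;
      const int t0 = std::max(0, -o), t1 = L - 1 - std::max(0, o);
      if (t1 < t0) continue;
      dW.slice(j) += dys.cols(t0, t1) * xs.cols(t0 + o, t1 + o).t();
      dx.slice(n).cols(t0 + o, t1 + o) += W.slice(j).t() * dys.cols(t0, t1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube cpp_dwconv_fwd(const arma::cube& x, const arma::mat& K) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices, k = K.n_cols;
  const int ctr = (k + 1) / 2;
  cube y(C, L, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.slice_memptr(n);
    double* yp = y.slice_memptr(n);
    for (int j = 0; j < k; ++j) {
      const int o = j + 1 - ctr;
      const int t0 = std::max(0, -o), t1 = L - 1 - std::max(0, o);
      const double* Kj = K.colptr(j);
      for (int t = t0; t <= t1; ++t) {
        const double* xc = xp + (size_t)(t + o) * C;
        double* yc = yp + (size_t)t * C;
        for (int c = 0; c < C; ++c) yc[c] += Kj[c] * xc[c];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_dwconv_bwd(const arma::cube& dy, const arma::cube& x,
                          const arma::mat& K) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices, k = K.n_cols;
  const int ctr = (k + 1) / 2;
  cube dx(size(x), fill::zeros);
  mat dK(C, k, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.slice_memptr(n);
    const double* dyp = dy.slice_memptr(n);
    double* dxp = dx.slice_memptr(n);
    for (int j = 0; j < k; ++j) {
      const int o = j + 1 - ctr;
      const int t0 = std::max(0, -o), t1 = L - 1 - std::max(0, o);
      const double* Kj = K.colptr(j);
      double* dKj = dK.colptr(j);
      for (int t = t0; t <= t1; ++t) {
        const double* xc = xp + (size_t)(t + o) * C;
        const double* dyc = dyp + (size_t)t * C;
        double* dxc = dxp + (size_t)(t + o) * C;
        for (int c = 0; c < C; ++c) {
          dKj[c] += xc[c] * dyc[c];
          dxc[c] += Kj[c] * dyc[c];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dK") = dK);
}

static const double INV_SQRT2 = 0.7071067811865475;
static const double INV_SQRT2PI = 0.3989422804014327;

// [[Rcpp::export]]
Rcpp::NumericVector cpp_gelu_fwd(const Rcpp::NumericVector& x) {
  Rcpp::NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] * 0.5 * (1.0 + std::erf(x[i] * INV_SQRT2));
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_gelu_bwd(const Rcpp::NumericVector& x,
                                 const Rcpp::NumericVector& dy) {
  Rcpp::NumericVector dx(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double phi = 0.5 * (1.0 + std::erf(x[i] * INV_SQRT2));
    const double pdf = INV_SQRT2PI * std::exp(-0.5 * x[i] * x[i]);
    dx[i] = dy[i] * (phi + x[i] * pdf);
  }
  dx.attr("dim") = x.attr("dim");
  return dx;
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_fwd(const arma::cube& x, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& run_mean,
                      const arma::vec& run_var, const bool train,
                      const double momentum, const double eps) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices;
  const double m = (double)L * N;
  vec mu(C), v(C);
  if (train) {
    mu.zeros(); v.zeros();
    for (int n = 0; n < N; ++n) {
      const double* xp = x.slice_memptr(n);
      for (int t = 0; t < L; ++t)
        for (int c = 0; c < C; ++c) {
          const double val = xp[(size_t)t * C + c];
          mu[c] += val; v[c] += val * val;
        }
    }
    mu /= m;
    v = v / m - mu % mu;
  } else {
    mu = run_mean; v = run_var;
  }
  vec inv = 1.0 / sqrt(v + eps);
  cube xhat(C, L, N), y(C, L, N);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.slice_memptr(n);
    double* hp = xhat.slice_memptr(n);
    double* yp = y.slice_memptr(n);
    for (int t = 0; t < L; ++t)
      for (int c = 0; c < C; ++c) {
        const size_t i = (size_t)t * C + c;
        hp[i] = (xp[i] - mu[c]) * inv[c];
        yp[i] = gamma[c] * hp[i] + beta[c];
      }
  }
  vec nm = run_mean, nv = run_var;
  if (train) {
    nm = (1 - momentum) * run_mean + momentum * mu;
    nv = (1 - momentum) * run_var + momentum * v;
  }
  return Rcpp::List::create(
    Rcpp::Named("out") = y, Rcpp::Named("xhat") = xhat,
    Rcpp::Named("inv") = inv, Rcpp::Named("run_mean") = nm,
    Rcpp::Named("run_var") = nv);
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_bwd(const arma::cube& dy, const arma::cube& xhat,
                      const arma::vec& inv, const arma::vec& gamma) {
  const int C = dy.n_rows, L = dy.n_cols, N = dy.n_slices;
  const double m = (double)L * N;
  vec dg(C, fill::zeros), db(C, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* dp = dy.slice_memptr(n);
    const double* hp = xhat.slice_memptr(n);
    for (int t = 0; t < L; ++t)
      for (int c = 0; c < C; ++c) {
        const size_t i = (size_t)t * C + c;
        dg[c] += dp[i] * hp[i];
        db[c] += dp[i];
      }
  }
  cube dx(C, L, N);
  for (int n = 0; n < N; ++n) {
    const double* dp = dy.slice_memptr(n);
    const double* hp = xhat.slice_memptr(n);
    double* op = dx.slice_memptr(n);
    for (int t = 0; t < L; ++t)
      for (int c = 0; c < C; ++c) {
        const size_t i = (size_t)t * C + c;
        op[i] = inv[c] * gamma[c] * (dp[i] - db[c] / m - hp[i] * dg[c] / m);
      }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dg,
                            Rcpp::Named("dbeta") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const arma::cube& x, const int stride) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int Lp = L / stride;
  cube y(C, Lp, N);
  Rcpp::IntegerVector am((size_t)C * Lp * N);
  int* ap = am.begin();
  for (int n = 0; n < N; ++n) {
    const double* xp = x.slice_memptr(n);
    double* yp = y.slice_memptr(n);
    for (int t = 0; t < Lp; ++t)
      for (int c = 0; c < C; ++c) {
        double best = xp[(size_t)(t * stride) * C + c];
        int bj = 0;
        for (int j = 1; j < stride; ++j) {
          const double v = xp[(size_t)(t * stride + j) * C + c];
          if (v > best) { best = v; bj = j; }
        }
        const size_t i = (size_t)t * C + c;
        yp[i] = best;
        ap[(size_t)n * C * Lp + i] = bj;
      }
  }
  am.attr("dim") = Rcpp::IntegerVector::create(C, Lp, N);
  return Rcpp::List::create(Rcpp::Named("out") = y, Rcpp::Named("am") = am,
                            Rcpp::Named("L_in") = L);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& dy, const Rcpp::IntegerVector& am,
                           const int L_in, const int stride) {
  const int C = dy.n_rows, Lp = dy.n_cols, N = dy.n_slices;
  cube dx(C, L_in, N, fill::zeros);
  const int* ap = am.begin();
  for (int n = 0; n < N; ++n) {
    const double* dp = dy.slice_memptr(n);
    double* op = dx.slice_memptr(n);
    for (int t = 0; t < Lp; ++t)
      for (int c = 0; c < C; ++c) {
        const size_t i = (size_t)t * C + c;
        const int bj = ap[(size_t)n * C * Lp + i];
        op[(size_t)(t * stride + bj) * C + c] += dp[i];
      }
  }
  return dx;
}

// linear interpolation along time; i0/i1 are 0-based input indices and w
// the weight of i1, precomputed per output position
// [[Rcpp::export]]
arma::cube cpp_interp_fwd(const arma::cube& x, const arma::ivec& i0,
                          const arma::ivec& i1, const arma::vec& w) {
  const int C = x.n_rows, N = x.n_slices, Lo = i0.n_elem;
  cube y(C, Lo, N);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.slice_memptr(n);
    double* yp = y.slice_memptr(n);
    for (int p = 0; p < Lo; ++p) {
      const double* a = xp + (size_t)i0[p] * C;
      const double* b = xp + (size_t)i1[p] * C;
      const double wp = w[p];
      double* yc = yp + (size_t)p * C;
      for (int c = 0; c < C; ++c) yc[c] = (1 - wp) * a[c] + wp * b[c];
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_interp_bwd(const arma::cube& dy, const arma::ivec& i0,
                          const arma::ivec& i1, const arma::vec& w,
                          const int L_in) {
  const int C = dy.n_rows, N = dy.n_slices, Lo = dy.n_cols;
  cube dx(C, L_in, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* dp = dy.slice_memptr(n);
    double* op = dx.slice_memptr(n);
    for (int p = 0; p < Lo; ++p) {
      const double wp = w[p];
      const double* dc = dp + (size_t)p * C;
      double* a = op + (size_t)i0[p] * C;
      double* b = op + (size_t)i1[p] * C;
      for (int c = 0; c < C; ++c) {
        a[c] += (1 - wp) * dc[c];
        b[c] += wp * dc[c];
      }
    }
  }
  return dx;
}
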