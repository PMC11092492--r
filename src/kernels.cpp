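// Low-level numeric kernels: im2col-based 2-D convolution, ceil-mode 2x2
// max-pooling, fused batch-norm + gain-rectification ops, the anchor-point
// quadratic program of the mean-field manifold estimator, and a
// min-norm-point-in-hull solver used as the exact linear-separability
// certificate.
//
// Activation layout everywhere: a C x (H*W*N) matrix whose column index is
// h + H*(w + W*n)  (row index = channel). This keeps batch normalization and
// elementwise ops as plain row operations and lets convolution be a single
// GEMM. Convolutions run in single precision internally (the GEMM and the
// im2col gather are memory-bound); the R-facing API stays double. The hot
// ops take Rcpp proxies rather than Armadillo copies to avoid shuttling
// whole activation maps across the interface.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fmat fmat_of(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  const double* p = x.begin();
  float* q = out.memptr();
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return out;
}

static NumericMatrix num_of(const arma::fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  const float* p = x.memptr();
  double* q = out.begin();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) q[i] = (double)p[i];
  return out;
}

static arma::fmat im2col(const arma::fmat& X, int H, int W, int N,
                         int kh, int kw, int stride, int pad,
                         int& Ho, int& Wo) {
  const int C = X.n_rows;
  Ho = (H + 2 * pad - kh) / stride + 1;
  Wo = (W + 2 * pad - kw) / stride + 1;
  arma::fmat cols(kh * kw * C, (size_t)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t outcol = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        for (int j = 0; j < kw; ++j) {
          const int w = wo * stride - pad + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int h = ho * stride - pad + i;
            if (h < 0 || h >= H) continue;
            const size_t incol = (size_t)h + (size_t)H * (w + (size_t)W * n);
            const size_t r0 = (size_t)C * (i + (size_t)kh * j);
            std::memcpy(cols.colptr(outcol) + r0, X.colptr(incol),
                        C * sizeof(float));
          }
        }
      }
    }
  }
  return cols;
}

static arma::fmat col2im(const arma::fmat& cols, int C, int H, int W, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::fmat X(C, (size_t)H * W * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t outcol = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        for (int j = 0; j < kw; ++j) {
          const int w = wo * stride - pad + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int h = ho * stride - pad + i;
            if (h < 0 || h >= H) continue;
            const size_t incol = (size_t)h + (size_t)H * (w + (size_t)W * n);
            const size_t r0 = (size_t)C * (i + (size_t)kh * j);
            float* xp = X.colptr(incol);
            const float* cp = cols.colptr(outcol) + r0;
            for (int c = 0; c < C; ++c) xp[c] += cp[c];
          }
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
NumericMatrix conv_fwd_cpp(const NumericMatrix& X, const NumericMatrix& Wmat,
                           int H, int W, int N, int kh, int kw,
                           int stride, int pad) {
  int Ho, Wo;
  arma::fmat cols = im2col(fmat_of(X), H, W, N, kh, kw, stride, pad, Ho, Wo);
  return num_of(fmat_of(Wmat) * cols);
}

// forward convolution keeping the im2col matrix for reuse in the backward
// pass (saves the gather, the dominant memory traffic, once per layer)
// [[Rcpp::export]]
List conv_fwd_keep_cpp(const NumericMatrix& X, const NumericMatrix& Wmat,
                       int H, int W, int N, int kh, int kw,
                       int stride, int pad) {
  int Ho, Wo;
  XPtr<arma::fmat> cols(new arma::fmat(
      im2col(fmat_of(X), H, W, N, kh, kw, stride, pad, Ho, Wo)), true);
  return List::create(_["y"] = num_of(fmat_of(Wmat) * (*cols)),
                      _["cols"] = cols);
}

// [[Rcpp::export]]
List conv_bwd_cached_cpp(const NumericMatrix& Wmat, const NumericMatrix& dY,
                         SEXP colsPtr, int C, int H, int W, int N,
                         int kh, int kw, int stride, int pad, bool need_dx) {
  XPtr<arma::fmat> cols(colsPtr);
  arma::fmat dYf = fmat_of(dY);
  NumericMatrix dW = num_of(dYf * cols->t());
  if (!need_dx) return List::create(_["dW"] = dW);
  arma::fmat dcols = fmat_of(Wmat).t() * dYf;
  return List::create(_["dW"] = dW,
                      _["dX"] = num_of(col2im(dcols, C, H, W, N,
                                              kh, kw, stride, pad)));
}

// [[Rcpp::export]]
List conv_bwd_cpp(const NumericMatrix& X, const NumericMatrix& Wmat,
                  const NumericMatrix& dY, int H, int W, int N,
                  int kh, int kw, int stride, int pad, bool need_dx) {
  int Ho, Wo;
  arma::fmat cols = im2col(fmat_of(X), H, W, N, kh, kw, stride, pad, Ho, Wo);
  arma::fmat dYf = fmat_of(dY);
  NumericMatrix dW = num_of(dYf * cols.t());
  if (!need_dx) return List::create(_["dW"] = dW);
  arma::fmat dcols = fmat_of(Wmat).t() * dYf;
  return List::create(_["dW"] = dW,
                      _["dX"] = num_of(col2im(dcols, X.nrow(), H, W, N,
                                              kh, kw, stride, pad)));
}

// 2x2 stride-2 max pooling, ceil mode (ragged right/bottom windows allowed).
// [[Rcpp::export]]
List maxpool2_fwd_cpp(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.nrow();
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericMatrix Y(C, (size_t)Ho * Wo * N);
  IntegerMatrix idx(C, (size_t)Ho * Wo * N);
  const double* xp = X.begin();
  double* yp = Y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t outcol = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        double* ypc = yp + outcol * C;
        int* ipc = ip + outcol * C;
        bool first = true;
        for (int dj = 0; dj < 2; ++dj) {
          const int w = 2 * wo + dj;
          if (w >= W) continue;
          for (int di = 0; di < 2; ++di) {
            const int h = 2 * ho + di;
            if (h >= H) continue;
            const size_t incol = (size_t)h + (size_t)H * (w + (size_t)W * n);
            const double* xpc = xp + incol * C;
            if (first) {
              for (int c = 0; c < C; ++c) { ypc[c] = xpc[c]; ipc[c] = (int)incol; }
              first = false;
            } else {
              for (int c = 0; c < C; ++c)
                if (xpc[c] > ypc[c]) { ypc[c] = xpc[c]; ipc[c] = (int)incol; }
            }
          }
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool2_bwd_cpp(const NumericMatrix& dY,
                               const IntegerMatrix& idx,
                               int H, int W, int N) {
  const int C = dY.nrow();
  NumericMatrix dX(C, (size_t)H * W * N);
  const double* dp = dY.begin();
  const int* ip = idx.begin();
  double* xp = dX.begin();
  const size_t M = (size_t)dY.ncol();
  for (size_t j = 0; j < M; ++j)
    for (int c = 0; c < C; ++c)
      xp[(size_t)ip[j * C + c] * C + c] += dp[j * C + c];
  return dX;
}

// per-channel batch statistics in one pass
// [[Rcpp::export]]
List bn_stats_cpp(const NumericMatrix& a) {
  const int C = a.nrow();
  const size_t M = a.ncol();
  NumericVector mu(C), v(C);
  std::vector<double> s(C, 0.0), ss(C, 0.0);
  const double* p = a.begin();
  for (size_t j = 0; j < M; ++j) {
    const double* pc = p + j * C;
    for (int c = 0; c < C; ++c) { s[c] += pc[c]; ss[c] += pc[c] * pc[c]; }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] = s[c] / (double)M;
    v[c] = ss[c] / (double)M - mu[c] * mu[c];
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// fused standardize + gain rectification: h = G * max(0, (a - mu)/sigma),
// optionally returning the standardized input for the backward pass
// [[Rcpp::export]]
List bn_relu_fwd_cpp(const NumericMatrix& a, const NumericVector& mu,
                     const NumericVector& var, double G, double eps,
                     bool keep_xhat) {
  const int C = a.nrow();
  const size_t M = a.ncol();
  std::vector<double> is(C);
  for (int c = 0; c < C; ++c) is[c] = 1.0 / std::sqrt(var[c] + eps);
  NumericMatrix h(C, M);
  const double* ap = a.begin();
  double* hp = h.begin();
  if (!keep_xhat) {
    for (size_t j = 0; j < M; ++j) {
      const double* ac = ap + j * C;
      double* hc = hp + j * C;
      for (int c = 0; c < C; ++c) {
        double z = (ac[c] - mu[c]) * is[c];
        hc[c] = z > 0 ? G * z : 0.0;
      }
    }
    return List::create(_["h"] = h);
  }
  NumericMatrix xhat(C, M);
  double* xp = xhat.begin();
  for (size_t j = 0; j < M; ++j) {
    const double* ac = ap + j * C;
    double* hc = hp + j * C;
    double* xc = xp + j * C;
    for (int c = 0; c < C; ++c) {
      double z = (ac[c] - mu[c]) * is[c];
      xc[c] = z;
      hc[c] = z > 0 ? G * z : 0.0;
    }
  }
  return List::create(_["h"] = h, _["xhat"] = xhat);
}

// fused backward through gain rectification and batch-statistic
// standardization: q = dh * G * [xhat > 0];
// da = (q - mean_j(q) - xhat * mean_j(q * xhat)) / sigma
// [[Rcpp::export]]
NumericMatrix bn_relu_bwd_cpp(const NumericMatrix& dh,
                              const NumericMatrix& xhat,
                              const NumericVector& var, double G,
                              double eps) {
  const int C = dh.nrow();
  const size_t M = dh.ncol();
  std::vector<double> is(C), mq(C, 0.0), mqx(C, 0.0);
  for (int c = 0; c < C; ++c) is[c] = 1.0 / std::sqrt(var[c] + eps);
  NumericMatrix q(C, M);
  const double* dp = dh.begin();
  const double* xp = xhat.begin();
  double* qp = q.begin();
  for (size_t j = 0; j < M; ++j) {
    const double* dc = dp + j * C;
    const double* xc = xp + j * C;
    double* qc = qp + j * C;
    for (int c = 0; c < C; ++c) {
      double qq = xc[c] > 0 ? dc[c] * G : 0.0;
      qc[c] = qq;
      mq[c] += qq;
      mqx[c] += qq * xc[c];
    }
  }
  for (int c = 0; c < C; ++c) { mq[c] /= (double)M; mqx[c] /= (double)M; }
  for (size_t j = 0; j < M; ++j) {
    double* qc = qp + j * C;
    const double* xc = xp + j * C;
    for (int c = 0; c < C; ++c)
      qc[c] = (qc[c] - mq[c] - xc[c] * mqx[c]) * is[c];
  }
  return q;
}

// Anchor-point program of the mean-field manifold theory. For each Gaussian
// sample t (columns of Tm), solve
//   min_v 0.5 ||v - t||^2   s.t.  s_i . v + kappa <= 0 for every point s_i
// by cyclic coordinate descent on the dual (v = t - S mu, mu >= 0).
// Returns the squared field displacement F = ||t - v||^2 and the anchor
// point s~ = S mu / sum(mu) (max-projection point when t is interior).
// [[Rcpp::export]]
List mft_anchor_cpp(const arma::mat& S, const arma::mat& Tm, double kappa,
                    int maxit, double tol) {
  const int m = S.n_cols, D1 = S.n_rows, nt = Tm.n_cols;
  arma::mat Q = S.t() * S;
  arma::vec qd = Q.diag();
  arma::vec F(nt, arma::fill::zeros);
  arma::mat anchors(D1, nt, arma::fill::zeros);
  arma::uvec interior(nt, arma::fill::zeros);
  for (int k = 0; k < nt; ++k) {
    arma::vec t = Tm.col(k);
    arma::vec g = S.t() * t + kappa;           // constraint values at v = t
    if (g.max() <= 0) {                        // t already feasible
      interior(k) = 1;
      arma::uword imax; (S.t() * t).max(imax);
      anchors.col(k) = S.col(imax);
      continue;
    }
    arma::vec mu(m, arma::fill::zeros);
    arma::vec Qmu(m, arma::fill::zeros);
    for (int it = 0; it < maxit; ++it) {
      double delta = 0.0;
      for (int i = 0; i < m; ++i) {
        if (qd(i) <= 0) continue;
        double newmu = mu(i) + (g(i) - Qmu(i)) / qd(i);
        if (newmu < 0) newmu = 0;
        double d = newmu - mu(i);
        if (d != 0.0) {
          Qmu += d * Q.col(i);
          mu(i) = newmu;
          delta = std::max(delta, std::abs(d));
        }
      }
      if (delta < tol) break;
    }
    arma::vec lam = S * mu;
    F(k) = arma::dot(lam, lam);
    double musum = arma::accu(mu);
    if (musum > 0) anchors.col(k) = lam / musum;
  }
  return List::create(_["F"] = F, _["anchors"] = anchors,
                      _["interior"] = interior);
}

// Minimum-norm point in the convex hull of the columns of Z (signed points
// y_i x_i), by away-step Frank-Wolfe. The dichotomy is linearly separable by
// a homogeneous hyperplane iff 0 is not in the hull; a strict separator found
// along the way certifies separability early.
// [[Rcpp::export]]
List min_norm_hull_cpp(const arma::mat& Z, int maxit, double tol) {
  const int n = Z.n_cols;
  double scale = 0.0;
  for (int i = 0; i < n; ++i) scale = std::max(scale, arma::dot(Z.col(i), Z.col(i)));
  if (scale == 0.0)
    return List::create(_["separable"] = false, _["minnorm2"] = 0.0);
  arma::vec mu(n, arma::fill::zeros);
  mu(0) = 1.0;
  arma::vec w = Z.col(0);
  bool sep = false;
  double f = arma::dot(w, w);
  for (int it = 0; it < maxit; ++it) {
    arma::vec g = Z.t() * w;
    if (g.min() > 1e-10 * std::sqrt(scale * f)) { sep = true; break; }
    if (f < tol * scale) break;                  // norm collapsed: 0 in hull
    arma::uword ifw; g.min(ifw);
    double gap_fw = f - g(ifw);
    arma::uword iaw = 0; double gaw = -arma::datum::inf;
    for (int i = 0; i < n; ++i)
      if (mu(i) > 0 && g(i) > gaw) { gaw = g(i); iaw = i; }
    double gap_aw = gaw - f;
    if (std::max(gap_fw, gap_aw) < 1e-14 * scale) break;  // stationary
    if (gap_fw >= gap_aw) {
      arma::vec d = Z.col(ifw) - w;
      double dd = arma::dot(d, d);
      if (dd <= 0) break;
      double gamma = std::min(1.0, std::max(0.0, -arma::dot(w, d) / dd));
      mu *= (1.0 - gamma); mu(ifw) += gamma;
      w += gamma * d;
    } else {
      arma::vec d = w - Z.col(iaw);
      double dd = arma::dot(d, d);
      if (dd <= 0) break;
      double gmax = mu(iaw) / (1.0 - mu(iaw) + 1e-300);
      double gamma = std::min(gmax, std::max(0.0, -arma::dot(w, d) / dd));
      if (gamma <= 0) break;
      mu *= (1.0 + gamma); mu(iaw) -= gamma;
      w += gamma * d;
    }
    f = arma::dot(w, w);
  }
  if (!sep) {
    arma::vec g = Z.t() * w;
    sep = g.min() > 1e-10 * std::sqrt(scale * std::max(f, 1e-300)) && f > tol * scale;
  }
  return List::create(_["separable"] = sep, _["minnorm2"] = f);
}


// --- float activation chain -------------------------------------------------
// Training and evaluation keep whole activation maps in single precision on
// the C++ heap (R passes opaque handles), halving memory traffic on this
// bandwidth-bound workload. Weights and statistics cross the interface as
// doubles (they are small).

typedef Rcpp::XPtr<arma::fmat> fptr;

static fptr wrap_f(arma::fmat* m) { return fptr(m, true); }

// [[Rcpp::export]]
SEXP px_to_f(const NumericMatrix& X) {
  arma::fmat* out = new arma::fmat(X.nrow(), X.ncol());
  const double* p = X.begin();
  float* q = out->memptr();
  const size_t n = (size_t)X.nrow() * X.ncol();
  for (size_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return wrap_f(out);
}

// [[Rcpp::export]]
NumericMatrix f_to_num(SEXP xp) {
  fptr x(xp);
  return num_of(*x);
}

// [[Rcpp::export]]
List conv_fwd_f(SEXP xp, const NumericMatrix& Wmat, int H, int W, int N,
                int kh, int kw, int stride, int pad, bool keep_cols) {
  fptr x(xp);
  int Ho, Wo;
  arma::fmat* cols = new arma::fmat(
      im2col(*x, H, W, N, kh, kw, stride, pad, Ho, Wo));
  arma::fmat Wf = fmat_of(Wmat);
  arma::fmat* y = new arma::fmat(Wf * (*cols));
  if (keep_cols)
    return List::create(_["y"] = wrap_f(y), _["cols"] = wrap_f(cols));
  delete cols;
  return List::create(_["y"] = wrap_f(y));
}

// [[Rcpp::export]]
SEXP add_f(SEXP ap, SEXP bp) {
  fptr a(ap), b(bp);
  return wrap_f(new arma::fmat(*a + *b));
}

// [[Rcpp::export]]
List bn_stats_f(SEXP ap) {
  fptr a(ap);
  const int C = a->n_rows;
  const size_t M = a->n_cols;
  std::vector<double> s(C, 0.0), ss(C, 0.0);
  const float* p = a->memptr();
  for (size_t j = 0; j < M; ++j) {
    const float* pc = p + j * C;
    for (int c = 0; c < C; ++c) { s[c] += pc[c]; ss[c] += (double)pc[c] * pc[c]; }
  }
  NumericVector mu(C), v(C);
  for (int c = 0; c < C; ++c) {
    mu[c] = s[c] / (double)M;
    v[c] = ss[c] / (double)M - mu[c] * mu[c];
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// [[Rcpp::export]]
List bn_relu_fwd_f(SEXP ap, const NumericVector& mu, const NumericVector& var,
                   double G, double eps, bool keep_xhat) {
  fptr a(ap);
  const int C = a->n_rows;
  const size_t M = a->n_cols;
  std::vector<float> is(C), muf(C);
  for (int c = 0; c < C; ++c) {
    is[c] = (float)(1.0 / std::sqrt(var[c] + eps));
    muf[c] = (float)mu[c];
  }
  const float g = (float)G;
  arma::fmat* h = new arma::fmat(C, M);
  arma::fmat* xh = keep_xhat ? new arma::fmat(C, M) : nullptr;
  const float* apt = a->memptr();
  float* hp = h->memptr();
  float* xp = xh ? xh->memptr() : nullptr;
  for (size_t j = 0; j < M; ++j) {
    const float* ac = apt + j * C;
    float* hc = hp + j * C;
    if (xh) {
      float* xc = xp + j * C;
      for (int c = 0; c < C; ++c) {
        float z = (ac[c] - muf[c]) * is[c];
        xc[c] = z;
        hc[c] = z > 0 ? g * z : 0.0f;
      }
    } else {
      for (int c = 0; c < C; ++c) {
        float z = (ac[c] - muf[c]) * is[c];
        hc[c] = z > 0 ? g * z : 0.0f;
      }
    }
  }
  if (keep_xhat)
    return List::create(_["h"] = wrap_f(h), _["xhat"] = wrap_f(xh));
  return List::create(_["h"] = wrap_f(h));
}

// [[Rcpp::export]]
SEXP bn_relu_bwd_f(SEXP dhp, SEXP xhatp, const NumericVector& var,
                   double G, double eps) {
  fptr dh(dhp), xhat(xhatp);
  const int C = dh->n_rows;
  const size_t M = dh->n_cols;
  std::vector<float> is(C);
  std::vector<double> mq(C, 0.0), mqx(C, 0.0);
  for (int c = 0; c < C; ++c) is[c] = (float)(1.0 / std::sqrt(var[c] + eps));
  const float g = (float)G;
  arma::fmat* q = new arma::fmat(C, M);
  const float* dp = dh->memptr();
  const float* xp = xhat->memptr();
  float* qp = q->memptr();
  for (size_t j = 0; j < M; ++j) {
    const float* dc = dp + j * C;
    const float* xc = xp + j * C;
    float* qc = qp + j * C;
    for (int c = 0; c < C; ++c) {
      float qq = xc[c] > 0 ? dc[c] * g : 0.0f;
      qc[c] = qq;
      mq[c] += qq;
      mqx[c] += (double)qq * xc[c];
    }
  }
  std::vector<float> mqf(C), mqxf(C);
  for (int c = 0; c < C; ++c) {
    mqf[c] = (float)(mq[c] / (double)M);
    mqxf[c] = (float)(mqx[c] / (double)M);
  }
  for (size_t j = 0; j < M; ++j) {
    float* qc = qp + j * C;
    const float* xc = xp + j * C;
    for (int c = 0; c < C; ++c)
      qc[c] = (qc[c] - mqf[c] - xc[c] * mqxf[c]) * is[c];
  }
  return wrap_f(q);
}

// [[Rcpp::export]]
SEXP accum_f(SEXP ap, SEXP bp) {
  fptr a(ap), b(bp);
  *a += *b;
  return ap;
}

// [[Rcpp::export]]
List maxpool2_fwd_f(SEXP xp, int H, int W, int N, bool keep_idx) {
  fptr x(xp);
  const int C = x->n_rows;
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  arma::fmat* Y = new arma::fmat(C, (size_t)Ho * Wo * N);
  std::vector<int>* idx = keep_idx ?
    new std::vector<int>((size_t)C * Ho * Wo * N) : nullptr;
  const float* xpt = x->memptr();
  float* yp = Y->memptr();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t outcol = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        float* ypc = yp + outcol * C;
        int* ipc = idx ? idx->data() + outcol * C : nullptr;
        bool first = true;
        for (int dj = 0; dj < 2; ++dj) {
          const int w = 2 * wo + dj;
          if (w >= W) continue;
          for (int di = 0; di < 2; ++di) {
            const int h = 2 * ho + di;
            if (h >= H) continue;
            const size_t incol = (size_t)h + (size_t)H * (w + (size_t)W * n);
            const float* xpc = xpt + incol * C;
            if (first) {
              for (int c = 0; c < C; ++c) {
                ypc[c] = xpc[c];
                if (ipc) ipc[c] = (int)incol;
              }
              first = false;
            } else {
              for (int c = 0; c < C; ++c)
                if (xpc[c] > ypc[c]) {
                  ypc[c] = xpc[c];
                  if (ipc) ipc[c] = (int)incol;
                }
            }
          }
        }
      }
    }
  }
  List out = List::create(_["y"] = wrap_f(Y));
  if (keep_idx)
    out["idx"] = Rcpp::XPtr<std::vector<int> >(idx, true);
  return out;
}

// [[Rcpp::export]]
SEXP maxpool2_bwd_f(SEXP dyp, SEXP idxp, int H, int W, int N) {
  fptr dy(dyp);
  Rcpp::XPtr<std::vector<int> > idx(idxp);
  const int C = dy->n_rows;
  arma::fmat* dX = new arma::fmat(C, (size_t)H * W * N, arma::fill::zeros);
  const float* dp = dy->memptr();
  const int* ip = idx->data();
  float* xp = dX->memptr();
  const size_t M = dy->n_cols;
  for (size_t j = 0; j < M; ++j)
    for (int c = 0; c < C; ++c)
      xp[(size_t)ip[j * C + c] * C + c] += dp[j * C + c];
  return wrap_f(dX);
}

// [[Rcpp::export]]
List conv_bwd_f(const NumericMatrix& Wmat, SEXP dyp, SEXP colsp,
                int C, int H, int W, int N, int kh, int kw,
                int stride, int pad, bool need_dx) {
  fptr dy(dyp), cols(colsp);
  NumericMatrix dW = num_of((*dy) * cols->t());
  if (!need_dx) return List::create(_["dW"] = dW);
  arma::fmat dcols = fmat_of(Wmat).t() * (*dy);
  arma::fmat* dX = new arma::fmat(col2im(dcols, C, H, W, N,
                                         kh, kw, stride, pad));
  return List::create(_["dW"] = dW, _["dX"] = wrap_f(dX));
}
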