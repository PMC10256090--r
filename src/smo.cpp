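#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// RBF kernel matrix between rows of A (na x d) and B (nb x d)
static void rbf_cross(const NumericMatrix &A, const NumericMatrix &B,
                      double gamma, std::vector<double> &K) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  K.assign((size_t)na * nb, 0.0);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = A(i, c) - B(j, c);
        s += diff * diff;
      }
      K[(size_t)i * nb + j] = std::exp(-gamma * s);
    }
  }
}

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix X, NumericVector y, double C, double gamma,
               double tol = 1e-3, int max_passes = 2000000) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = X(i, c) - X(j, c);
        s += diff * diff;
      }
      double v = std::exp(-gamma * s);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }

  std::vector<double> alpha(n, 0.0), grad(n);
  // gradient of the dual objective: grad_i = y_i * f(x_i) - 1
  for (int i = 0; i < n; ++i) grad[i] = -1.0;

  int iter = 0;
  const double eps = 1e-12;
  while (iter++ < max_passes) {
    // maximal violating pair (libsvm-style working set selection)
    int i_up = -1, i_low = -1;
    double g_max = -std::numeric_limits<double>::infinity();
    double g_min = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      // I_up: y=+1 & alpha<C, or y=-1 & alpha>0
      if ((y[t] > 0 && alpha[t] < C - eps) || (y[t] < 0 && alpha[t] > eps)) {
        double v = -y[t] * grad[t];
        if (v > g_max) { g_max = v; i_up = t; }
      }
      if ((y[t] > 0 && alpha[t] > eps) || (y[t] < 0 && alpha[t] < C - eps)) {
        double v = -y[t] * grad[t];
        if (v < g_min) { g_min = v; i_low = t; }
      }
    }
    if (i_up < 0 || i_low < 0 || g_max - g_min < tol) break;
    int i = i_up, j = i_low;
    double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j];
    double Kij = K[(size_t)i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta < 1e-12) eta = 1e-12;
    double delta = (g_max - g_min) / eta;  // step in alpha_i along y_i
    // clip to box: alpha_i += y_i*step_i ; alpha_j -= y_j*step_i
    double ai_old = alpha[i], aj_old = alpha[j];
    double di = (y[i] > 0) ? (C - ai_old) : ai_old;       // max increase dir
    double dj = (y[j] > 0) ? aj_old : (C - aj_old);
    double step = std::min(delta, std::min(di, dj));
    if (step <= 0) break;
    alpha[i] += (y[i] > 0 ? step : -step);
    alpha[j] += (y[j] > 0 ? -step : step);
    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (K[(size_t)i * n + t] * y[i] * dai +
                         K[(size_t)j * n + t] * y[j] * daj);
  }

  // bias from free support vectors (fallback: midpoint of bounds)
  double b_sum = 0.0; int b_cnt = 0;
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  for (int t = 0; t < n; ++t) {
    double ygf = y[t] * grad[t];  // y_t*f_t - 1 times y? grad = y f - 1
    double f_t = (grad[t] + 1.0) * y[t]; // f(x_t) without bias
    if (alpha[t] > eps && alpha[t] < C - eps) {
      b_sum += y[t] - f_t;
      ++b_cnt;
    } else if ((y[t] > 0 && alpha[t] <= eps) ||
               (y[t] < 0 && alpha[t] >= C - eps)) {
      ub = std::min(ub, y[t] - f_t);
    } else {
      lb = std::max(lb, y[t] - f_t);
    }
    (void)ygf;
  }
  double b;
  if (b_cnt > 0) b = b_sum / b_cnt;
  else if (std::isfinite(ub) && std::isfinite(lb)) b = 0.5 * (ub + lb);
  else if (std::isfinite(ub)) b = ub;
  else if (std::isfinite(lb)) b = lb;
  else b = 0.0;

  // keep only support vectors
  std::vector<int> sv;
  for (int t = 0; t < n; ++t) if (alpha[t] > eps) sv.push_back(t);
  int ns = (int)sv.size();
  NumericMatrix Xs(ns, d);
  NumericVector coef(ns);
  for (int s = 0; s < ns; ++s) {
    for (int c = 0; c < d; ++c) Xs(s, c) = X(sv[s], c);
    coef[s] = alpha[sv[s]] * y[sv[s]];
  }
  return List::create(_["sv"] = Xs, _["coef"] = coef, _["b"] = b,
                      _["n_sv"] = ns, _["iterations"] = iter);
}

// [[Rcpp::export(name = ".smo_decision")]]
NumericVector smo_decision(NumericMatrix Xs, NumericVector coef, double b,
                           double gamma, NumericMatrix Xnew) {
  int ns = Xs.nrow(), m = Xnew.nrow();
  NumericVector out(m);
  std::vector<double> K;
  rbf_cross(Xnew, Xs, gamma, K);
  for (int i = 0; i < m; ++i) {
    double s = b;
    for (int j = 0; j < ns; ++j) s += coef[j] * K[(size_t)i * ns + j];
    out[i] = s;
  }
  return out;
}

// polyphase rational resampler core: output m = sum_j x[j] h[pos - j p] * p,
// pos = hl + m q, over the j range where taps exist
// [[Rcpp::export(name = ".polyphase_resample")]]
NumericVector polyphase_resample(NumericVector x, NumericVector h,
                                 int p, int q, int hl, int nout) {
  int n = x.size(), L = h.size();
  NumericVector y(nout);
  for (int m = 0; m < nout; ++m) {
    long pos = (long)hl + (long)m * q;
    long jlo = (pos - L + 1 + p - 1) / p; if (jlo < 0) jlo = 0;
    long jhi = pos / p; if (jhi > n - 1) jhi = n - 1;
    double s = 0.0;
    for (long j = jlo; j <= jhi; ++j) s += x[j] * h[pos - j * p];
    y[m] = s * p;
  }
  return y;
}
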