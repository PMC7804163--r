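#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// kernel codes: 1 = polynomial (dot(x1,x2)/scale^2 + 1)^p, 2 = gaussian exp(-d2/(2 sigma^2))
namespace {

inline double dot(const double *a, const double *b, int m) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) s += a[k] * b[k];
  return s;
}

inline double sqdist(const double *a, const double *b, int m) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) { double d = a[k] - b[k]; s += d * d; }
  return s;
}

inline double kern(const double *a, const double *b, int m,
                   int type, double p, double scale, double sigma) {
  if (type == 2) return std::exp(-sqdist(a, b, m) / (2.0 * sigma * sigma));
  double v = dot(a, b, m) / (scale * scale) + 1.0;
  double r = v;
  for (int q = 1; q < static_cast<int>(p); ++q) r *= v;
  return r;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".kernel_matrix_cpp")]]
NumericMatrix kernel_matrix_cpp(NumericMatrix X1, NumericMatrix X2,
                                int type, double p, double scale, double sigma) {
  int n1 = X1.nrow(), n2 = X2.nrow(), m = X1.ncol();
  // copy rows to contiguous storage (R matrices are column-major)
  std::vector<double> A(n1 * m), B(n2 * m);
  for (int i = 0; i < n1; ++i)
    for (int k = 0; k < m; ++k) A[i * m + k] = X1(i, k);
  for (int i = 0; i < n2; ++i)
    for (int k = 0; k < m; ++k) B[i * m + k] = X2(i, k);
  NumericMatrix K(n1, n2);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i)
      K(i, j) = kern(&A[i * m], &B[j * m], m, type, p, scale, sigma);
  return K;
}

// SMO with maximal-violating-pair working-set selection (LIBSVM WSS1) on the
// standard soft-margin dual: min 0.5 a'Qa - e'a, 0 <= a <= C, y'a = 0,
// Q_ij = y_i y_j K_ij.
//' @noRd
// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix K, NumericVector y, double C,
                 double eps, double max_iter) {
  const int n = K.nrow();
  const double tau = 1e-12;
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  double iter = 0.0;
  double m_val = 0.0, M_val = 0.0;
  for (;;) {
    // working set selection
    int i = -1, j = -1;
    double Gmax = -INFINITY, Gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool lo = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (lo && v < Gmin) { Gmin = v; j = t; }
    }
    m_val = Gmax; M_val = Gmin;
    if (Gmax - Gmin < eps || iter >= max_iter || i < 0 || j < 0) break;
    ++iter;

    double Qii = K(i, i), Qjj = K(j, j), Qij = y[i] * y[j] * K(i, j);
    double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      double quad = Qii + Qjj + 2.0 * y[i] * y[j] * K(i, j);
      if (quad <= 0) quad = tau;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Qii + Qjj - 2.0 * Qij;
      if (quad <= 0) quad = tau;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dAi = alpha[i] - ai_old, dAj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dAi + y[j] * K(t, j) * dAj);
  }

  // intercept: average of -y_i G_i over free support vectors
  double b, bsum = 0.0;
  int nfree = 0;
  double ctol = 1e-8 * C;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > ctol && alpha[t] < C - ctol) { bsum += -y[t] * G[t]; ++nfree; }
  }
  if (nfree > 0) b = bsum / nfree; else b = 0.5 * (m_val + M_val);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["kkt_gap"] = m_val - M_val);
}
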