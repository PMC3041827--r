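#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual with a
// precomputed kernel matrix. Maximal-violating-pair working-set selection
// with the standard m(alpha) - M(alpha) < eps stopping rule. Per-class upper
// bounds (cpos/cneg) support optional class weighting.
//
// Maintains f_i = sum_j alpha_j y_j K_ij (no intercept); the intercept is
// recovered from the free support vectors at the end.

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, IntegerVector y, double cpos, double cneg,
               double eps = 1e-3, int max_iter = 0) {
  const int n = K.nrow();
  if (max_iter <= 0) max_iter = std::max(10000000 / std::max(n, 1), 200 * n);
  std::vector<double> alpha(n, 0.0), f(n, 0.0), C(n);
  for (int t = 0; t < n; ++t) C[t] = (y[t] > 0) ? cpos : cneg;

  int iter = 0;
  double m_up = 0, m_low = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // select maximal violating pair
    int i = -1, j = -1;
    m_up = -std::numeric_limits<double>::infinity();
    m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = y[t] - f[t];  // equals -y_t * grad_t
      const bool in_up = (y[t] > 0 && alpha[t] < C[t]) || (y[t] < 0 && alpha[t] > 0);
      const bool in_low = (y[t] < 0 && alpha[t] < C[t]) || (y[t] > 0 && alpha[t] > 0);
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;

    const double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta < 1e-12) eta = 1e-12;

    const double ai_old = alpha[i], aj_old = alpha[j];
    // bounds on alpha_j for the pair update
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C[j], C[i] + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C[i]);
      H = std::min(C[j], ai_old + aj_old);
    }
    const double Ei = f[i] - y[i], Ej = f[j] - y[j];
    double aj = aj_old + y[j] * (Ei - Ej) / eta;
    if (aj < L) aj = L;
    if (aj > H) aj = H;
    if (std::abs(aj - aj_old) < 1e-14) {
      // numerically stuck pair; nudge the bound to avoid cycling
      break;
    }
    const double ai = ai_old + y[i] * y[j] * (aj_old - aj);
    alpha[i] = ai;
    alpha[j] = aj;

    const double di = (ai - ai_old) * y[i], dj = (aj - aj_old) * y[j];
    for (int t = 0; t < n; ++t) f[t] += di * K(i, t) + dj * K(j, t);
  }

  // intercept: y_t - f_t == b for free support vectors
  double b_sum = 0; int b_n = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C[t] - 1e-8) {
      b_sum += y[t] - f[t];
      ++b_n;
    }
  }
  const double b = b_n > 0 ? b_sum / b_n : (m_up + m_low) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["gap"] = m_up - m_low);
}
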