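#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for soft-margin C-SVC on a precomputed
// kernel matrix.  Solves
//   min_a  1/2 a' Q a - 1' a   s.t. 0 <= a_i <= C,  y' a = 0,
// with Q_ij = y_i y_j K_ij, using maximal-violating-pair working-set
// selection (the classic LIBSVM WSS1 rule).  Returns the dual coefficients,
// the offset b and the support-vector index set.  Sized for the small
// problems of leave-one-out grids (tens of subjects), where per-call
// overhead dominates any asymptotic concern.

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix K, IntegerVector y, double C,
               double tol = 1e-3, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("labels/kernel size mismatch");
  if (C <= 0) stop("C must be positive");

  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  int iter = 0;
  double m_up = 0, m_low = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // working-set selection: i maximizes -y_i grad_i over I_up,
    // j minimizes -y_j grad_j over I_low
    int i = -1, j = -1;
    m_up = -std::numeric_limits<double>::infinity();
    m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      double g = -y[t] * grad[t];
      if (up && g > m_up)  { m_up = g;  i = t; }
      if (low && g < m_low) { m_low = g; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < tol) break;

    // analytic two-variable update
    double yi = y[i], yj = y[j];
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double delta = (m_up - m_low) / quad;  // step along (y_i e_i - y_j e_j)

    // box clipping: alpha_i += y_i*d, alpha_j -= y_j*d keeps y'a = 0
    double d = delta;
    double ai_max = (yi > 0) ? (C - alpha[i]) : alpha[i];
    double aj_max = (yj > 0) ? alpha[j] : (C - alpha[j]);
    if (d > ai_max) d = ai_max;
    if (d > aj_max) d = aj_max;
    if (d <= 0) break;  // numerically stuck at the box

    alpha[i] += yi * d;
    alpha[j] -= yj * d;
    // grad_t = y_t sum_s a_s y_s K_ts - 1; the paired step changes it by
    // y_t * d * (K_ti - K_tj)
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * d * (K(i, t) - K(j, t));
  }
  if (iter >= max_iter)
    stop("SMO did not converge within %d iterations (gap %.3g)",
         max_iter, m_up - m_low);

  // offset: average -y_t grad_t over free SVs, else midpoint of the bounds
  double b = 0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { b += -y[t] * grad[t]; ++nfree; }
  if (nfree > 0) b /= nfree; else b = (m_up + m_low) / 2.0;

  std::vector<int> sv;
  NumericVector a(n);
  for (int t = 0; t < n; ++t) {
    a[t] = alpha[t];
    if (alpha[t] > 1e-12) sv.push_back(t + 1);
  }
  return List::create(_["alpha"] = a, _["b"] = b,
                      _["support"] = wrap(sv), _["iterations"] = iter);
}

// Decision values f(x) = sum_i alpha_i y_i K(x_i, x) + b for a matrix of
// test-vs-training kernel evaluations (rows = test points).

// [[Rcpp::export(name = ".smo_decision")]]
NumericVector smo_decision(NumericMatrix Ktest, NumericVector alpha,
                           IntegerVector y, double b) {
  const int m = Ktest.nrow(), n = Ktest.ncol();
  if (alpha.size() != n || y.size() != n) stop("coefficient size mismatch");
  NumericVector f(m);
  for (int r = 0; r < m; ++r) {
    double s = b;
    for (int c = 0; c < n; ++c) s += alpha[c] * y[c] * Ktest(r, c);
    f[r] = s;
  }
  return f;
}
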