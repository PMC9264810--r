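#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss linear SVM with the bias
// absorbed as an augmented constant feature (so the dual has box
// constraints only).  Deterministic cyclic update order; stops when the
// largest projected gradient over a full sweep drops below tol.
// [[Rcpp::export]]
List svm_dcd(const NumericMatrix& xa, const NumericVector& y,
             double cost, int max_sweeps, double tol) {
  const int n = xa.nrow(), d = xa.ncol();
  std::vector<double> alpha(n, 0.0), wa(d, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += xa(i, j) * xa(i, j);
    qii[i] = s;
  }
  bool converged = false;
  int sweeps = 0;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double pg_max = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += wa[j] * xa(i, j);
      double g = y[i] * wx - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= cost) pg = std::max(g, 0.0);
      if (std::fabs(pg) > pg_max) pg_max = std::fabs(pg);
      if (pg != 0.0) {
        double a_new = std::min(std::max(alpha[i] - g / qii[i], 0.0), cost);
        double delta = a_new - alpha[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) wa[j] += delta * y[i] * xa(i, j);
          alpha[i] = a_new;
        }
      }
    }
    sweeps = sweep + 1;
    if (pg_max < tol) { converged = true; break; }
  }
  return List::create(_["wa"] = NumericVector(wa.begin(), wa.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["converged"] = converged, _["sweeps"] = sweeps);
}
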