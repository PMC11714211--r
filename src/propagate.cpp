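#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Power iteration for damped propagation on a column-stochastic sparse
// matrix in CSC layout (slot vectors of a dgCMatrix):
//   p_{t+1} = alpha * W p_t + (1 - alpha) * v
// Personalized propagation uses alpha = damping, v = personalization;
// random walk with restart uses alpha = 1 - gamma, v = p0.
// Stops when the L1 change drops below tol, when the iteration stagnates at
// machine precision (so tolerances below double resolution still terminate
// at the numerical fixed point), or at max_iter.
// [[Rcpp::export(name = ".propagate_power")]]
List propagate_power(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                     NumericVector v, double alpha, double tol,
                     int max_iter) {
  const int n = v.size();
  std::vector<double> p(v.begin(), v.end());
  std::vector<double> wp(n);
  bool converged = false;
  int iter = 0;
  const double beta = 1.0 - alpha;
  while (iter < max_iter) {
    ++iter;
    std::fill(wp.begin(), wp.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double pj = p[j];
      if (pj == 0.0) continue;
      for (int k = Wp[j]; k < Wp[j + 1]; ++k)
        wp[Wi[k]] += Wx[k] * pj;
    }
    double delta = 0.0, norm1 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double nv = alpha * wp[i] + beta * v[i];
      delta += std::fabs(nv - p[i]);
      norm1 += std::fabs(nv);
      wp[i] = nv;
    }
    std::swap(p, wp);
    const double stag = 8.0 * std::numeric_limits<double>::epsilon() * norm1;
    if (delta < tol || delta <= stag) { converged = true; break; }
  }
  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
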