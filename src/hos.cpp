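// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Third-order cumulant lattice C3(k, l) = (1/N) * sum_n x(n) x(n+k) x(n+l)
// over all n for which n, n+k, n+l are valid indices. Lags k, l run over
// [-max_lag, max_lag]; output is (2*max_lag+1) x (2*max_lag+1) with lag 0 at
// the centre. Exploits C3(k,l) = C3(l,k): only l >= k is computed.
// [[Rcpp::export]]
arma::mat c3_lattice_cpp(const arma::vec& x, const int max_lag) {
  const int n = x.n_elem;
  const int L = max_lag;
  const int m = 2 * L + 1;
  arma::mat out(m, m, arma::fill::zeros);
  for (int k = -L; k <= L; ++k) {
    for (int l = k; l <= L; ++l) {
      // valid n: 0 <= n, n+k, n+l < n  ->  max(0,-k,-l) <= n < n - max(0,k,l)
      int lo = std::max(0, std::max(-k, -l));
      int hi = n - std::max(0, std::max(k, l));
      double acc = 0.0;
      for (int i = lo; i < hi; ++i) acc += x[i] * x[i + k] * x[i + l];
      acc /= (double)n;
      out(k + L, l + L) = acc;
      out(l + L, k + L) = acc;
    }
  }
  return out;
}
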