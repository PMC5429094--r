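#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Lea-Coulson / MSS recursion for the Luria-Delbruck mutant-count
// distribution. p_0 = exp(-m); p_n = (m/n) * sum_{i=0}^{n-1} p_i/(n-i+1).
// O(n^2); kept in C++ because the likelihood is evaluated repeatedly with
// n_max equal to the largest observed count (heavy-tailed, often >10^3).
// The reciprocals 1/(n-i+1) are precomputed so the inner loop is a pure
// multiply-accumulate.

static void ld_fill(double m, int n_max, double *p) {
  std::vector<double> recip(n_max + 2);
  for (int j = 1; j <= n_max + 1; ++j) recip[j] = 1.0 / (j + 1.0);
  p[0] = std::exp(-m);
  for (int n = 1; n <= n_max; ++n) {
    double s = 0.0;
    const double *r = recip.data() + n;  // r[-i] = 1/(n-i+1)
    for (int i = 0; i < n; ++i) {
      s += p[i] * r[-i];
    }
    p[n] = m * s / static_cast<double>(n);
  }
}

// [[Rcpp::export]]
NumericVector ld_pmf_cpp(double m, int n_max) {
  NumericVector p(n_max + 1);
  ld_fill(m, n_max, REAL(p));
  return p;
}

// Log-likelihood sum(tab[k] * log p_k) for a tabulated count vector
// (tab[k] cultures observed with k mutants), without materialising the
// pmf on the R side.

// [[Rcpp::export]]
double ld_loglik_cpp(NumericVector tab, double m) {
  int n_max = tab.size() - 1;
  std::vector<double> p(n_max + 1);
  ld_fill(m, n_max, p.data());
  double ll = 0.0;
  for (int k = 0; k <= n_max; ++k) {
    if (tab[k] > 0) {
      double pk = p[k] > 1e-300 ? p[k] : 1e-300;
      ll += tab[k] * std::log(pk);
    }
  }
  return ll;
}
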