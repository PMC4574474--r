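#include <Rcpp.h>
using namespace Rcpp;

// Exact Poisson-binomial probability mass function by the standard
// dynamic-programming convolution: f_{j}(t) = f_{j-1}(t) (1 - p_j)
// + f_{j-1}(t-1) p_j.  All quantities are probabilities in [0,1], so the
// recursion is numerically stable (no cancellation) for cohort-scale n.
// [[Rcpp::export]]
NumericVector poisbinom_pmf_cpp(NumericVector p) {
  int n = p.size();
  NumericVector f(n + 1);
  f[0] = 1.0;
  for (int j = 0; j < n; ++j) {
    double pj = p[j];
    for (int t = j + 1; t >= 1; --t)
      f[t] = f[t] * (1.0 - pj) + f[t - 1] * pj;
    f[0] *= (1.0 - pj);
  }
  return f;
}
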