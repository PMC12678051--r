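#include <Rcpp.h>
using namespace Rcpp;

// Row-wise log(mean(exp(M))) with the usual max shift; the inner loop
// of every sequence-likelihood evaluation, so it avoids the temporary
// n x K allocations an R implementation needs.
// [[Rcpp::export(name = ".row_log_mean_exp_cpp")]]
NumericVector row_log_mean_exp_cpp(NumericMatrix M) {
  const int n = M.nrow(), K = M.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double mx = M(i, 0);
    for (int k = 1; k < K; ++k) if (M(i, k) > mx) mx = M(i, k);
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(M(i, k) - mx);
    out[i] = mx + std::log(s / K);
  }
  return out;
}
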