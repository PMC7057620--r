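#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding of the 5-state copy-number HMM with
// distance-dependent transitions:
//   rho(d)   = 1 - exp(-d / expected_len)
//   P(i->j)  = rho * entry[j]              (j != i)
//   P(i->i)  = 1 - rho * (1 - entry[i])
// Rows sum to 1; as d grows the chain relaxes to the entry
// distribution, so `expected_len` acts as the CNV length prior.
// Ties in the predecessor argmax resolve toward the normal state
// (copy number 2): candidates are scanned in the order 2,0,1,3,4 and a
// strict improvement is required to displace the incumbent.

static const int ORDER[5] = {2, 0, 1, 3, 4};

// [[Rcpp::export]]
IntegerVector viterbi_path_cpp(NumericMatrix emiss_ll, NumericVector dist_bp,
                               double expected_len, NumericVector entry) {
  const int n = emiss_ll.nrow();
  const int S = 5;
  if (n == 0) return IntegerVector(0);
  NumericMatrix delta(n, S);
  IntegerMatrix psi(n, S);
  for (int j = 0; j < S; ++j)
    delta(0, j) = std::log(entry[j]) + emiss_ll(0, j);
  for (int t = 1; t < n; ++t) {
    double rho = 1.0 - std::exp(-dist_bp[t - 1] / expected_len);
    double ltrans[5][5];
    for (int i = 0; i < S; ++i)
      for (int j = 0; j < S; ++j)
        ltrans[i][j] = (i == j)
          ? std::log(1.0 - rho * (1.0 - entry[i]))
          : std::log(rho * entry[j]);
    for (int j = 0; j < S; ++j) {
      int best_i = ORDER[0];
      double best = delta(t - 1, best_i) + ltrans[best_i][j];
      for (int k = 1; k < S; ++k) {
        int i = ORDER[k];
        double v = delta(t - 1, i) + ltrans[i][j];
        if (v > best) { best = v; best_i = i; }
      }
      delta(t, j) = best + emiss_ll(t, j);
      psi(t, j) = best_i;
    }
  }
  int last = ORDER[0];
  double best = delta(n - 1, last);
  for (int k = 1; k < S; ++k) {
    int j = ORDER[k];
    if (delta(n - 1, j) > best) { best = delta(n - 1, j); last = j; }
  }
  IntegerVector path(n);
  path[n - 1] = last;
  for (int t = n - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  return path;
}
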