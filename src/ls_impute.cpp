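#include <Rcpp.h>
using namespace Rcpp;

// Haploid Li-Stephens haplotype-copying model, forward-backward.
// States are the H reference haplotypes; between adjacent columns the
// copied template switches to a uniformly chosen haplotype with
// probability `switch_rate` (otherwise stays), and observed alleles
// mismatch the template with probability `error_rate`. Columns where
// `obs` is NA (the CNV marker column in a validation haplotype) emit
// nothing. Returns the posterior over reference haplotypes at
// `query_col` (1-based).

// [[Rcpp::export]]
NumericVector ls_posterior_cpp(IntegerMatrix ref, IntegerVector obs,
                               int query_col, double switch_rate,
                               double error_rate) {
  const int H = ref.nrow();
  const int P = ref.ncol();
  if (obs.size() != P) stop("obs length must equal ncol(ref)");
  if (query_col < 1 || query_col > P) stop("query_col out of range");
  const int q = query_col - 1;
  const double stay = 1.0 - switch_rate;
  const double sw = switch_rate / H;

  std::vector<double> fwd(H * P), tmp(H);
  // forward
  double s = 0.0;
  for (int h = 0; h < H; ++h) {
    double e = 1.0;
    if (obs[0] != NA_INTEGER)
      e = (ref(h, 0) == obs[0]) ? 1.0 - error_rate : error_rate;
    fwd[h] = e / H;
    s += fwd[h];
  }
  for (int h = 0; h < H; ++h) fwd[h] /= s;
  for (int t = 1; t < P; ++t) {
    double tot = 0.0;
    for (int h = 0; h < H; ++h) tot += fwd[(t - 1) * H + h];
    s = 0.0;
    for (int h = 0; h < H; ++h) {
      double pred = stay * fwd[(t - 1) * H + h] + sw * tot;
      double e = 1.0;
      if (obs[t] != NA_INTEGER)
        e = (ref(h, t) == obs[t]) ? 1.0 - error_rate : error_rate;
      fwd[t * H + h] = pred * e;
      s += fwd[t * H + h];
    }
    for (int h = 0; h < H; ++h) fwd[t * H + h] /= s;
  }
  // backward, only down to the query column
  std::vector<double> bwd(H, 1.0);
  for (int t = P - 2; t >= q; --t) {
    double tot = 0.0;
    s = 0.0;
    for (int h = 0; h < H; ++h) {
      double e = 1.0;
      if (obs[t + 1] != NA_INTEGER)
        e = (ref(h, t + 1) == obs[t + 1]) ? 1.0 - error_rate : error_rate;
      tmp[h] = e * bwd[h];
      tot += tmp[h];
    }
    for (int h = 0; h < H; ++h) {
      bwd[h] = stay * tmp[h] + sw * tot;
      s += bwd[h];
    }
    for (int h = 0; h < H; ++h) bwd[h] /= s;
  }
  NumericVector post(H);
  double tot = 0.0;
  for (int h = 0; h < H; ++h) {
    post[h] = fwd[q * H + h] * bwd[h];
    tot += post[h];
  }
  for (int h = 0; h < H; ++h) post[h] /= tot;
  return post;
}
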