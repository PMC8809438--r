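#include <Rcpp.h>
using namespace Rcpp;

// Mean nearest taxon distance of the tips indexed by idx (1-based) in d.
// Ties in nearest-taxon distance are immaterial: only the minimum value
// enters the mean.
static double mntd_idx(const NumericMatrix& d, const int* idx, int k) {
  double tot = 0.0;
  for (int a = 0; a < k; ++a) {
    double best = R_PosInf;
    int i = idx[a] - 1;
    for (int b = 0; b < k; ++b) {
      if (a == b) continue;
      double v = d(i, idx[b] - 1);
      if (v < best) best = v;
    }
    tot += best;
  }
  return tot / k;
}

// [[Rcpp::export]]
double cpp_mntd(const NumericMatrix& d, const IntegerVector& idx) {
  return mntd_idx(d, idx.begin(), idx.size());
}

// MNTD for each column of a k x R matrix of tip indices (the null draws).
// [[Rcpp::export]]
NumericVector cpp_mntd_many(const NumericMatrix& d, const IntegerMatrix& draws) {
  const int R = draws.ncol(), k = draws.nrow();
  NumericVector out(R);
  std::vector<int> idx(k);
  for (int r = 0; r < R; ++r) {
    for (int a = 0; a < k; ++a) idx[a] = draws(a, r);
    out[r] = mntd_idx(d, idx.data(), k);
  }
  return out;
}
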