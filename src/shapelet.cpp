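#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum Euclidean distance between a subsequence S and all contiguous
// windows of T (the shapelet-to-series distance). No normalization: plain
// Euclidean distance over raw values.

static double min_subseq_dist(const double *S, int l, const double *T, int m) {
  double best = R_PosInf;
  for (int off = 0; off + l <= m; ++off) {
    double acc = 0.0;
    for (int j = 0; j < l; ++j) {
      double d = S[j] - T[off + j];
      acc += d * d;
      if (acc >= best) break; // early abandon
    }
    if (acc < best) best = acc;
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
double cpp_subseq_dist(NumericVector S, NumericVector T) {
  if (S.size() > T.size()) stop("subsequence longer than series");
  return min_subseq_dist(S.begin(), S.size(), T.begin(), T.size());
}

// Distance of one shapelet to each row of a series matrix (n x m).
// [[Rcpp::export]]
NumericVector cpp_subseq_dist_rows(NumericVector S, NumericMatrix T) {
  int n = T.nrow(), m = T.ncol(), l = S.size();
  if (l > m) stop("subsequence longer than series");
  NumericVector out(n);
  std::vector<double> row(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) row[j] = T(i, j);
    out[i] = min_subseq_dist(S.begin(), l, row.data(), m);
  }
  return out;
}
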