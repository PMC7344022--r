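#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy.
//
// Templates of length m start at i = 1..N-m (0-based: 0..N-m-1); both the
// m-window and the (m+1)-window counts run over this common index range, so
// every (m+1)-match is also an m-match and a_total <= b_total holds by
// construction. Self-matches are excluded; matching uses the Chebyshev
// (max component) distance with predicate d <= r.
//
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;  // number of template start indices
  double b = 0.0, a = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { match_m = false; break; }
      }
      if (!match_m) continue;
      b += 2.0;  // counts are symmetric in (i, j)
      double dd = std::fabs(x[i + m] - x[j + m]);
      if (dd <= r) a += 2.0;
    }
  }
  return NumericVector::create(_["b_total"] = b, _["a_total"] = a,
                               _["n_templates"] = (double)nt);
}

// Voxelwise sample entropy over a time-by-voxel matrix.
//
// Each column is one voxel's time series. Returns the entropy value per
// column (NaN where undefined) plus an integer reason code:
//   0 = defined, 1 = short series, 2 = zero variance, 3 = zero matches.
// sd is the sample standard deviation (n-1 denominator); with
// per_series_sd the tolerance is r_factor * sd, otherwise r_abs.
//
// [[Rcpp::export]]
List sampen_map_cpp(NumericMatrix ts, int m, double r_factor,
                    bool per_series_sd, double r_abs) {
  const int N = ts.nrow();
  const int V = ts.ncol();
  NumericVector values(V);
  IntegerVector reason(V);
  std::vector<double> x(N);
  for (int v = 0; v < V; ++v) {
    if (N < m + 2) { values[v] = NA_REAL; reason[v] = 1; continue; }
    double mean = 0.0;
    for (int t = 0; t < N; ++t) { x[t] = ts(t, v); mean += x[t]; }
    mean /= N;
    double ss = 0.0;
    for (int t = 0; t < N; ++t) { double d = x[t] - mean; ss += d * d; }
    double sd = std::sqrt(ss / (N - 1));
    double r = per_series_sd ? r_factor * sd : r_abs;
    if (per_series_sd && sd == 0.0) { values[v] = NA_REAL; reason[v] = 2; continue; }
    const int nt = N - m;
    double b = 0.0, a = 0.0;
    for (int i = 0; i < nt - 1; ++i) {
      for (int j = i + 1; j < nt; ++j) {
        double d = 0.0;
        bool match_m = true;
        for (int k = 0; k < m; ++k) {
          double dd = std::fabs(x[i + k] - x[j + k]);
          if (dd > d) d = dd;
          if (d > r) { match_m = false; break; }
        }
        if (!match_m) continue;
        b += 2.0;
        double dd = std::fabs(x[i + m] - x[j + m]);
        if (dd <= r) a += 2.0;
      }
    }
    if (b == 0.0 || a == 0.0) { values[v] = NA_REAL; reason[v] = 3; continue; }
    values[v] = -std::log(a / b);
    reason[v] = 0;
  }
  return List::create(_["values"] = values, _["reason"] = reason);
}
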