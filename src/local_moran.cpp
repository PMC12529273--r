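#include <Rcpp.h>
using namespace Rcpp;

// Conditional permutation null for Local Moran's I: for each point i, hold
// z[i] fixed and draw the neighbour values from the remaining n-1
// observations without replacement (partial Fisher-Yates on a scratch
// buffer, uniform regardless of the buffer's current order). Uses R's RNG
// so results are reproducible via set.seed().
//
// Returns an n x 4 matrix: permutation mean of I_i, permutation sd,
// #{perm I >= observed I}, #{perm I <= observed I}. Rows for isolated
// points (no neighbours) are NA.
// [[Rcpp::export]]
NumericMatrix local_moran_perm_cpp(NumericVector z, List nb, List wt,
                                   NumericVector iobs, double m2, int nsim) {
  int n = z.size();
  NumericMatrix out(n, 4);
  std::vector<double> buf(n > 1 ? n - 1 : 1);
  for (int i = 0; i < n; ++i) {
    IntegerVector nbi = nb[i];  // 0-based neighbour indices
    int k = nbi.size();
    if (k == 0) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL;
      out(i, 2) = NA_REAL; out(i, 3) = NA_REAL;
      continue;
    }
    NumericVector wi = wt[i];
    int m = 0;
    for (int j = 0; j < n; ++j) if (j != i) buf[m++] = z[j];
    double zi_m2 = z[i] / m2;
    double s = 0.0, s2 = 0.0;
    int nge = 0, nle = 0;
    double obs = iobs[i];
    for (int sim = 0; sim < nsim; ++sim) {
      double lag = 0.0;
      for (int j = 0; j < k; ++j) {
        int r = j + (int)(unif_rand() * (m - j));
        if (r >= m) r = m - 1;
        std::swap(buf[j], buf[r]);
        lag += wi[j] * buf[j];
      }
      double I = zi_m2 * lag;
      s += I; s2 += I * I;
      if (I >= obs - 1e-12) ++nge;
      if (I <= obs + 1e-12) ++nle;
    }
    double mean = s / nsim;
    double var = nsim > 1 ? (s2 - nsim * mean * mean) / (nsim - 1) : 0.0;
    out(i, 0) = mean;
    out(i, 1) = var > 0 ? std::sqrt(var) : 0.0;
    out(i, 2) = nge;
    out(i, 3) = nle;
  }
  return out;
}
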