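#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy of a single series.
//
// Template vectors v_i = (x_i, ..., x_{i+m-1}) for i = 1..N-m; pairs
// (i, j != i) match at length m (resp. m+1) when the Chebyshev distance
// is <= r, i.e. Theta(r - d) with Theta(0) = 1.  Both match counts use
// the same i-range so the m+1 count is a subset of the m count, and
// SampEn = -log(B_{m+1} / B_m) on the pooled counts (the per-i
// normalisations 1/(N-m-1) cancel).  r = eps * population sd of x.
//
// Returns NA_real_ when either pooled count is zero (undefined entropy,
// flagged rather than +Inf).
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double eps) {
  const int n = x.size();
  if (m < 1) stop("embedding dimension m must be >= 1");
  if (eps <= 0) stop("tolerance scale eps must be > 0");
  if (n <= m + 1)
    stop("series length (%d) must exceed m + 1 (%d)", n, m + 1);

  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) { double d = x[i] - mu; ss += d * d; }
  const double r = eps * std::sqrt(ss / n);  // population sd

  const int nt = n - m;  // number of template vectors
  double bm = 0.0, bm1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      // Chebyshev distance over the first m coordinates, early exit
      double dmax = 0.0;
      bool match = true;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dmax) dmax = d;
        if (dmax > r) { match = false; break; }
      }
      if (!match) continue;
      bm += 1.0;
      // extend to length m+1: only the appended coordinate can break the match
      if (std::fabs(x[i + m] - x[j + m]) <= r) bm1 += 1.0;
    }
  }
  if (bm == 0.0 || bm1 == 0.0) return NA_REAL;
  return -std::log(bm1 / bm);
}

// Column-wise sample entropy for a windows x edges matrix.
// [[Rcpp::export(name = ".sampen_cols_cpp")]]
NumericVector sampen_cols_cpp(NumericMatrix x, int m, double eps) {
  const int p = x.ncol();
  NumericVector out(p);
  for (int e = 0; e < p; ++e) {
    NumericVector col = x(_, e);
    out[e] = sampen_cpp(col, m, eps);
  }
  return out;
}
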