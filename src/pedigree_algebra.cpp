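#include <Rcpp.h>
using namespace Rcpp;

// Pedigree codes are 1..n, topologically sorted (parents precede offspring).
// A missing parent is coded 0.

// Meuwissen & Luo (1992) inbreeding. O(n * pedigree depth) memory-light
// variant: for each animal the generation coefficients L over its ancestors
// are accumulated by a descending sweep, giving a_ii = sum_j L_j^2 D_j.
// [[Rcpp::export]]
NumericVector ml_inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n), D(n);
  std::vector<double> L(n + 1);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    // Mendelian sampling variance given parental inbreeding
    if (s > 0 && d > 0)
      D[i] = 0.5 - 0.25 * (F[s - 1] + F[d - 1]);
    else if (s > 0)
      D[i] = 0.75 - 0.25 * F[s - 1];
    else if (d > 0)
      D[i] = 0.75 - 0.25 * F[d - 1];
    else
      D[i] = 1.0;
    if (s == 0 || d == 0) { F[i] = 0.0; continue; }
    // a_ii by back-tracing generation coefficients
    std::fill(L.begin(), L.begin() + i + 2, 0.0);
    L[i + 1] = 1.0;
    double aii = 0.0;
    for (int c = i + 1; c >= 1; --c) {
      double lc = L[c];
      if (lc == 0.0) continue;
      aii += lc * lc * D[c - 1];
      int cs = sire[c - 1], cd = dam[c - 1];
      if (cs > 0) L[cs] += 0.5 * lc;
      if (cd > 0) L[cd] += 0.5 * lc;
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Dense tabular numerator relationship matrix.  The first `ngroup` codes are
// pseudo-founders (metafounders) whose mutual relationships are given by
// `founder`; with ngroup = 0 this is the plain tabular method.  Missing
// parents (code 0) contribute nothing.
// [[Rcpp::export]]
NumericMatrix tabular_A_cpp(IntegerVector sire, IntegerVector dam,
                            NumericMatrix founder, int ngroup) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < ngroup; ++i)
    for (int j = 0; j < ngroup; ++j)
      A(i, j) = founder(i, j);
  for (int i = ngroup; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s > i + 1 || d > i + 1) stop("pedigree not topologically sorted");
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s > 0) v += 0.5 * A(s - 1, j);
      if (d > 0) v += 0.5 * A(d - 1, j);
      A(i, j) = v;
      A(j, i) = v;
    }
    double asd = (s > 0 && d > 0) ? A(s - 1, d - 1) : 0.0;
    A(i, i) = 1.0 + 0.5 * asd;
  }
  return A;
}

// Colleau (2002) indirect method: products A %*% V without forming A.
// A = T Dm T' with T = (I - B)^{-1}, B routing 0.5 to each known parent,
// and Dm the Mendelian sampling variances from inbreeding F.
// [[Rcpp::export]]
NumericMatrix A_times_V_cpp(IntegerVector sire, IntegerVector dam,
                            NumericVector F, NumericMatrix V) {
  int n = sire.size(), k = V.ncol();
  if (V.nrow() != n) stop("V must have one row per animal");
  NumericVector Dm(n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s > 0 && d > 0)      Dm[i] = 0.5 - 0.25 * (F[s - 1] + F[d - 1]);
    else if (s > 0)          Dm[i] = 0.75 - 0.25 * F[s - 1];
    else if (d > 0)          Dm[i] = 0.75 - 0.25 * F[d - 1];
    else                     Dm[i] = 1.0;
  }
  NumericMatrix Q(n, k);
  std::vector<double> w(n);
  for (int c = 0; c < k; ++c) {
    for (int i = 0; i < n; ++i) w[i] = V(i, c);
    for (int i = n - 1; i >= 0; --i) {           // w = T' v
      int s = sire[i], d = dam[i];
      if (s > 0) w[s - 1] += 0.5 * w[i];
      if (d > 0) w[d - 1] += 0.5 * w[i];
    }
    for (int i = 0; i < n; ++i) w[i] *= Dm[i];   // w = Dm T' v
    for (int i = 0; i < n; ++i) {                // q = T w
      int s = sire[i], d = dam[i];
      double q = w[i];
      if (s > 0) q += 0.5 * Q(s - 1, c);
      if (d > 0) q += 0.5 * Q(d - 1, c);
      Q(i, c) = q;
    }
  }
  return Q;
}
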