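#include <Rcpp.h>
using namespace Rcpp;

// Founder haplotypes from a Gaussian-copula autoregressive process: a
// latent AR(1) chain along each chromosome (coefficient phi[j] between
// adjacent markers, phi = 0 at chromosome starts) thresholded at the
// normal quantile of each marker's base allele frequency.  Marginals match
// the requested frequencies; neighbouring markers carry distance-decaying
// linkage disequilibrium.
// [[Rcpp::export]]
IntegerMatrix copula_haps_cpp(NumericVector thresh, NumericVector phi,
                              int k) {
  int m = thresh.size();
  IntegerMatrix out(k, m);
  for (int i = 0; i < k; ++i) {
    double z = 0.0;
    for (int j = 0; j < m; ++j) {
      double ph = phi[j];
      z = ph * z + std::sqrt(1.0 - ph * ph) * R::norm_rand();
      out(i, j) = (z < thresh[j]) ? 1 : 0;
    }
  }
  return out;
}

// One recombinant gamete per offspring from the indexed parent's two
// haplotypes.  r[j] is the recombination fraction between markers j-1 and j
// (r = 0.5 at chromosome starts, which uniformises the starting phase).
// [[Rcpp::export]]
IntegerMatrix drop_gametes_cpp(IntegerMatrix H1, IntegerMatrix H2,
                               IntegerVector parent, NumericVector r) {
  int k = parent.size(), m = H1.ncol();
  IntegerMatrix out(k, m);
  for (int i = 0; i < k; ++i) {
    int p = parent[i] - 1;
    int phase = 0;
    for (int j = 0; j < m; ++j) {
      if (R::unif_rand() < r[j]) phase ^= 1;
      out(i, j) = phase ? H2(p, j) : H1(p, j);
    }
  }
  return out;
}
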