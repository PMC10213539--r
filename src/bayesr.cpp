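#include <Rcpp.h>
using namespace Rcpp;

// BayesR Gibbs sampler: SNP effects from a K-component normal mixture
// (first component a point mass at zero), Dirichlet prior on the mixture
// proportions, scaled-inverse-chi-square update for the residual variance.
// The per-class effect variances tau2 are held fixed (fractions of the
// total additive variance), as in the original formulation.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List bayesr_gibbs_cpp(NumericMatrix X, NumericVector y, NumericVector tau2,
                      NumericVector dir_alpha, int niter, int burnin,
                      int thin, double s2e_start) {
  int n = X.nrow(), m = X.ncol(), K = tau2.size();
  if (tau2[0] != 0.0) stop("first mixture class must have zero variance");
  std::vector<double> beta(m, 0.0), xtx(m), e(n), logw(K), pi(K, 1.0 / K);
  std::vector<int> cls(m, 0);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int i = 0; i < n; ++i) e[i] = y[i];
  double s2e = s2e_start;
  NumericVector snp_var(m), beta_mean(m), pi_mean(K);
  NumericMatrix class_prob(m, K);
  std::vector<double> s2e_trace;
  int nsave = 0;

  for (int it = 0; it < niter; ++it) {
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) continue;              // constant marker
      double bj = beta[j];
      double rhs = 0.0;
      if (bj != 0.0) {
        for (int i = 0; i < n; ++i) { e[i] += X(i, j) * bj; rhs += X(i, j) * e[i]; }
      } else {
        for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      }
      // marginal log-likelihood of each class
      double wmax = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double lw = std::log(pi[k] + 1e-300);
        if (tau2[k] > 0.0) {
          double denom = xtx[j] + s2e / tau2[k];
          lw += -0.5 * std::log(tau2[k] * xtx[j] / s2e + 1.0)
                + 0.5 * rhs * rhs / (s2e * denom);
        }
        logw[k] = lw;
        if (lw > wmax) wmax = lw;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { logw[k] = std::exp(logw[k] - wmax); tot += logw[k]; }
      double u = R::runif(0.0, tot);
      int k = 0;
      for (double cum = logw[0]; k < K - 1 && u > cum; cum += logw[++k]) ;
      cls[j] = k;
      if (tau2[k] > 0.0) {
        double denom = xtx[j] + s2e / tau2[k];
        double bnew = R::rnorm(rhs / denom, std::sqrt(s2e / denom));
        beta[j] = bnew;
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * bnew;
      } else {
        beta[j] = 0.0;
      }
    }
    // mixture proportions ~ Dirichlet(alpha + counts)
    {
      std::vector<double> g(K);
      double s = 0.0;
      std::vector<int> cnt(K, 0);
      for (int j = 0; j < m; ++j) cnt[cls[j]]++;
      for (int k = 0; k < K; ++k) { g[k] = R::rgamma(dir_alpha[k] + cnt[k], 1.0); s += g[k]; }
      for (int k = 0; k < K; ++k) pi[k] = g[k] / s;
    }
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = sse / R::rchisq((double) n - 2.0);
    if (!R_finite(s2e) || s2e <= 0.0) stop("residual variance diverged");

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      ++nsave;
      for (int j = 0; j < m; ++j) {
        snp_var[j] += beta[j] * beta[j];
        beta_mean[j] += beta[j];
        class_prob(j, cls[j]) += 1.0;
      }
      for (int k = 0; k < K; ++k) pi_mean[k] += pi[k];
      s2e_trace.push_back(s2e);
    }
  }
  if (nsave == 0) stop("no post-burn-in samples saved");
  for (int j = 0; j < m; ++j) {
    snp_var[j] /= nsave; beta_mean[j] /= nsave;
    for (int k = 0; k < K; ++k) class_prob(j, k) /= nsave;
  }
  for (int k = 0; k < K; ++k) pi_mean[k] /= nsave;
  return List::create(_["snp_var"] = snp_var, _["beta_mean"] = beta_mean,
                      _["class_prob"] = class_prob, _["pi_mean"] = pi_mean,
                      _["s2e_samples"] = wrap(s2e_trace), _["n_saved"] = nsave);
}
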