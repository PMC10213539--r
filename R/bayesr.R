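#' BayesR configuration
#'
#' Four-component normal mixture on SNP effects: the classes have variances
#' equal to fixed fractions of the total additive variance, the first class
#' being a point mass at zero.
#'
#' @param var_fractions nondecreasing mixture variance fractions, first 0
#'   (defaults to the canonical 0, 1e-4, 1e-3, 1e-2).
#' @param niter,burnin,thin chain length, burn-in, thinning.
#' @param dir_alpha Dirichlet prior counts on the mixture proportions.
#' @param seed integer seed.
#' @return An `ml_bayesr_config`.
#' @export
bayesr_config <- function(var_fractions = c(0, 1e-4, 1e-3, 1e-2),
                          niter = 25000L, burnin = 5000L, thin = 10L,
                          dir_alpha = rep(1, length(var_fractions)),
                          seed = 1L) {
  stopifnot(var_fractions[1] == 0, !is.unsorted(var_fractions),
            niter > burnin, thin >= 1)
  structure(list(var_fractions = var_fractions, niter = as.integer(niter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 dir_alpha = dir_alpha, seed = as.integer(seed)),
            class = "ml_bayesr_config")
}

#' Run the BayesR Gibbs sampler
#'
#' Samples SNP effects, class indicators, mixture proportions and the
#' residual variance; per-iteration SNP variances (squared effects) are
#' averaged over post-burn-in samples to form the posterior SNP variance.
#' Phenotypes should be pre-adjusted for fixed and litter effects (one
#' record per genotyped animal).
#'
#' @param geno an `ml_genotypes` over the animals in `y`.
#' @param y named numeric vector of adjusted phenotypes (names = animal
#'   ids present in `geno`).
#' @param config an [bayesr_config()].
#' @param sigma2_g total additive variance anchoring the class variances;
#'   default `0.5 * var(y)`.
#' @return An `ml_bayesr_posterior`: `snp_var` (posterior mean SNP
#'   variance), `class_prob` (markers x classes), `pi_mean`,
#'   `beta_mean`, `s2e_summary`, and the configuration used.
#' @export
run_bayesr <- function(geno, y, config = bayesr_config(),
                       sigma2_g = NULL) {
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by animal id")
  ai <- match(ids, geno$ids)
  if (anyNA(ai)) stop("phenotyped animal missing from genotype set")
  M <- geno$dosage[ai, , drop = FALSE]
  cm <- colMeans(M, na.rm = TRUE)
  X <- sweep(M, 2, cm)
  X[is.na(X)] <- 0
  yc <- y - mean(y)
  if (is.null(sigma2_g)) sigma2_g <- 0.5 * var(yc)
  tau2 <- config$var_fractions * sigma2_g
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(config$seed)
  fit <- bayesr_gibbs_cpp(X, yc, tau2, config$dir_alpha, config$niter,
                          config$burnin, config$thin,
                          s2e_start = max(0.5 * var(yc), 1e-8))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  snp_var <- stats::setNames(fit$snp_var, colnames(geno$dosage))
  structure(list(snp_var = snp_var,
                 beta_mean = stats::setNames(fit$beta_mean,
                                             colnames(geno$dosage)),
                 class_prob = fit$class_prob, pi_mean = fit$pi_mean,
                 s2e_summary = c(mean = mean(fit$s2e_samples),
                                 sd = sd(fit$s2e_samples)),
                 n_saved = fit$n_saved, config = config,
                 sigma2_g = sigma2_g),
            class = "ml_bayesr_posterior")
}

#' Convert posterior SNP variances to ssGBLUP weights
#'
#' Weights proportional to the posterior SNP variances, floored to avoid
#' exact zeros, then rescaled so the trace of the weight matrix equals the
#' number of SNP.
#'
#' @param post an `ml_bayesr_posterior`, or a bare numeric vector of
#'   posterior SNP variances.
#' @param floor minimum pre-scaling relative weight (default 1e-8).
#' @return Named numeric weight vector `d` with `sum(d) == length(d)`.
#' @export
variances_to_weights <- function(post, floor = 1e-8) {
  v <- if (inherits(post, "ml_bayesr_posterior")) post$snp_var else post
  stopifnot(all(v >= 0))
  if (all(v == 0)) stop("all-zero posterior SNP variances")
  d <- pmax(v / mean(v), floor)
  d * length(d) / sum(d)
}
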