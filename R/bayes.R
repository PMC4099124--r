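#' Spike-and-slab mixture prior configuration
#'
#' Hyper-parameters of the Bayesian SNP regression: each effect is a
#' mixture `pi N(0, tau sigma2_beta) + (1 - pi) N(0, sigma2_beta)` with
#' the weight `pi` on the near-zero spike, a Uniform(0,1) prior on `pi`,
#' and scaled inverse chi-square priors on the group SNP-effect variance
#' (`v_beta`, `S2_beta`) and the residual variance (`v_e`, `S2_e`). The
#' small factor `tau` shrinks irrelevant SNP effects towards zero without
#' removing them from the model, and the group (not locus-specific)
#' variance preserves Bayesian learning.
#'
#' @param S2_beta,S2_e scale parameters (> 0).
#' @param tau spike shrinkage factor in (0,1).
#' @param v_beta,v_e degrees of freedom (> 2 so the prior mean exists).
#' @param pi_on_spike if `TRUE` (default) `pi` weights the spike, so a
#'   large posterior `pi` means few SNPs carry effects.
#' @return list of class `mixture_prior`.
#' @export
mixture_prior <- function(S2_beta, S2_e, tau = 1e-4, v_beta = 4, v_e = 10,
                          pi_on_spike = TRUE) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  if (v_beta <= 2 || v_e <= 2)
    stop("degrees of freedom must exceed 2 (prior mean must exist)")
  if (S2_beta <= 0 || S2_e <= 0) stop("scales must be > 0")
  structure(list(tau = tau, v_beta = v_beta, v_e = v_e,
                 S2_beta = S2_beta, S2_e = S2_e,
                 pi_on_spike = pi_on_spike),
            class = "mixture_prior")
}

#' Derive mixture-prior scales from variance components
#'
#' Assuming the SNPs capture all the additive genetic variance, the prior
#' mean of the SNP-effect variance is
#' `E[sigma2_beta] = sigma2_a / (2 sum_j p_j (1 - p_j))` and the prior
#' mean of the residual variance is `sigma2_E`. Since a scaled inverse
#' chi-square with df `v` and scale `S2` has mean `v S2 / (v - 2)`, the
#' scales follow as `S2 = E * (v - 2) / v`.
#'
#' @param vc a [variance_components()].
#' @param freqs allele frequencies of the (polymorphic) SNPs.
#' @inheritParams mixture_prior
#' @return A [mixture_prior()].
#' @export
derive_hyperparameters <- function(vc, freqs, tau = 1e-4, v_beta = 4,
                                   v_e = 10, pi_on_spike = TRUE) {
  if (v_beta <= 2 || v_e <= 2) stop("degrees of freedom must exceed 2")
  p <- freqs[freqs > 0 & freqs < 1]
  if (!length(p)) stop("need at least one polymorphic SNP")
  e_s2b <- vc$sigma2_a / (2 * sum(p * (1 - p)))
  mixture_prior(S2_beta = e_s2b * (v_beta - 2) / v_beta,
                S2_e = vc$sigma2_E * (v_e - 2) / v_e,
                tau = tau, v_beta = v_beta, v_e = v_e,
                pi_on_spike = pi_on_spike)
}

#' Gibbs sampler settings
#'
#' @param n_iter total iterations (study-scale default 100,000).
#' @param burn_in discarded warm-up iterations (study-scale 20,000).
#' @param thinning keep every k-th post-burn-in sample (default 1: all
#'   samples kept).
#' @param seed RNG seed.
#' @return list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 100000, burn_in = 20000, thinning = 1,
                         seed = 1L) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), seed = as.integer(seed)),
            class = "gibbs_config")
}

#' Gibbs sampling for the spike-and-slab SNP regression
#'
#' Systematic-scan Gibbs sampler for
#' `y = 1 mu + X beta + e`. Each sweep updates `mu` (normal full
#' conditional under a flat prior), each `(delta_j, beta_j)` jointly
#' (`delta_j` from its two-point conditional with `beta_j` integrated
#' out, then `beta_j` from its normal conditional given the component),
#' `pi` from `Beta(1 + n_spike, 1 + n_slab)` (Uniform-prior conjugacy),
#' the group variance `sigma2_beta` from its scaled inverse chi-square
#' conditional pooling `beta_j^2 / t_j` over both components
#' (`t_j = tau` in the spike, 1 in the slab), and `sigma2_e` from its
#' scaled inverse chi-square conditional on the residuals. Residuals are
#' updated incrementally after every effect move and refreshed to machine
#' precision every 1,000 sweeps.
#'
#' Posterior means over the kept samples are returned as the estimates;
#' `fix_pi` and `fix_variances` allow conditioning on known values, which
#' turns single-SNP posteriors into closed-form conjugate quantities used
#' for validation.
#'
#' @param y phenotype vector (no missing values).
#' @param X centered dosage matrix (individuals x SNPs, no missing).
#' @param prior a [mixture_prior()].
#' @param cfg a [gibbs_config()].
#' @param fix_pi `NULL` or a fixed value for `pi` (0 with
#'   `pi_on_spike = TRUE` puts every SNP in the slab).
#' @param fix_variances `NULL` or list with `sigma2_beta` and/or
#'   `sigma2_e` held fixed.
#' @return Object of class `bayes_fit`: posterior summary with
#'   `beta_mean`, `inclusion_freq` (slab membership frequency per SNP),
#'   `mu_mean`, `pi_mean`, `sigma2_beta_mean`, `sigma2_e_mean`, scalar
#'   chains (`pi_chain`, `sigma2_beta_chain`, `sigma2_e_chain`,
#'   `mu_chain`; for m <= 8 SNPs also the full `beta_chain`),
#'   `resid_drift` (largest incremental-residual deviation seen at
#'   refresh points) and the configuration used.
#' @export
gibbs_sample <- function(y, X, prior, cfg, fix_pi = NULL,
                         fix_variances = NULL) {
  stopifnot(inherits(prior, "mixture_prior"), inherits(cfg, "gibbs_config"))
  if (anyNA(X) || anyNA(y)) stop("y and X must be complete")
  if (length(y) < 2) stop("need at least 2 records")
  set.seed(cfg$seed)
  update_pi <- is.null(fix_pi)
  pi_init <- if (update_pi) 0.5 else fix_pi
  fvb <- !is.null(fix_variances$sigma2_beta)
  fve <- !is.null(fix_variances$sigma2_e)
  res <- cpp_gibbs_mixture(
    as.numeric(y), as.matrix(X),
    prior$tau, prior$v_beta, prior$S2_beta, prior$v_e, prior$S2_e,
    cfg$n_iter, cfg$burn_in, cfg$thinning,
    update_pi, pi_init, prior$pi_on_spike,
    fvb, if (fvb) fix_variances$sigma2_beta else -1,
    fve, if (fve) fix_variances$sigma2_e else -1,
    1000L)
  if (!all(is.finite(res$beta_mean)))
    stop("non-finite state in Gibbs sampler")
  res$prior <- prior
  res$config <- cfg
  class(res) <- "bayes_fit"
  res
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf(
    "bayes_fit: %d SNPs, %d kept samples; pi_mean = %.3f, sigma2_e = %.3g\n",
    length(x$beta_mean), x$n_kept, x$pi_mean, x$sigma2_e_mean))
  invisible(x)
}

#' Predict direct genomic values from posterior mean SNP effects
#'
#' `DGV_i = sum_j x_ij beta_mean_j` over all loci; the population mean is
#' excluded (a constant shift, irrelevant to Pearson accuracy).
#'
#' @param X_new centered dosage matrix on the same markers, same order,
#'   as used in training.
#' @param fit a `bayes_fit` (or any vector of per-SNP effects).
#' @return Numeric DGV vector.
#' @export
predict_dgv <- function(X_new, fit) {
  beta <- if (inherits(fit, "bayes_fit")) fit$beta_mean else fit
  if (ncol(X_new) != length(beta))
    stop("marker count mismatch between X_new and the fitted effects")
  drop(as.matrix(X_new) %*% beta)
}

#' Geweke-style burn-in adequacy check
#'
#' Compares the means of the first and last fractions of a kept scalar
#' chain with a two-sample z statistic using spectral-density-free
#' batch-variance estimates. |z| below ~3 indicates no gross
#' non-stationarity after burn-in.
#'
#' @param chain numeric vector of kept samples.
#' @param frac1,frac2 fractions used from the start and end.
#' @return The z statistic.
#' @export
geweke_z <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  n <- length(chain)
  a <- chain[seq_len(max(2, floor(frac1 * n)))]
  b <- chain[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
  # variance of the mean from batch means (robust to autocorrelation)
  batch_var <- function(x) {
    nb <- max(2, floor(sqrt(length(x))))
    means <- tapply(x, cut(seq_along(x), nb), mean)
    var(means) / nb
  }
  (mean(a) - mean(b)) / sqrt(batch_var(a) + batch_var(b))
}

#' Center dosages by twice the allele frequency
#'
#' @param g a [geno_matrix()] or dosage matrix.
#' @param freqs frequencies to center by (default observed).
#' @return list with `X` (centered matrix) and `p`.
#' @export
center_dosages <- function(g, freqs = NULL) {
  X <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  p <- if (is.null(freqs)) colMeans(X) / 2 else freqs
  list(X = sweep(X, 2, 2 * p), p = p)
}
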