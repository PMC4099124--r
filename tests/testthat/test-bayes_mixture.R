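test_that("hyper-parameter scales follow the scaled-inv-chi-square mean", {
  vc <- variance_components(1, 1)
  pr <- derive_hyperparameters(vc, 0.5)
  # E[sigma2_beta] = 1 / (2 * 0.25) = 2; v=4 halves it
  expect_equal(pr$S2_beta, 1)
  expect_equal(pr$S2_e, 0.8)

  pr2 <- derive_hyperparameters(variance_components(3, 2), c(0.5, 0.1))
  t <- 3 / (2 * (0.25 + 0.09))
  expect_equal(pr2$S2_beta, t / 2)
  expect_equal(pr2$S2_e, 2 * 0.8)

  expect_error(derive_hyperparameters(vc, 0.5, v_beta = 2), "exceed 2")
  expect_error(mixture_prior(1, 1, tau = 0), "tau")
})

test_that("with fixed pi and variances the sampler matches the conjugate
           closed form", {
  set.seed(90)
  n <- 120
  x <- scale(rbinom(n, 2, 0.5), scale = FALSE)   # centered: orthogonal to 1
  beta_true <- 0.7
  y <- drop(x) * beta_true + rnorm(n)
  pr <- mixture_prior(S2_beta = 0.5, S2_e = 0.8)
  cfg <- gibbs_config(6000, 1000, seed = 91)
  s2b <- 0.5; s2e <- 1
  fit <- gibbs_sample(y, matrix(x), pr, cfg, fix_pi = 0,
                      fix_variances = list(sigma2_beta = s2b,
                                           sigma2_e = s2e))
  xx <- sum(x^2)
  post_mean <- sum(x * y) / (xx + s2e / s2b)
  post_var <- s2e / (xx + s2e / s2b)
  mc_se <- sqrt(post_var / fit$n_kept)
  expect_lt(abs(fit$beta_mean - post_mean), 3 * mc_se * 2)

  # two orthogonal SNPs: closed form per coordinate
  x2 <- rep(c(-1, 1), n / 2) * abs(drop(x))      # orthogonalish by design
  X2 <- cbind(drop(x), drop(scale(x2, scale = FALSE)))
  X2[, 2] <- X2[, 2] - X2[, 1] * sum(X2[, 1] * X2[, 2]) / sum(X2[, 1]^2)
  y2 <- X2 %*% c(0.5, -0.4) + rnorm(n)
  fit2 <- gibbs_sample(drop(y2), X2, pr, cfg, fix_pi = 0,
                       fix_variances = list(sigma2_beta = s2b,
                                            sigma2_e = s2e))
  for (j in 1:2) {
    xxj <- sum(X2[, j]^2)
    pm <- sum(X2[, j] * y2) / (xxj + s2e / s2b)
    pv <- s2e / (xxj + s2e / s2b)
    expect_lt(abs(fit2$beta_mean[j] - pm), 3 * sqrt(pv / fit2$n_kept) * 2)
  }
})

test_that("a null response gives null posterior means", {
  set.seed(92)
  X <- matrix(rbinom(50 * 20, 2, 0.5), 50, 20)
  X <- sweep(X, 2, colMeans(X))
  fit <- gibbs_sample(rep(0, 50), X, mixture_prior(0.01, 0.8),
                      gibbs_config(2000, 500, seed = 93))
  expect_lt(max(abs(fit$beta_mean)), 0.05)
  expect_lt(abs(fit$mu_mean), 0.05)
})

test_that("chains are seed-deterministic and residuals stay consistent", {
  set.seed(94)
  n <- 80; m <- 60
  X <- sweep(matrix(rbinom(n * m, 2, 0.3), n, m), 2, 2 * 0.3)
  y <- X[, 1] - X[, 2] + rnorm(n)
  pr <- mixture_prior(0.05, 0.8)
  cfg <- gibbs_config(3000, 500, seed = 95)
  f1 <- gibbs_sample(y, X, pr, cfg)
  f2 <- gibbs_sample(y, X, pr, cfg)
  expect_identical(f1$beta_mean, f2$beta_mean)
  expect_identical(f1$pi_chain, f2$pi_chain)
  expect_lt(f1$resid_drift, 1e-8)
})

test_that("burn-in leaves no gross trend in the kept chains", {
  set.seed(96)
  n <- 100; m <- 50
  X <- sweep(matrix(rbinom(n * m, 2, 0.4), n, m), 2, 2 * 0.4)
  y <- X[, 1] + rnorm(n)
  fit <- gibbs_sample(y, X, mixture_prior(0.05, 0.8),
                      gibbs_config(6000, 2000, seed = 97))
  expect_lt(abs(geweke_z(fit$sigma2_e_chain)), 5)
  expect_lt(abs(geweke_z(fit$pi_chain)), 5)
})

test_that("planted QTL are recovered on a sparse trait with unlinked
           markers", {
  hits <- logical(10)
  for (s in 1:10) {
    set.seed(110 + s)
    n <- 500; m <- 1000
    X <- sapply(runif(m, 0.1, 0.9), function(p) rbinom(n, 2, p))
    g <- toy_geno(X)
    tr <- build_trait(list(n_qtl = 5, effect_distribution = "equal",
                           sigma2_a = 1, sigma2_E = 1), g)
    ph <- simulate_proofs(tr$tbv, 0.5, tr$architecture)   # h2 = 0.5
    cen <- center_dosages(g)
    prior <- derive_hyperparameters(variance_components(1, 1),
                                    cen$p[cen$p > 0 & cen$p < 1])
    fit <- gibbs_sample(ph$y, cen$X, prior,
                        gibbs_config(10000, 2000, seed = 110 + s))
    top20 <- order(-abs(fit$beta_mean))[1:20]
    hits[s] <- all(tr$architecture$qtl_indices %in% top20) &&
      fit$pi_mean >= 0.9
  }
  expect_gte(sum(hits), 8)
})

test_that("DGV prediction sums posterior-mean effects over loci", {
  X <- matrix(c(0, 1, 2) - 1, 3, 1)
  expect_equal(predict_dgv(X, c(1)), c(-1, 0, 1))
  expect_equal(predict_dgv(X, c(0)), c(0, 0, 0))
  Xd <- rbind(X, X[2, , drop = FALSE])
  expect_equal(predict_dgv(Xd, c(2))[2], predict_dgv(Xd, c(2))[4])
  expect_error(predict_dgv(matrix(0, 2, 3), c(1, 2)), "mismatch")
})

test_that("centering by allele frequency shifts DGV by a constant only", {
  set.seed(98)
  n <- 60; m <- 40
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  beta <- rnorm(m, 0, 0.1)
  d_raw <- drop(X %*% beta)
  cen <- center_dosages(toy_geno(X))
  d_cen <- drop(cen$X %*% beta)
  expect_lt(diff(range(d_raw - d_cen)), 1e-12)
})
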