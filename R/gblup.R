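#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = (M - P)(M - P)' / (2 * sum_j p_j (1 - p_j))`, where `M` is the
#' dosage matrix and `P` the matrix whose j-th column is `2 p_j`. Under
#' Hardy-Weinberg proportions the diagonal of `G` averages close to 1.
#' Monomorphic markers carry no information and are excluded from the
#' sum with a warning.
#'
#' @param g a [geno_matrix()] with no missing genotypes.
#' @param freqs allele frequencies used for centering; defaults to the
#'   observed frequencies in `g` (the combined genotyped set).
#' @return Object of class `grm`: list with `G` (n x n), `p` (frequencies
#'   used) and `scale` (`2 sum p(1-p)`).
#' @export
compute_grm <- function(g, freqs = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  X <- g$dosages
  if (anyNA(X)) stop("genotypes must be complete (impute first)")
  p <- if (is.null(freqs)) colMeans(X) / 2 else freqs
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic marker(s) excluded from the GRM")
    X <- X[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  sc <- 2 * sum(p * (1 - p))
  if (sc <= 0) stop("scaling constant is zero")
  W <- sweep(X, 2, 2 * p)
  G <- tcrossprod(W) / sc
  dimnames(G) <- list(g$sample_ids, g$sample_ids)
  structure(list(G = G, p = p, scale = sc), class = "grm")
}

#' GBLUP prediction of direct genomic values
#'
#' Fits `y = 1 mu + g + e` with `g ~ N(0, G sigma2_a)` and
#' `e ~ N(0, I sigma2_E)` on the training animals (mu fixed, estimated by
#' GLS) and predicts validation DGV either by conditional regression
#' `G_vt (G_tt)^-1 g_t` (default, algebraically `sigma2_a G_vt V^-1 r`) or
#' through the joint mixed-model equations with missing validation
#' phenotypes; the two are equivalent. A singular system is stabilised by
#' a 1e-8 ridge on the G diagonal, with a message.
#'
#' @param y training phenotype vector (length = `length(train_idx)`).
#' @param G a `grm` (or plain matrix) covering training and prediction
#'   animals.
#' @param vc list with `sigma2_a` and `sigma2_E` (see
#'   [variance_components()]).
#' @param train_idx,predict_idx disjoint row indices of `G`.
#' @param method "conditional" or "joint".
#' @return Named DGV vector for `predict_idx` (deviations from the mean;
#'   mu is not included).
#' @export
fit_gblup <- function(y, G, vc, train_idx, predict_idx,
                      method = c("conditional", "joint")) {
  method <- match.arg(method)
  Gm <- if (inherits(G, "grm")) G$G else G
  if (length(intersect(train_idx, predict_idx)))
    stop("train_idx and predict_idx must be disjoint")
  stopifnot(length(y) == length(train_idx), vc$sigma2_a > 0, vc$sigma2_E > 0)
  Gtt <- Gm[train_idx, train_idx]
  Gvt <- Gm[predict_idx, train_idx, drop = FALSE]
  nt <- length(train_idx)
  V <- vc$sigma2_a * Gtt + diag(vc$sigma2_E, nt)
  Vi <- tryCatch(solve(V), error = function(e) {
    message("singular system; adding 1e-8 ridge to the G diagonal")
    solve(vc$sigma2_a * (Gtt + diag(1e-8, nt)) + diag(vc$sigma2_E, nt))
  })
  one <- rep(1, nt)
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  r <- Vi %*% (y - mu)
  if (method == "conditional") {
    dgv <- drop(vc$sigma2_a * Gvt %*% r)
  } else {
    # joint MME over train + predict animals with Z selecting training rows
    all_idx <- c(train_idx, predict_idx)
    na <- length(all_idx)
    Ga <- Gm[all_idx, all_idx] + diag(1e-8, na)
    Gi <- solve(Ga)
    lambda <- vc$sigma2_E / vc$sigma2_a
    Zt <- cbind(diag(1, nt), matrix(0, nt, na - nt))
    C <- rbind(cbind(nt, t(one) %*% Zt),
               cbind(t(Zt) %*% one, crossprod(Zt) + lambda * Gi))
    rhs <- c(sum(y), drop(t(Zt) %*% y))
    sol <- solve(C, rhs)
    dgv <- sol[-1][(nt + 1):na]
  }
  names(dgv) <- rownames(Gm)[predict_idx]
  dgv
}

#' Variance components container
#'
#' @param sigma2_a additive genetic variance.
#' @param sigma2_E residual (environmental) variance.
#' @param source "plug-in" (simulator truth) or "EM-REML".
#' @return list of class `variance_components`.
#' @export
variance_components <- function(sigma2_a, sigma2_E, source = "plug-in") {
  stopifnot(sigma2_a > 0, sigma2_E > 0)
  structure(list(sigma2_a = sigma2_a, sigma2_E = sigma2_E, source = source),
            class = "variance_components")
}

#' EM-REML variance component estimation for the GRM animal model
#'
#' Estimates `sigma2_a` and `sigma2_E` in `y = 1 mu + g + e`,
#' `g ~ N(0, G sigma2_a)`, by classical EM-REML iterations
#' (`theta_new = theta + theta^2 (y' P V_i P y - tr(P V_i)) / n` for each
#' component), computed in the eigenbasis of `G` so each iteration is
#' O(n). Convergence is declared when the relative parameter change of
#' the proposed update falls below `tol` (checked before accepting, so
#' `tol = Inf` returns the initial values).
#'
#' @param y phenotype vector.
#' @param G a `grm` or matrix over the same animals.
#' @param init optional list with starting `sigma2_a`, `sigma2_E`
#'   (default: half the phenotypic variance each).
#' @param max_iter,tol iteration cap and relative-change tolerance.
#' @return A [variance_components()] with attributes `iterations` and
#'   `converged`.
#' @export
em_reml <- function(y, G, init = NULL, max_iter = 200, tol = 1e-6) {
  n <- length(y)
  if (n < 30) stop("need at least 30 records for REML")
  Gm <- if (inherits(G, "grm")) G$G else G
  eg <- eigen(Gm, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, n)))
  vp <- var(y)
  th <- if (is.null(init)) c(a = vp / 2, e = vp / 2)
        else c(a = init$sigma2_a, e = init$sigma2_E)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    v <- th["a"] * d + th["e"]
    vi <- 1 / v
    xvx <- sum(xt^2 * vi)
    # P y and traces in the eigenbasis (X reduces to the vector xt)
    py <- yt * vi - xt * vi * sum(xt * vi * yt) / xvx
    trP <- sum(vi) - sum(xt^2 * vi^2) / xvx
    trPG <- sum(d * vi) - sum(xt^2 * d * vi^2) / xvx
    new_a <- th["a"] + th["a"]^2 * (sum(py^2 * d) - trPG) / n
    new_e <- th["e"] + th["e"]^2 * (sum(py^2) - trP) / n
    new <- c(a = max(new_a, 1e-10), e = max(new_e, 1e-10))
    if (max(abs(new - th) / pmax(abs(th), 1e-12)) < tol) {
      converged <- TRUE
      break
    }
    th <- new
    it <- it + 1
  }
  if (!converged) warning("EM-REML did not converge in ", max_iter,
                          " iterations")
  out <- variance_components(th[["a"]], th[["e"]], source = "EM-REML")
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}

#' Ridge SNP-BLUP direct genomic values
#'
#' Random-regression BLUP of SNP effects with a common per-SNP variance
#' `sigma2_a / (2 sum p(1-p))`, predicting DGV by summing the estimated
#' SNP effects. Algebraically identical to GBLUP with the VanRaden G; kept
#' as an independent route for cross-checking.
#'
#' @param y training phenotypes.
#' @param g a [geno_matrix()] over all animals.
#' @param vc a [variance_components()].
#' @param train_idx,predict_idx disjoint row indices.
#' @param freqs centering frequencies (default observed).
#' @return Named DGV vector for `predict_idx`.
#' @export
fit_snp_ridge <- function(y, g, vc, train_idx, predict_idx, freqs = NULL) {
  X <- g$dosages
  p <- if (is.null(freqs)) colMeans(X) / 2 else freqs
  keep <- p > 0 & p < 1
  W <- sweep(X[, keep, drop = FALSE], 2, 2 * p[keep])
  sc <- 2 * sum(p[keep] * (1 - p[keep]))
  s2b <- vc$sigma2_a / sc
  Wt <- W[train_idx, , drop = FALSE]
  nt <- length(train_idx)
  V <- s2b * tcrossprod(Wt) + diag(vc$sigma2_E, nt)
  Vi <- solve(V)
  one <- rep(1, nt)
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  beta <- s2b * drop(crossprod(Wt, Vi %*% (y - mu)))
  dgv <- drop(W[predict_idx, , drop = FALSE] %*% beta)
  names(dgv) <- g$sample_ids[predict_idx]
  dgv
}
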