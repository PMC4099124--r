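#' Per-marker allele frequencies
#'
#' Frequency of the counted ("2") allele at each SNP, computed over
#' non-missing genotypes only.
#'
#' @param g a [geno_matrix()] or a dosage matrix.
#' @return Numeric vector `p` of length m; `NA` (with a warning) for
#'   markers where every genotype is missing.
#' @export
allele_frequencies <- function(g) {
  X <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  n_obs <- colSums(!is.na(X))
  p <- colSums(X, na.rm = TRUE) / (2 * n_obs)
  if (any(n_obs == 0)) {
    warning(sum(n_obs == 0), " marker(s) with all genotypes missing")
    p[n_obs == 0] <- NA_real_
  }
  unname(p)
}

#' Hardy-Weinberg disequilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against expected Hardy-Weinberg proportions computed from the
#' sample allele frequency (no continuity correction). Monomorphic
#' markers return p = 1 by convention (no disequilibrium is testable).
#'
#' @param n0,n1,n2 counts of genotypes 0, 1, 2 (vectors are recycled to a
#'   common length for vectorised use).
#' @return Upper-tail p-value(s).
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (any(n <= 0)) stop("total genotype count must be > 0")
  p <- (n1 + 2 * n2) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  chi2 <- ifelse(p == 0 | p == 1, 0,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Apply marker quality-control filters
#'
#' Removes SNPs with minor allele frequency below `maf_min`, missing rate
#' above `missing_max`, or a Hardy-Weinberg disequilibrium p-value below
#' `hwe_p_min`. All three rules are evaluated on the input matrix and the
#' failing markers are removed jointly, so filtering is idempotent and
#' order-independent. Defaults are the standard 50 k bull-chip filters
#' (MAF < 0.05, missing > 15%, HWE p < 1e-4).
#'
#' @param g a [geno_matrix()].
#' @param maf_min,missing_max,hwe_p_min filter thresholds in (0,1);
#'   `maf_min = 0` / `missing_max = 1` / `hwe_p_min = 0` disable a rule.
#' @return list with `geno` (filtered [geno_matrix()]) and `report`
#'   (data.frame: `id`, `maf`, `missing_rate`, `hwe_p`, `pass`,
#'   `reasons` — comma-separated subset of MAF, MISSING, HWE).
#' @export
apply_filters <- function(g, maf_min = 0.05, missing_max = 0.15,
                          hwe_p_min = 1e-4) {
  stopifnot(inherits(g, "geno_matrix"))
  X <- g$dosages
  miss <- colMeans(is.na(X))
  p <- allele_frequencies(g)
  maf <- pmin(p, 1 - p)
  n0 <- colSums(X == 0, na.rm = TRUE)
  n1 <- colSums(X == 1, na.rm = TRUE)
  n2 <- colSums(X == 2, na.rm = TRUE)
  hwe_p <- hwe_test(n0, n1, n2)

  fail_maf <- is.na(maf) | maf < maf_min
  fail_miss <- miss > missing_max
  fail_hwe <- hwe_p < hwe_p_min
  reasons <- mapply(function(a, b, c)
    paste(c("MAF", "MISSING", "HWE")[c(a, b, c)], collapse = ","),
    fail_maf, fail_miss, fail_hwe, USE.NAMES = FALSE)
  pass <- !(fail_maf | fail_miss | fail_hwe)
  report <- data.frame(id = g$map$id, maf = maf, missing_rate = miss,
                       hwe_p = hwe_p, pass = pass, reasons = reasons,
                       row.names = NULL)
  if (!any(pass)) stop("all markers removed by QC filters")
  keep <- which(pass)
  g2 <- geno_matrix(X[, keep, drop = FALSE], g$map[keep, , drop = FALSE],
                    g$sample_ids)
  list(geno = g2, report = report)
}
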