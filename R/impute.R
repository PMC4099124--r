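#' Family-based genotype imputation (Mendelian forcing)
#'
#' Fills missing genotypes only where Mendelian logic forces a unique
#' value: when both parents are genotyped and homozygous at a marker, the
#' offspring genotype is the sum of the transmitted alleles. No
#' probabilistic guesses are made at this stage. Individuals are processed
#' in pedigree order, so genotypes forced for a parent propagate to its
#' descendants. Mendelian conflicts between observed parent and offspring
#' genotypes are counted and the genotype is left untouched.
#'
#' @param g a [geno_matrix()] with missing entries.
#' @param pedigree data.frame (`id`, `sire`, `dam`), parents before
#'   offspring; parents absent from `g` are simply unused.
#' @return A [geno_matrix()] with forced genotypes filled; attribute
#'   `conflicts` holds the number of Mendelian conflicts observed.
#' @export
family_impute <- function(g, pedigree) {
  stopifnot(inherits(g, "geno_matrix"))
  X <- g$dosages
  posof <- stats::setNames(seq_len(nrow(X)), g$sample_ids)
  conflicts <- 0L
  for (r in seq_len(nrow(pedigree))) {
    i <- posof[as.character(pedigree$id[r])]
    if (is.na(i)) next
    si <- posof[as.character(pedigree$sire[r])]
    di <- posof[as.character(pedigree$dam[r])]
    if (is.na(si) && is.na(di)) next
    child <- X[i, ]
    sg <- if (!is.na(si)) X[si, ] else rep(NA_real_, ncol(X))
    dg <- if (!is.na(di)) X[di, ] else rep(NA_real_, ncol(X))
    conflicts <- conflicts +
      sum((child == 0 & sg == 2) | (child == 2 & sg == 0), na.rm = TRUE) +
      sum((child == 0 & dg == 2) | (child == 2 & dg == 0), na.rm = TRUE)
    forced <- is.na(child) & !is.na(sg) & !is.na(dg) &
      sg %in% c(0, 2) & dg %in% c(0, 2)
    if (any(forced)) X[i, forced] <- sg[forced] / 2 + dg[forced] / 2
  }
  out <- geno_matrix(X, g$map, g$sample_ids)
  attr(out, "conflicts") <- conflicts
  out
}

#' Count Mendelian conflicts between observed genotypes
#'
#' A conflict is an offspring homozygous for the allele a genotyped parent
#' cannot transmit (parent 0 with child 2, or parent 2 with child 0).
#'
#' @param g a [geno_matrix()].
#' @param pedigree data.frame (`id`, `sire`, `dam`).
#' @return Integer conflict count.
#' @export
mendelian_conflicts <- function(g, pedigree) {
  attr(family_impute(g, pedigree), "conflicts")
}

phasing_windows <- function(m, size, overlap) {
  step <- max(1L, as.integer(round(size * (1 - overlap))))
  starts <- seq(1L, max(1L, m - size + 1L), by = step)
  if (starts[length(starts)] + size - 1L < m)
    starts <- c(starts, m - size + 1L)
  lapply(unique(starts), function(s) c(s, min(s + size - 1L, m)))
}

# order-preserving unique haplotypes with counts, most frequent first
pool_haps <- function(H) {
  key <- apply(H, 1, paste, collapse = "")
  tab <- table(key)
  first <- !duplicated(key)
  Hu <- H[first, , drop = FALSE]
  f <- as.numeric(tab[key[first]])
  ord <- order(-f, seq_along(f))
  list(H = Hu[ord, , drop = FALSE], f = f[ord])
}

#' Phase a fully genotyped reference and build a haplotype library
#'
#' Phasing is a deterministic two-stage heuristic. Homozygous sites
#' self-phase; heterozygous sites are first resolved by trio logic (a
#' homozygous parent pins the transmitted allele). Remaining ambiguous
#' sites are resolved window by window, left to right with overlapping
#' windows: within each window, fully resolved haplotypes form a candidate
#' pool and each partially resolved haplotype is completed by copying the
#' most frequent pool haplotype consistent with its known alleles and its
#' genotype; sites already phased in the overlap with the previous window
#' anchor the orientation, so phase information propagates along the
#' chromosome. Windows never span chromosome boundaries.
#'
#' @param reference a [geno_matrix()] with no missing genotypes.
#' @param pedigree pedigree data.frame used for trio phasing (parents
#'   before offspring).
#' @param window_size markers per phasing window.
#' @param overlap fraction of overlap between consecutive windows.
#' @return Object of class `hap_library`: list with `haps` (2n x m 0/1
#'   matrix, rows 2i-1/2i the paternal/maternal haplotypes of reference
#'   individual i), `map`, `sample_ids`, `window_size`, `overlap` and
#'   `unphased_fallbacks` (count of haplotype-window fills that had no
#'   consistent candidate and were completed by site-parity assignment).
#' @export
build_library <- function(reference, pedigree, window_size = 50,
                          overlap = 0.5) {
  stopifnot(inherits(reference, "geno_matrix"))
  G <- reference$dosages
  if (anyNA(G)) stop("reference must have no missing genotypes")
  n <- nrow(G); m <- ncol(G)
  posof <- stats::setNames(seq_len(n), reference$sample_ids)

  # paternal allele: NA = unresolved
  P <- matrix(NA_real_, n, m)
  P[G == 0] <- 0
  P[G == 2] <- 1
  sire_pos <- rep(NA_integer_, n); dam_pos <- rep(NA_integer_, n)
  pr <- match(reference$sample_ids, as.character(pedigree$id))
  ok <- !is.na(pr)
  sire_pos[ok] <- posof[as.character(pedigree$sire[pr[ok]])]
  dam_pos[ok] <- posof[as.character(pedigree$dam[pr[ok]])]
  for (i in seq_len(n)) {
    het <- which(G[i, ] == 1)
    if (!length(het)) next
    if (!is.na(sire_pos[i])) {
      sg <- G[sire_pos[i], het]
      P[i, het[sg == 0]] <- 0
      P[i, het[sg == 2]] <- 1
    }
    unres <- het[is.na(P[i, het])]
    if (length(unres) && !is.na(dam_pos[i])) {
      dg <- G[dam_pos[i], unres]
      P[i, unres[dg == 0]] <- 1      # maternal allele is 0
      P[i, unres[dg == 2]] <- 0
    }
  }

  fallbacks <- 0L
  rngs <- chrom_ranges(reference$map)
  anchors <- P

  # fill the NA entries of Pw from candidate pool haplotypes: exact
  # consistency first (most frequent candidate wins), then, if `force`,
  # the fewest-mismatch candidate
  fill_window <- function(Pw, Gw, pool_mat, force) {
    for (pass in 1:2) {
      need <- which(rowSums(is.na(Pw)) > 0)
      if (!length(need)) break
      if (is.null(pool_mat)) {
        done <- which(rowSums(is.na(Pw)) == 0)
        if (!length(done)) {
          if (pass == 2) {
            # no resolvable haplotype anywhere: site-parity fallback
            for (i in need) {
              na_at <- which(is.na(Pw[i, ]))
              Pw[i, na_at] <- seq_along(na_at) %% 2
              fallbacks <<- fallbacks + 1L
            }
          }
          next
        }
        pool <- pool_haps(rbind(Pw[done, , drop = FALSE],
                                Gw[done, , drop = FALSE] -
                                  Pw[done, , drop = FALSE]))
      } else {
        pool <- pool_mat
      }
      A1 <- (Pw[need, , drop = FALSE] == 1); A1[is.na(A1)] <- FALSE
      A0 <- (Pw[need, , drop = FALSE] == 0); A0[is.na(A0)] <- FALSE
      mism <- A1 %*% t(1 - pool$H) + A0 %*% t(pool$H)
      if (pass == 1 && !force) {
        compat <- mism == 0
        pick <- max.col(ifelse(compat, rep(pool$f, each = length(need)),
                               -1), ties.method = "first")
        hit <- rowSums(compat) > 0
      } else {
        pick <- max.col(-mism, ties.method = "first")
        hit <- rep(TRUE, length(need))
        fallbacks <<- fallbacks +
          sum(mism[cbind(seq_along(pick), pick)] > 0)
      }
      for (k in which(hit)) {
        i <- need[k]
        na_at <- is.na(Pw[i, ])
        Pw[i, na_at] <- pool$H[pick[k], na_at]
      }
      if (pass == 1 && force) break
    }
    Pw
  }

  sweep_chromosomes <- function(P, full_lib = NULL) {
    for (cc in seq_len(nrow(rngs))) {
      wins <- phasing_windows(rngs$end[cc] - rngs$start[cc] + 1L,
                              window_size, overlap)
      for (w in wins) {
        cols <- (rngs$start[cc] + w[1] - 1L):(rngs$start[cc] + w[2] - 1L)
        pool_mat <- if (is.null(full_lib)) NULL else
          pool_haps(rbind(full_lib[, cols, drop = FALSE],
                          G[, cols, drop = FALSE] -
                            full_lib[, cols, drop = FALSE]))
        P[, cols] <- fill_window(P[, cols, drop = FALSE],
                                 G[, cols, drop = FALSE],
                                 pool_mat, force = !is.null(full_lib))
      }
    }
    P
  }

  # first sweep grows the pool window by window; the refinement sweep
  # re-phases the ambiguous entries against the full first-sweep library,
  # whose frequency spectrum corrects early-window guesses
  P1 <- sweep_chromosomes(P)
  P <- sweep_chromosomes(anchors, full_lib = P1)

  M <- G - P
  haps <- matrix(0L, 2 * n, m)
  haps[seq(1, 2 * n, 2), ] <- as.integer(P)
  haps[seq(2, 2 * n, 2), ] <- as.integer(M)
  structure(list(haps = haps, map = reference$map,
                 sample_ids = reference$sample_ids,
                 window_size = window_size, overlap = overlap,
                 unphased_fallbacks = fallbacks),
            class = "hap_library")
}

#' Mean switch-error rate of phased haplotypes against truth
#'
#' For each individual, heterozygous sites are compared between the
#' inferred and true haplotype pair; the switch-error rate is the number
#' of phase flips along consecutive heterozygous sites divided by the
#' number of opportunities.
#'
#' @param phased,truth 2n x m haplotype matrices (rows 2i-1/2i per
#'   individual).
#' @return Mean switch-error rate over individuals with at least two
#'   heterozygous sites.
#' @export
switch_error_rate <- function(phased, truth) {
  stopifnot(all(dim(phased) == dim(truth)))
  n <- nrow(phased) / 2
  rates <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p1 <- phased[2 * i - 1, ]; t1 <- truth[2 * i - 1, ]
    g <- phased[2 * i - 1, ] + phased[2 * i, ]
    het <- which(g == 1)
    if (length(het) < 2) next
    o <- p1[het] == t1[het]
    rates[i] <- sum(diff(o) != 0) / (length(het) - 1)
  }
  mean(rates, na.rm = TRUE)
}

#' Population imputation by sliding-window haplotype matching
#'
#' For each window, each target's observed low-density genotypes are
#' matched against the library haplotypes: a haplotype is compatible when
#' it agrees with at least `min_match` of the target's observed homozygous
#' sites in the window. Compatible haplotypes vote on missing alleles,
#' weighted by their library frequency; the imputed dosage is twice the
#' weighted allele frequency, rounded to a hard call. When no haplotype is
#' compatible the window shrinks by halving around its centre until a
#' match is found or `floor` markers remain; cells still unresolved after
#' all windows are filled with the marker's major genotype in the
#' reference. Observed genotypes are never altered.
#'
#' @param masked a [geno_matrix()] with missing entries to impute.
#' @param lib a `hap_library` built on the same map.
#' @param window list with `size` (markers), `overlap` (fraction),
#'   `min_match` (required agreement on observed homozygous sites) and
#'   `floor` (smallest shrunken window).
#' @return Object of class `imputation_result`: list with `geno` (no
#'   missing entries), `imputed_cells` (logical matrix of cells filled),
#'   `fraction_imputed` (per individual) and `fallback_cells` (count
#'   major-genotype filled).
#' @export
population_impute <- function(masked, lib,
                              window = list(size = 50, overlap = 0.5,
                                            min_match = 0.97, floor = 5)) {
  stopifnot(inherits(masked, "geno_matrix"), inherits(lib, "hap_library"))
  if (nrow(lib$map) != ncol(masked$dosages))
    stop("library map does not cover the masked matrix")
  if (nrow(lib$haps) == 0) stop("empty haplotype library")
  X <- masked$dosages
  miss0 <- is.na(X)
  targ <- which(rowSums(miss0) > 0)
  m <- ncol(X)
  # reference major genotype per marker (final fallback)
  Gref <- lib$haps[seq(1, nrow(lib$haps), 2), , drop = FALSE] +
    lib$haps[seq(2, nrow(lib$haps), 2), , drop = FALSE]
  major <- apply(Gref, 2, function(col) {
    tab <- tabulate(col + 1L, 3L)
    which.max(tab) - 1L
  })
  if (!length(targ)) {
    out <- geno_matrix(X, masked$map, masked$sample_ids)
    return(structure(list(geno = out, imputed_cells = miss0,
                          fraction_imputed = rowMeans(miss0),
                          fallback_cells = 0L),
                     class = "imputation_result"))
  }

  numer <- matrix(0, length(targ), m)
  denom <- matrix(0, length(targ), m)
  Xt <- X[targ, , drop = FALSE]
  rngs <- chrom_ranges(masked$map)
  for (cc in seq_len(nrow(rngs))) {
    nloc <- rngs$end[cc] - rngs$start[cc] + 1L
    wins <- phasing_windows(nloc, min(window$size, nloc), window$overlap)
    for (w in wins) {
      cols <- (rngs$start[cc] + w[1] - 1L):(rngs$start[cc] + w[2] - 1L)
      pool <- pool_haps(lib$haps[, cols, drop = FALSE])
      H <- pool$H; f <- pool$f
      Tw <- Xt[, cols, drop = FALSE]
      C0 <- Tw == 0; C0[is.na(C0)] <- FALSE
      C2 <- Tw == 2; C2[is.na(C2)] <- FALSE
      mism <- C0 %*% t(H) + C2 %*% t(1 - H)
      nobs <- rowSums(C0) + rowSums(C2)
      allowed <- floor((1 - window$min_match) * nobs)
      compat <- mism <= allowed
      Wt <- compat * rep(f, each = nrow(compat))
      rs <- rowSums(Wt)
      hit <- rs > 0
      if (any(hit)) {
        q <- (Wt[hit, , drop = FALSE] %*% H) / rs[hit]
        numer[hit, cols] <- numer[hit, cols] + q
        denom[hit, cols] <- denom[hit, cols] + 1
      }
      # shrink the window around its centre for unmatched targets
      for (k in which(!hit)) {
        lo <- 1L; hi <- length(cols)
        repeat {
          width <- hi - lo + 1L
          if (width <= window$floor) break
          cut <- width %/% 4L
          lo <- lo + cut; hi <- hi - cut
          sub <- lo:hi
          h2 <- H[, sub, drop = FALSE]
          c0 <- C0[k, sub]; c2 <- C2[k, sub]
          mm <- as.vector(h2 %*% ifelse(c0, 1, 0) +
                          (1 - h2) %*% ifelse(c2, 1, 0))
          alw <- floor((1 - window$min_match) * sum(c0 | c2))
          cmp <- mm <= alw
          if (any(cmp)) {
            wts <- f * cmp
            q <- as.vector(crossprod(h2, wts)) / sum(wts)
            numer[k, cols[sub]] <- numer[k, cols[sub]] + q
            denom[k, cols[sub]] <- denom[k, cols[sub]] + 1
            break
          }
        }
      }
    }
  }

  qbar <- numer / denom
  call <- floor(2 * qbar + 0.5)
  fallback <- 0L
  for (k in seq_along(targ)) {
    i <- targ[k]
    na_at <- which(miss0[i, ])
    v <- call[k, na_at]
    nofill <- !is.finite(v)
    v[nofill] <- major[na_at[nofill]]
    fallback <- fallback + sum(nofill)
    X[i, na_at] <- v
  }
  out <- geno_matrix(X, masked$map, masked$sample_ids)
  structure(list(geno = out, imputed_cells = miss0,
                 fraction_imputed = rowMeans(miss0),
                 fallback_cells = fallback),
            class = "imputation_result")
}

#' Two-stage genotype imputation (family step, then population step)
#'
#' Runs [family_impute()] to fill Mendelian-forced genotypes, then
#' [population_impute()] for everything else.
#'
#' @inheritParams population_impute
#' @param pedigree pedigree data.frame for the family step.
#' @return An `imputation_result`; `imputed_cells` marks every cell that
#'   was originally missing (both stages count as imputed).
#' @export
impute_genotypes <- function(masked, pedigree, lib,
                             window = list(size = 50, overlap = 0.5,
                                           min_match = 0.97, floor = 5)) {
  miss0 <- is.na(masked$dosages)
  fam <- family_impute(masked, pedigree)
  res <- population_impute(fam, lib, window)
  res$imputed_cells <- miss0
  res$fraction_imputed <- rowMeans(miss0)
  res
}

#' Imputation accuracy against true genotypes
#'
#' Fraction of imputed genotypes (over the originally masked cells only)
#' whose hard call equals the true genotype.
#'
#' @param imputed a [geno_matrix()] (or `imputation_result`).
#' @param truth the true [geno_matrix()].
#' @param masked_cells logical matrix marking the cells that were imputed.
#' @return list with `overall` accuracy and `per_individual` (named
#'   vector over individuals with at least one masked cell).
#' @export
imputation_accuracy <- function(imputed, truth, masked_cells) {
  if (inherits(imputed, "imputation_result")) {
    if (missing(masked_cells)) masked_cells <- imputed$imputed_cells
    imputed <- imputed$geno
  }
  Xi <- imputed$dosages; Xt <- truth$dosages
  stopifnot(all(dim(Xi) == dim(Xt)), all(dim(Xi) == dim(masked_cells)))
  if (!any(masked_cells)) stop("no masked cells; accuracy undefined")
  ok <- (Xi == Xt) & masked_cells
  rows <- which(rowSums(masked_cells) > 0)
  per_ind <- rowSums(ok[rows, , drop = FALSE]) /
    rowSums(masked_cells[rows, , drop = FALSE])
  names(per_ind) <- imputed$sample_ids[rows]
  list(overall = sum(ok) / sum(masked_cells), per_individual = per_ind)
}
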