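#' Apportion a low-density panel across chromosomes
#'
#' Splits `panel_size` SNPs over chromosomes proportionally to each
#' chromosome's marker content (largest-remainder rounding, ties broken by
#' chromosome order). Every chromosome receives at least one SNP whenever
#' `panel_size >= n_chromosomes`; otherwise single SNPs go to the largest
#' chromosomes first, with a warning.
#'
#' @param map marker map (data.frame with `chr`).
#' @param panel_size total number of SNPs on the panel.
#' @return Named integer vector of per-chromosome counts.
#' @export
allocate_per_chromosome <- function(map, panel_size) {
  if (panel_size > nrow(map)) stop("panel_size exceeds number of markers")
  chrs <- unique(map$chr)
  w <- as.numeric(table(factor(map$chr, levels = chrs)))
  if (panel_size < length(chrs)) {
    warning("panel_size < number of chromosomes; ",
            "allocating to the largest chromosomes only")
    counts <- integer(length(chrs))
    counts[order(-w, seq_along(w))[seq_len(panel_size)]] <- 1L
  } else {
    counts <- largest_remainder(w, panel_size, min_one = TRUE)
  }
  stats::setNames(counts, chrs)
}

#' Select a low-density panel balancing spacing and MAF
#'
#' Splits each chromosome into as many equal-length bins as SNPs allocated
#' to it, and picks within each bin the marker with the highest minor
#' allele frequency (ties broken by proximity to the bin centre, then by
#' lowest marker index). This trades off uniform marker density against
#' high informativeness, the usual design rule for custom low-density
#' genotyping arrays. An empty bin borrows the nearest unselected marker
#' from the adjacent bins, with a warning.
#'
#' @param g a [geno_matrix()] (QC-passing markers).
#' @param freqs allele frequencies (from [allele_frequencies()]); computed
#'   from `g` when `NULL`.
#' @param panel_size number of SNPs.
#' @param name optional label (e.g. "L384").
#' @return Object of class `panel_spec`: list with `name`,
#'   `marker_indices` (sorted, relative to `g`'s map), `per_chromosome`.
#' @export
select_panel <- function(g, panel_size, freqs = NULL, name = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  map <- g$map
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  maf <- pmin(freqs, 1 - freqs)
  counts <- allocate_per_chromosome(map, panel_size)
  sel <- integer(0)
  borrowed <- 0L
  for (cc in names(counts)) {
    k <- counts[[cc]]
    if (k == 0) next
    idx <- which(map$chr == as.integer(cc))
    pos <- map$pos[idx]
    lo <- min(pos); hi <- max(pos) + 1
    brk <- seq(lo, hi, length.out = k + 1)
    bin <- findInterval(pos, brk, rightmost.closed = TRUE)
    centres <- (brk[-1] + brk[-(k + 1)]) / 2
    chosen <- integer(0)
    empty_bins <- integer(0)
    for (b in seq_len(k)) {
      in_bin <- idx[bin == b]
      if (!length(in_bin)) { empty_bins <- c(empty_bins, b); next }
      mafs <- maf[in_bin]
      best <- in_bin[mafs == max(mafs)]
      if (length(best) > 1) {
        d <- abs(map$pos[best] - centres[b])
        best <- best[d == min(d)]
      }
      chosen <- c(chosen, min(best))
    }
    for (b in empty_bins) {            # borrow nearest unselected marker
      avail <- setdiff(idx, chosen)
      if (!length(avail)) next
      chosen <- c(chosen, avail[which.min(abs(map$pos[avail] - centres[b]))])
      borrowed <- borrowed + 1L
    }
    sel <- c(sel, chosen)
  }
  if (borrowed > 0)
    warning(borrowed, " empty bin(s); borrowed nearest unselected markers")
  sel <- sort(unique(sel))
  structure(list(name = if (is.null(name)) paste0("P", panel_size) else name,
                 marker_indices = sel,
                 per_chromosome = table(map$chr[sel])),
            class = "panel_spec")
}

#' Study panel sizes scaled to a synthetic map
#'
#' The five low-density study panels hold 6,177 (6 k), 2,480 (3 k), 1,536
#' (L1536), 768 (L768) and 384 (L384) of the 35,790 QC-passing 50 k SNPs.
#' For a synthetic map of `m` markers the same genome-wide densities are
#' kept by scaling each size by `m / 35790`.
#'
#' @param m number of markers on the (synthetic) full map.
#' @return Named integer vector of panel sizes
#'   (`6k`, `3k`, `L1536`, `L768`, `L384`).
#' @export
panel_preset_sizes <- function(m = 35790) {
  full <- c(`6k` = 6177, `3k` = 2480, L1536 = 1536, L768 = 768, L384 = 384)
  if (m == 35790) return(full)
  out <- pmax(1L, as.integer(round(full * m / 35790)))
  names(out) <- names(full)
  out
}

#' Mask genotypes down to a low-density panel
#'
#' Sets off-panel genotypes to missing for the given individuals; the map
#' keeps full-density coordinates so imputation targets remain defined.
#'
#' @param g a [geno_matrix()].
#' @param panel a `panel_spec`.
#' @param individuals indices or ids of individuals to mask (default all).
#' @param keep_unmasked marker indices never masked (e.g. large-effect
#'   SNPs genotyped directly on an augmented array).
#' @return A [geno_matrix()] of the same shape with off-panel entries
#'   missing for the masked individuals.
#' @export
mask_to_panel <- function(g, panel, individuals = NULL, keep_unmasked = NULL) {
  stopifnot(inherits(g, "geno_matrix"), inherits(panel, "panel_spec"))
  rows <- if (is.null(individuals)) seq_len(nrow(g$dosages))
          else if (is.character(individuals)) match(individuals, g$sample_ids)
          else individuals
  if (anyNA(rows)) stop("unknown individual id(s)")
  off <- setdiff(seq_len(ncol(g$dosages)),
                 union(panel$marker_indices, keep_unmasked))
  X <- g$dosages
  X[rows, off] <- NA
  geno_matrix(X, g$map, g$sample_ids)
}

#' Augment a panel with the largest-effect SNPs
#'
#' Adds (union semantics) the `k` markers with the largest absolute
#' estimated effect to the panel, mirroring the design option of placing a
#' trait's top SNPs directly on a low-density array.
#'
#' @param panel a `panel_spec`.
#' @param effect_estimates per-SNP estimated effects on the full map.
#' @param k number of top SNPs to add (default 2).
#' @return The augmented `panel_spec` (name suffixed `+topk`).
#' @export
augment_with_top_snps <- function(panel, effect_estimates, k = 2) {
  stopifnot(inherits(panel, "panel_spec"))
  if (k < 1) stop("k must be >= 1")
  if (k > length(effect_estimates)) stop("k exceeds number of markers")
  top <- order(-abs(effect_estimates), seq_along(effect_estimates))[seq_len(k)]
  structure(list(name = paste0(panel$name, "+top", k),
                 marker_indices = sort(union(panel$marker_indices, top)),
                 per_chromosome = panel$per_chromosome,
                 top_snps = top),
            class = "panel_spec")
}
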