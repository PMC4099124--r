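#' Genotype matrix container
#'
#' Bundles an individuals-by-markers allele dosage matrix (entries 0, 1, 2
#' or `NA` for missing) with its marker map. Dosages count copies of the
#' "2" allele at each SNP.
#'
#' @param dosages numeric/integer matrix, individuals in rows.
#' @param map data.frame with columns `chr` (integer chromosome), `pos`
#'   (base-pair position, strictly increasing within chromosome), `id`
#'   (marker name) and optionally `morgan` (genetic position in Morgans
#'   within the chromosome).
#' @param sample_ids character vector of individual identifiers.
#' @return An object of class `geno_matrix`: a list with elements
#'   `dosages`, `map`, `sample_ids`.
#' @export
geno_matrix <- function(dosages, map, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(dosages)))
  stopifnot(ncol(dosages) == nrow(map),
            all(c("chr", "pos", "id") %in% names(map)),
            length(sample_ids) == nrow(dosages))
  bad <- dosages[!is.na(dosages) & !(dosages %in% c(0, 1, 2))]
  if (length(bad)) stop("dosages must be 0, 1, 2 or NA")
  for (cc in unique(map$chr)) {
    p <- map$pos[map$chr == cc]
    if (any(diff(p) <= 0))
      stop("map positions must be strictly increasing within chromosome")
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- map$id
  structure(list(dosages = dosages, map = map, sample_ids = sample_ids),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers on %d chromosome(s); %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chr)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Subset a genotype matrix by individuals and/or markers
#'
#' @param g a [geno_matrix()].
#' @param individuals character ids or row indices (`NULL` keeps all).
#' @param markers marker indices (`NULL` keeps all).
#' @return A [geno_matrix()].
#' @export
subset_geno <- function(g, individuals = NULL, markers = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  rows <- if (is.null(individuals)) seq_len(nrow(g$dosages))
          else if (is.character(individuals)) match(individuals, g$sample_ids)
          else individuals
  if (anyNA(rows)) stop("unknown individual id(s)")
  cols <- if (is.null(markers)) seq_len(ncol(g$dosages)) else markers
  geno_matrix(g$dosages[rows, cols, drop = FALSE],
              g$map[cols, , drop = FALSE], g$sample_ids[rows])
}

# marker index ranges per chromosome (markers are stored chr-ordered)
chrom_ranges <- function(map) {
  chrs <- unique(map$chr)
  idx <- lapply(chrs, function(cc) range(which(map$chr == cc)))
  data.frame(chr = chrs,
             start = vapply(idx, `[`, 1L, 1),
             end = vapply(idx, `[`, 1L, 2))
}
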