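#' Write genotypes in the ped/map text dialect
#'
#' `<prefix>.map` has four columns (chromosome, marker id, 0, base-pair
#' position); `<prefix>.ped` has one row per individual: id, sire, dam,
#' then one space-separated allele pair per marker coded 1/2 (dosage is
#' the number of "2" alleles; a missing genotype is written "0 0").
#'
#' @param g a [geno_matrix()].
#' @param prefix output path prefix.
#' @param pedigree optional pedigree supplying sire/dam columns
#'   (0 when absent).
#' @return `prefix`, invisibly.
#' @export
write_ped_map <- function(g, prefix, pedigree = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  map <- data.frame(g$map$chr, g$map$id, 0, g$map$pos)
  write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  X <- g$dosages
  a1 <- matrix("0", nrow(X), ncol(X)); a2 <- a1
  a1[!is.na(X) & X >= 1] <- "2"; a1[!is.na(X) & X == 0] <- "1"
  a2[!is.na(X) & X == 2] <- "2"; a2[!is.na(X) & X <= 1] <- "1"
  inter <- matrix("", nrow(X), 2 * ncol(X))
  inter[, seq(1, 2 * ncol(X), 2)] <- a1
  inter[, seq(2, 2 * ncol(X), 2)] <- a2
  sire <- dam <- rep(0, nrow(X))
  if (!is.null(pedigree)) {
    at <- match(g$sample_ids, as.character(pedigree$id))
    sire <- ifelse(is.na(at), 0, pedigree$sire[at])
    dam <- ifelse(is.na(at), 0, pedigree$dam[at])
  }
  out <- cbind(g$sample_ids, sire, dam, inter)
  write.table(out, paste0(prefix, ".ped"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read genotypes from the ped/map text dialect
#'
#' @param prefix path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return list with `geno` (a [geno_matrix()]) and `pedigree`
#'   (data.frame `id`, `sire`, `dam` as read from the ped columns).
#' @export
read_ped_map <- function(prefix) {
  map_raw <- read.table(paste0(prefix, ".map"), colClasses =
                          c("integer", "character", "integer", "numeric"))
  map <- data.frame(chr = map_raw[[1]], pos = map_raw[[4]],
                    id = map_raw[[2]],
                    morgan = local({
                      m <- map_raw[[4]] / 1e8
                      m
                    }))
  ped <- read.table(paste0(prefix, ".ped"), colClasses = "character")
  ids <- ped[[1]]
  al <- as.matrix(ped[, -(1:3), drop = FALSE])
  m <- nrow(map)
  a1 <- al[, seq(1, 2 * m, 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, 2), drop = FALSE]
  dos <- (a1 == "2") + (a2 == "2")
  dos[a1 == "0" | a2 == "0"] <- NA
  g <- geno_matrix(dos, map, sample_ids = ids)
  list(geno = g,
       pedigree = data.frame(id = ids, sire = ped[[2]], dam = ped[[3]],
                             stringsAsFactors = FALSE))
}

#' Write / read phenotype tables (TSV: id, y, reliability, birth_year)
#'
#' @param phenotypes data.frame from [simulate_proofs()].
#' @param path file path.
#' @return `path` invisibly; `read_phenotypes()` returns the data.frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c("character", "numeric", "numeric", "integer"))
}

#' Write / read pedigree tables (CSV: id, sire, dam, birth_year;
#' 0 = unknown)
#'
#' @param pedigree pedigree data.frame.
#' @param path file path.
#' @return `path` invisibly; `read_pedigree()` returns the data.frame.
#' @export
write_pedigree <- function(pedigree, path) {
  cols <- intersect(c("id", "sire", "dam", "birth_year"), names(pedigree))
  write.table(pedigree[, cols], path, quote = FALSE, sep = ",",
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  read.table(path, header = TRUE, sep = ",")
}
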