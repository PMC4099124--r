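#' Simulation configuration
#'
#' Parameters of the synthetic bull population: a neutral forward-in-time
#' burn-in creates linkage disequilibrium, after which founders are drawn
#' and a multi-generation pedigree is gene-dropped. Defaults are a
#' desk-scale rendition of a 50 k-genotyped Holstein bull population:
#' 29 autosomes, ~3,000 markers, ~2,000 pedigreed individuals.
#'
#' @param n_chromosomes number of autosomes.
#' @param chromosome_length_morgans length of each chromosome in Morgans
#'   (scalar, recycled, or vector of length `n_chromosomes`).
#' @param n_markers total number of biallelic SNPs, allocated to
#'   chromosomes proportionally to length (largest-remainder rounding).
#' @param n_founders number of founder individuals drawn after burn-in.
#' @param burn_in_generations random-mating generations used to build LD.
#' @param effective_size burn-in population size (Ne).
#' @param founder_freq initial allele frequency at every marker before
#'   burn-in drift.
#' @param pedigree_generations number of pedigreed generations after the
#'   founders.
#' @param sires_per_generation sires sampled per generation.
#' @param dams_per_generation dams sampled per generation.
#' @param offspring_per_mating offspring per dam.
#' @param seed integer seed; fully determines all simulator output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 29, chromosome_length_morgans = 1,
                       n_markers = 3000, n_founders = 200,
                       burn_in_generations = 200, effective_size = 100,
                       founder_freq = 0.5,
                       pedigree_generations = 4, sires_per_generation = 25,
                       dams_per_generation = 225, offspring_per_mating = 2,
                       seed = 1L) {
  len <- rep_len(chromosome_length_morgans, n_chromosomes)
  counts <- c(n_chromosomes, n_markers, n_founders, effective_size,
              pedigree_generations, sires_per_generation,
              dams_per_generation, offspring_per_mating)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (any(len <= 0)) stop("zero-length chromosome")
  if (burn_in_generations < 0) stop("burn_in_generations must be >= 0")
  if (founder_freq <= 0 || founder_freq >= 1) stop("founder_freq in (0,1)")
  structure(list(n_chromosomes = n_chromosomes,
                 chromosome_length_morgans = len, n_markers = n_markers,
                 n_founders = n_founders,
                 burn_in_generations = burn_in_generations,
                 effective_size = effective_size,
                 founder_freq = founder_freq,
                 pedigree_generations = pedigree_generations,
                 sires_per_generation = sires_per_generation,
                 dams_per_generation = dams_per_generation,
                 offspring_per_mating = offspring_per_mating,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# largest-remainder apportionment of `total` items proportional to weights;
# ties broken by position. Optionally guarantees >= 1 per class.
largest_remainder <- function(weights, total, min_one = FALSE) {
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  if (min_one && any(base == 0) && total >= length(weights)) {
    while (any(base == 0)) {
      give <- which.max(ifelse(base == 0, quota, -Inf))
      take <- which.max(base)
      base[give] <- base[give] + 1
      base[take] <- base[take] - 1
    }
  }
  as.integer(base)
}

# evenly spaced marker map; 1 Morgan ~ 100 Mb of synthetic physical position
build_map <- function(cfg) {
  per_chr <- largest_remainder(cfg$chromosome_length_morgans, cfg$n_markers,
                               min_one = TRUE)
  maps <- lapply(seq_len(cfg$n_chromosomes), function(cc) {
    nc <- per_chr[cc]
    L <- cfg$chromosome_length_morgans[cc]
    morgan <- (seq_len(nc) - 0.5) / nc * L
    data.frame(chr = cc, pos = round(morgan * 1e8),
               id = sprintf("snp%d_%d", cc, seq_len(nc)), morgan = morgan)
  })
  do.call(rbind, maps)
}

#' Simulate founder haplotypes with linkage disequilibrium
#'
#' Initialises a random-mating population of `effective_size` individuals
#' whose alleles are drawn at frequency `founder_freq`, runs
#' `burn_in_generations` of random mating with Haldane recombination
#' (crossovers ~ Poisson(chromosome length in Morgans)), and then draws
#' `n_founders` offspring as the founder pool. Drift during burn-in
#' spreads allele frequencies over (0,1) and builds LD that decays with
#' map distance.
#'
#' @param cfg a [sim_config()].
#' @param seed seed to set before simulating; `NULL` leaves the RNG state
#'   untouched (used when a caller manages seeding).
#' @return Object of class `founder_pool`: list with `haps` (a
#'   `2 * n_founders` x m 0/1 matrix, rows 2i-1 and 2i forming individual
#'   i's haplotype pair) and `map`.
#' @export
simulate_founder_haplotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  map <- build_map(cfg)
  rng <- chrom_ranges(map)
  ne <- cfg$effective_size
  m <- nrow(map)
  H <- matrix(as.integer(runif(2 * ne * m) < cfg$founder_freq), nrow = 2 * ne)
  for (g in seq_len(cfg$burn_in_generations)) {
    H <- next_generation(H, ne, rng, map)
  }
  pool <- next_generation(H, cfg$n_founders, rng, map)
  structure(list(haps = pool, map = map, cfg = cfg), class = "founder_pool")
}

# one round of random mating: n offspring, two distinct parents each
next_generation <- function(H, n, rng, map) {
  np <- nrow(H) / 2
  p1 <- sample.int(np, n, replace = TRUE)
  shift <- sample.int(np - 1, n, replace = TRUE)
  p2 <- 1 + (p1 - 1 + shift) %% np       # distinct from p1
  row_a <- as.integer(rbind(2 * p1 - 1, 2 * p2 - 1))
  row_b <- as.integer(rbind(2 * p1, 2 * p2))
  cpp_make_gametes(H, row_a, row_b, rng$start, rng$end, map$morgan,
                   attr_chr_len(map, rng))
}

attr_chr_len <- function(map, rng) {
  vapply(seq_len(nrow(rng)), function(i) {
    mm <- map$morgan[rng$start[i]:rng$end[i]]
    # chromosome length implied by the evenly spaced map
    max(mm) + min(mm)
  }, numeric(1))
}

#' Simulate a multi-generation breeding pedigree
#'
#' Discrete generations: each generation samples
#' `sires_per_generation` sires and `dams_per_generation` dams from the
#' previous generation and produces `offspring_per_mating` offspring per
#' dam. Founders have unknown parents (coded 0). Birth year increments by
#' one per generation.
#'
#' @param cfg a [sim_config()].
#' @param base_year birth year of the founder generation.
#' @param seed seed (`NULL` to leave RNG state untouched).
#' @return data.frame with columns `id`, `sire`, `dam`, `birth_year`,
#'   `sex`, sorted so parents precede offspring.
#' @export
simulate_pedigree <- function(cfg, base_year = 2000, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  nf <- cfg$n_founders
  ped <- data.frame(id = seq_len(nf), sire = 0L, dam = 0L,
                    birth_year = base_year,
                    sex = rep_len(c("M", "F"), nf))
  prev <- ped
  next_id <- nf + 1L
  for (g in seq_len(cfg$pedigree_generations)) {
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    sires <- sample(males, min(cfg$sires_per_generation, length(males)))
    dams <- sample(females, min(cfg$dams_per_generation, length(females)))
    n_off <- length(dams) * cfg$offspring_per_mating
    off <- data.frame(
      id = seq.int(next_id, length.out = n_off),
      sire = rep(sample(sires, length(dams), replace = TRUE),
                 each = cfg$offspring_per_mating),
      dam = rep(dams, each = cfg$offspring_per_mating),
      birth_year = base_year + g,
      sex = rep_len(c("M", "F"), n_off))
    next_id <- next_id + n_off
    ped <- rbind(ped, off)
    prev <- off
  }
  ped
}

#' Drop founder genomes through a pedigree
#'
#' Each non-founder receives one recombinant gamete from each parent
#' (Haldane map); genotype dosage is the sum of the two gametes' alleles,
#' so Mendelian consistency holds by construction. An unknown parent
#' (coded 0) contributes a gamete recombined from a randomly drawn founder
#' pool individual, which keeps allele frequencies stationary.
#'
#' @param pedigree data.frame (`id`, `sire`, `dam`, ...) with parents
#'   appearing before their offspring; 0 = unknown parent.
#' @param founders a `founder_pool` from [simulate_founder_haplotypes()].
#' @param seed seed (`NULL` to leave RNG state untouched).
#' @return Object of class `gene_drop`: list with `geno` (a
#'   [geno_matrix()]), `haps` (2n x m phased 0/1 matrix; rows 2i-1/2i are
#'   individual i's paternal/maternal haplotypes) and `pedigree`.
#' @export
gene_drop <- function(pedigree, founders, seed = NULL) {
  stopifnot(inherits(founders, "founder_pool"))
  if (!is.null(seed)) set.seed(seed)
  map <- founders$map
  rng <- chrom_ranges(map)
  chr_len <- attr_chr_len(map, rng)
  n <- nrow(pedigree)
  m <- nrow(map)
  ids <- as.character(pedigree$id)
  pos <- match(ids, ids)                  # identity; position lookup below
  posof <- stats::setNames(seq_len(n), ids)
  sire_pos <- ifelse(pedigree$sire == 0, NA_integer_,
                     posof[as.character(pedigree$sire)])
  dam_pos <- ifelse(pedigree$dam == 0, NA_integer_,
                    posof[as.character(pedigree$dam)])
  if (any(!is.na(sire_pos) & sire_pos >= seq_len(n)) ||
      any(!is.na(dam_pos) & dam_pos >= seq_len(n)))
    stop("pedigree must list parents before their offspring")

  # generation level for batched gamete dropping
  level <- integer(n)
  for (i in seq_len(n)) {
    lv <- 0L
    if (!is.na(sire_pos[i])) lv <- max(lv, level[sire_pos[i]] + 1L)
    if (!is.na(dam_pos[i])) lv <- max(lv, level[dam_pos[i]] + 1L)
    level[i] <- lv
  }

  npool <- nrow(founders$haps) / 2
  big <- matrix(0L, nrow = 2 * npool + 2 * n, ncol = m)
  big[seq_len(2 * npool), ] <- founders$haps
  off <- 2 * npool                       # row offset of pedigree individuals

  # the first `npool` parentless individuals receive founder-pool
  # haplotype pairs; any later parentless individual (an orphan inserted
  # into a deeper generation) draws two independent recombined gametes
  # from random pool individuals, like any unknown parent
  parentless <- which(is.na(sire_pos) & is.na(dam_pos))
  is_founder <- rep(FALSE, n)
  is_founder[parentless[seq_len(min(npool, length(parentless)))]] <- TRUE
  fidx <- which(is_founder)
  level[!is_founder & level == 0L] <- 1L   # orphans are dropped like kin
  for (k in seq_along(fidx)) {
    i <- fidx[k]
    big[off + 2 * i - 1, ] <- founders$haps[2 * k - 1, ]
    big[off + 2 * i, ] <- founders$haps[2 * k, ]
  }

  parent_rows <- function(ppos, i) {
    if (!is.na(ppos)) {
      c(off + 2 * ppos - 1, off + 2 * ppos)
    } else {                             # unknown parent: founder-pool gamete
      f <- sample.int(npool, 1)
      c(2 * f - 1, 2 * f)
    }
  }
  for (lv in sort(unique(level[level > 0]))) {
    idx <- which(level == lv & !is_founder)
    ra <- integer(2 * length(idx)); rb <- integer(2 * length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      pr <- parent_rows(sire_pos[i], i)
      mr <- parent_rows(dam_pos[i], i)
      ra[2 * k - 1] <- pr[1]; rb[2 * k - 1] <- pr[2]
      ra[2 * k] <- mr[1]; rb[2 * k] <- mr[2]
    }
    gam <- cpp_make_gametes(big, ra, rb, rng$start, rng$end, map$morgan,
                            chr_len)
    for (k in seq_along(idx)) {
      i <- idx[k]
      big[off + 2 * i - 1, ] <- gam[2 * k - 1, ]
      big[off + 2 * i, ] <- gam[2 * k, ]
    }
  }

  haps <- big[off + seq_len(2 * n), , drop = FALSE]
  dos <- haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
    haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  g <- geno_matrix(dos, map, sample_ids = ids)
  structure(list(geno = g, haps = haps, pedigree = pedigree),
            class = "gene_drop")
}

#' Build a quantitative trait architecture on simulated genotypes
#'
#' Samples `n_qtl` QTL among segregating markers, draws additive
#' substitution effects and rescales them so the realized variance of the
#' true breeding values equals `sigma2_a`. True breeding value of
#' individual i is the sum over QTL of dosage times effect.
#'
#' @param arch_spec list with `n_qtl`, `effect_distribution` ("gaussian",
#'   "gamma" — shape-0.4 magnitudes with random sign, giving a few
#'   dominant QTL — or "equal" — unit magnitudes with random sign, every
#'   QTL detectable), `sigma2_a` (additive genetic variance) and
#'   `sigma2_E` (environmental variance).
#' @param genotypes a [geno_matrix()] (no missing entries).
#' @param seed seed (`NULL` to leave RNG state untouched).
#' @return list with `architecture` (class `trait_architecture`: QTL
#'   indices, rescaled effects, variance components, heritability) and
#'   `tbv` (named vector of true breeding values).
#' @export
build_trait <- function(arch_spec, genotypes, seed = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (!is.null(seed)) set.seed(seed)
  X <- genotypes$dosages
  if (anyNA(X)) stop("genotypes must be complete")
  p <- colMeans(X) / 2
  seg <- which(p > 0 & p < 1)
  nq <- arch_spec$n_qtl
  if (nq > length(seg)) stop("n_qtl exceeds number of segregating markers")
  if (arch_spec$sigma2_a <= 0 || arch_spec$sigma2_E <= 0)
    stop("variance components must be > 0")
  qtl <- sort(sample(seg, nq))
  dist <- if (is.null(arch_spec$effect_distribution)) "gaussian"
          else arch_spec$effect_distribution
  a <- switch(dist,
              gaussian = rnorm(nq),
              gamma = stats::rgamma(nq, shape = 0.4) *
                sample(c(-1, 1), nq, replace = TRUE),
              equal = sample(c(-1, 1), nq, replace = TRUE),
              stop("unknown effect_distribution"))
  tbv <- drop(X[, qtl, drop = FALSE] %*% a)
  v <- var(tbv)
  if (!is.finite(v) || v <= 0)
    stop("TBV variance is zero; cannot rescale to sigma2_a")
  sc <- sqrt(arch_spec$sigma2_a / v)
  a <- a * sc
  tbv <- tbv * sc
  names(tbv) <- genotypes$sample_ids
  arch <- structure(list(qtl_indices = qtl, qtl_effects = a,
                         sigma2_a = arch_spec$sigma2_a,
                         sigma2_E = arch_spec$sigma2_E,
                         heritability = arch_spec$sigma2_a /
                           (arch_spec$sigma2_a + arch_spec$sigma2_E)),
                    class = "trait_architecture")
  list(architecture = arch, tbv = tbv)
}

#' Simulate pseudo de-regressed proofs with reliability-controlled noise
#'
#' Generates phenotypes `y_i = TBV_i + eps_i` with
#' `eps_i ~ N(0, sigma2_a (1 - r2_i) / r2_i)`, so that the squared
#' correlation between proof and true breeding value at reliability `r2`
#' tends to `r2` — the defining property of a de-regressed proof's
#' reliability.
#'
#' @param tbv named vector of true breeding values.
#' @param reliabilities per-animal reliability r-squared in (0, 1].
#' @param arch a `trait_architecture` (supplies `sigma2_a`).
#' @param birth_year optional per-animal birth year.
#' @param seed seed (`NULL` to leave RNG state untouched).
#' @return data.frame with `individual_id`, `y`, `reliability`,
#'   `birth_year`.
#' @export
simulate_proofs <- function(tbv, reliabilities, arch, birth_year = NA,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r2 <- rep_len(reliabilities, length(tbv))
  if (any(r2 <= 0 | r2 > 1)) stop("reliabilities must be in (0, 1]")
  noise_sd <- sqrt(arch$sigma2_a * (1 - r2) / r2)
  y <- tbv + rnorm(length(tbv), 0, noise_sd)
  data.frame(individual_id = names(tbv), y = y, reliability = r2,
             birth_year = rep_len(birth_year, length(tbv)),
             row.names = NULL)
}
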