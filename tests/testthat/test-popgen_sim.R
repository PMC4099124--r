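test_that("founder allele frequencies start at the configured value", {
  cfg <- sim_config(n_chromosomes = 1, n_markers = 100, n_founders = 50,
                    burn_in_generations = 0, effective_size = 50,
                    founder_freq = 0.5, seed = 11)
  pool <- simulate_founder_haplotypes(cfg)
  expect_equal(dim(pool$haps), c(100, 100))
  expect_lt(abs(mean(pool$haps) - 0.5), 0.05)
})

test_that("burn-in builds LD that decays with marker distance", {
  cfg <- sim_config(n_chromosomes = 1, n_markers = 200, n_founders = 100,
                    burn_in_generations = 200, effective_size = 100,
                    seed = 12)
  gd <- founders_geno(cfg)
  X <- gd$geno$dosages
  p <- colMeans(X) / 2
  seg <- p > 0.05 & p < 0.95
  r2_at <- function(lag) {
    i <- which(seg[seq_len(200 - lag)] & seg[(1 + lag):200])
    mean(mapply(function(a, b) cor(X[, a], X[, b])^2, i, i + lag))
  }
  expect_gt(r2_at(1), r2_at(10))
  # drift has spread the allele frequencies away from 0.5
  expect_gt(sd(p), 0.1)
})

test_that("simulation is fully determined by the seed", {
  cfg <- sim_config(n_chromosomes = 2, n_markers = 120, n_founders = 40,
                    burn_in_generations = 30, effective_size = 40,
                    pedigree_generations = 2, sires_per_generation = 6,
                    dams_per_generation = 15, offspring_per_mating = 2,
                    seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$geno$dosages, s2$geno$dosages)
  expect_identical(s1$traits$sparse$tbv, s2$traits$sparse$tbv)
  expect_identical(s1$traits$sparse$phenotypes$y,
                   s2$traits$sparse$phenotypes$y)
})

test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(chromosome_length_morgans = 0), "zero-length")
  expect_error(sim_config(n_markers = 0), "counts")
})

test_that("gene dropping is Mendelian-consistent and forces homozygotes", {
  st <- fixture_study()
  expect_identical(mendelian_conflicts(st$geno, st$pedigree), 0L)

  # both parents homozygous 0 everywhere -> offspring all 0
  haps <- matrix(0L, 4, 20)
  ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2),
                    birth_year = c(1, 1, 2))
  gd <- gene_drop(ped, toy_founders(haps), seed = 5)
  expect_true(all(gd$geno$dosages[3, ] == 0))
})

test_that("crossover counts match the Haldane expectation", {
  # one fully heterozygous parent pair on a 1-Morgan chromosome: the
  # observed switch count per gamete estimates Poisson(1) crossovers
  haps <- rbind(rep(1L, 100), rep(0L, 100), rep(1L, 100), rep(0L, 100))
  n_off <- 2500
  ped <- data.frame(id = seq_len(n_off + 2),
                    sire = c(0, 0, rep(1, n_off)),
                    dam = c(0, 0, rep(2, n_off)),
                    birth_year = c(1, 1, rep(2, n_off)))
  gd <- gene_drop(ped, toy_founders(haps, L = 1), seed = 6)
  gametes <- gd$haps[-(1:4), , drop = FALSE]   # offspring haplotypes
  switches <- apply(gametes, 1, function(h) sum(diff(h) != 0))
  # markers span [0.005, 0.995] Morgans so ~99% of crossovers are visible
  se <- sqrt(1 / length(switches))
  expect_lt(abs(mean(switches) - 0.99), 3 * se)
})

test_that("unknown parents draw gametes from the founder pool", {
  st <- fixture_study()
  ped <- st$pedigree
  ped$dam[nrow(ped)] <- 0L          # orphan one animal's dam
  pool <- simulate_founder_haplotypes(st$cfg, seed = st$cfg$seed)
  gd <- gene_drop(ped, pool, seed = 3)
  expect_false(anyNA(gd$geno$dosages))
  expect_identical(mendelian_conflicts(gd$geno, ped), 0L)
})

test_that("trait building rescales variance and ranks QTL shares", {
  st <- fixture_study()
  g <- st$geno
  tr5 <- build_trait(list(n_qtl = 5, sigma2_a = 1, sigma2_E = 1), g,
                     seed = 21)
  tr500 <- build_trait(list(n_qtl = 200, sigma2_a = 1, sigma2_E = 1), g,
                       seed = 21)
  expect_true(abs(var(tr5$tbv) / 1 - 1) < 0.01)
  expect_true(abs(var(tr500$tbv) / 1 - 1) < 0.01)
  share <- function(tr) {
    p <- allele_frequencies(g)[tr$architecture$qtl_indices]
    v <- 2 * p * (1 - p) * tr$architecture$qtl_effects^2
    max(v) / sum(v)
  }
  expect_gt(share(tr5), share(tr500))

  # degenerate: a monomorphic-looking trait cannot be rescaled
  gmono <- toy_geno(matrix(2, 4, 10))
  expect_error(build_trait(list(n_qtl = 1, sigma2_a = 1, sigma2_E = 1),
                           gmono), "segregating")
})

test_that("proof generation calibrates to the requested reliability", {
  arch <- structure(list(sigma2_a = 1, sigma2_E = 1),
                    class = "trait_architecture")
  tbv <- stats::setNames(rnorm(5000), paste0("a", 1:5000))
  ph <- simulate_proofs(tbv, 1, arch, seed = 31)
  expect_equal(ph$y, unname(tbv))

  ph8 <- simulate_proofs(tbv, 0.8, arch, seed = 32)
  expect_lt(abs(cor(ph8$y, tbv)^2 - 0.8), 0.02)
  eps <- ph8$y - tbv
  expect_lt(abs(var(eps) / (1 * 0.2 / 0.8) - 1), 0.1)

  expect_error(simulate_proofs(tbv, 0, arch), "reliabilities")
})
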