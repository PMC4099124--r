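test_that("family imputation fills only Mendelian-forced genotypes", {
  X <- rbind(sire1 = c(0, 2, 1, 0),
             dam1  = c(0, 0, 1, 2),
             kid1  = c(NA, NA, NA, NA))
  g <- toy_geno(X)
  ped <- data.frame(id = c("sire1", "dam1", "kid1"),
                    sire = c(0, 0, "sire1"), dam = c(0, 0, "dam1"))
  out <- family_impute(g, ped)
  expect_equal(unname(out$dosages["kid1", ]), c(0, 1, NA, 1))
  expect_identical(attr(out, "conflicts"), 0L)
})

test_that("family imputation logs Mendelian conflicts and leaves them", {
  X <- rbind(s = c(0, 0), d = c(0, 0), k = c(2, NA))
  ped <- data.frame(id = c("s", "d", "k"), sire = c(0, 0, "s"),
                    dam = c(0, 0, "d"))
  out <- family_impute(toy_geno(X), ped)
  expect_identical(attr(out, "conflicts"), 2L)   # one per offending parent
  expect_equal(unname(out$dosages["k", ]), c(2, 0))
})

test_that("trio logic pins the phase of a heterozygous child", {
  X <- rbind(s = c(0, 0, 0), d = c(2, 2, 2), k = c(1, 1, 1))
  ped <- data.frame(id = c("s", "d", "k"), sire = c(0, 0, "s"),
                    dam = c(0, 0, "d"))
  lib <- build_library(toy_geno(X), ped)
  expect_equal(lib$haps[5, ], c(0L, 0L, 0L))   # paternal from sire
  expect_equal(lib$haps[6, ], c(1L, 1L, 1L))   # maternal from dam
})

test_that("homozygous-only genotypes self-phase", {
  X <- rbind(a = c(0, 2, 0, 2), b = c(2, 2, 0, 0))
  ped <- data.frame(id = c("a", "b"), sire = 0, dam = 0)
  lib <- build_library(toy_geno(X), ped)
  expect_equal(lib$haps[1, ], lib$haps[2, ])
  expect_equal(lib$haps[1, ], c(0L, 1L, 0L, 1L))
})

test_that("phasing achieves a low switch-error rate on pedigree data", {
  cfg <- sim_config(n_chromosomes = 1, n_markers = 200, n_founders = 100,
                    burn_in_generations = 100, effective_size = 80,
                    pedigree_generations = 2, sires_per_generation = 12,
                    dams_per_generation = 100, offspring_per_mating = 2,
                    seed = 61)
  set.seed(61)
  pool <- simulate_founder_haplotypes(cfg, seed = NULL)
  ped <- simulate_pedigree(cfg, seed = NULL)
  gd <- gene_drop(ped, pool, seed = NULL)     # ~500 individuals
  lib <- build_library(gd$geno, ped)
  ser <- switch_error_rate(lib$haps, gd$haps)
  expect_lt(ser, 0.05)
})

test_that("a unique compatible haplotype is copied exactly", {
  h1 <- c(0L, 1L, 0L, 1L, 0L, 1L)
  h2 <- c(1L, 0L, 1L, 0L, 1L, 0L)
  ref <- rbind(a = h1 + h1, b = h2 + h2, c = h1 + h1, d = h2 + h2)
  ped <- data.frame(id = rownames(ref), sire = 0, dam = 0)
  lib <- build_library(toy_geno(ref), ped)
  target <- toy_geno(rbind(t = c(0, NA, NA, 2, NA, 2)))
  res <- population_impute(target, lib,
                           window = list(size = 6, overlap = 0.5,
                                         min_match = 0.97, floor = 2))
  expect_equal(unname(res$geno$dosages[1, ]), 2 * h1)
  expect_equal(res$fallback_cells, 0L)
})

test_that("incompatible targets fall back to the major genotype", {
  ref <- matrix(0, 6, 8)                      # all-zero reference
  rownames(ref) <- paste0("r", 1:6)
  ped <- data.frame(id = rownames(ref), sire = 0, dam = 0)
  lib <- build_library(toy_geno(ref), ped)
  target <- toy_geno(rbind(t = c(2, 2, NA, NA, 2, 2, NA, 2)))
  res <- population_impute(target, lib,
                           window = list(size = 8, overlap = 0.5,
                                         min_match = 0.97, floor = 2))
  expect_equal(unname(res$geno$dosages[1, c(3, 4, 7)]), c(0, 0, 0))
  expect_gt(res$fallback_cells, 0)
  # observed entries are never altered
  expect_equal(unname(res$geno$dosages[1, c(1, 2, 5, 6, 8)]),
               c(2, 2, 2, 2, 2))
})

test_that("accuracy is the fraction of masked cells called correctly", {
  truth <- toy_geno(matrix(rep(c(0, 1, 2), length.out = 10), 1))
  imp <- truth
  mask <- matrix(TRUE, 1, 10)
  expect_equal(imputation_accuracy(imp, truth, mask)$overall, 1)
  imp2 <- truth
  imp2$dosages[1, 5] <- 0     # a heterozygous truth cell, miscalled
  expect_equal(imputation_accuracy(imp2, truth, mask)$overall, 0.9)
  expect_error(imputation_accuracy(imp, truth, matrix(FALSE, 1, 10)),
               "no masked cells")
})

test_that("random filling matches its theoretical concordance", {
  set.seed(62)
  n <- 20000
  truth <- toy_geno(matrix(sample(0:2, n, TRUE, c(.25, .5, .25)), 1))
  imp <- truth
  imp$dosages[1, ] <- sample(0:2, n, TRUE, c(.25, .5, .25))
  acc <- imputation_accuracy(imp, truth, matrix(TRUE, 1, n))$overall
  # sum of squared genotype frequencies = 0.375
  expect_lt(abs(acc - 0.375), 0.015)
})

test_that("two-stage imputation beats the major-genotype baseline", {
  st <- fixture_study()
  sizes <- panel_preset_sizes(ncol(st$geno$dosages))
  pan <- select_panel(st$geno, sizes[["L768"]])
  sc <- scenario("S1")
  imp <- gpimpute:::impute_for_scenario(st, sc, pan, seed = 63)
  # baseline: fill every masked cell with the per-marker major genotype
  asg <- gpimpute:::scenario_assignment(st, sc, 63)
  masked <- mask_to_panel(st$geno, pan, individuals = asg$low_ids)
  mc <- is.na(masked$dosages)
  X <- st$geno$dosages
  majors <- apply(X, 2, function(col) which.max(tabulate(col + 1L, 3L)) - 1L)
  Xb <- masked$dosages
  idx <- which(is.na(Xb), arr.ind = TRUE)
  Xb[idx] <- majors[idx[, 2]]
  base_acc <- sum(Xb == X & mc) / sum(mc)
  expect_gt(imp$imputation_accuracy, base_acc)
  # population imputation never alters an observed genotype
  expect_equal(imp$geno$dosages[!mc], X[!mc])
})
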