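# Shared simulated populations, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

# small multi-generation study population (3 chromosomes, ~360 markers)
fixture_study <- function() {
  if (is.null(.fx$study)) {
    cfg <- sim_config(n_chromosomes = 3, chromosome_length_morgans = 1,
                      n_markers = 400, n_founders = 80,
                      burn_in_generations = 100, effective_size = 80,
                      pedigree_generations = 3, sires_per_generation = 10,
                      dams_per_generation = 60, offspring_per_mating = 2,
                      seed = 101)
    .fx$study <- simulate_study(cfg)
  }
  .fx$study
}

# hand-built genotype matrix on a trivial map
toy_geno <- function(dosages, chr = 1) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  map <- data.frame(chr = chr, pos = seq_len(m) * 1000,
                    id = paste0("m", seq_len(m)),
                    morgan = seq_len(m) / m)
  geno_matrix(dosages, map)
}

# founder pool with haplotypes fixed by hand (one chromosome)
toy_founders <- function(haps, L = 1) {
  m <- ncol(haps)
  map <- data.frame(chr = 1L, pos = round((seq_len(m) - 0.5) / m * L * 1e8),
                    id = paste0("m", seq_len(m)),
                    morgan = (seq_len(m) - 0.5) / m * L)
  structure(list(haps = haps, map = map, cfg = NULL), class = "founder_pool")
}

# genotypes without pedigree structure: founder pool drawn straight from
# the burn-in population
founders_geno <- function(cfg) {
  pool <- simulate_founder_haplotypes(cfg, seed = NULL)
  n <- nrow(pool$haps) / 2
  ped <- data.frame(id = seq_len(n), sire = 0L, dam = 0L,
                    birth_year = 2000L)
  gene_drop(ped, pool, seed = NULL)
}
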