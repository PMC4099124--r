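# gpimpute

Genomic prediction with imputed low-density SNP genotypes — a simulation
and evaluation toolkit for the dairy-cattle setting where older,
progeny-tested bulls are genotyped at ~50 k SNPs, young candidates are
genotyped on cheap low-density panels (384–6,177 SNPs), and candidate
genotypes are imputed up to the full map before prediction. The package
is for quantitative geneticists and breeding-program analysts who want
to quantify how imputation errors degrade different prediction methods,
and how panel design (density, large-effect SNP content) mitigates the
loss.

## What it implements

* **Population simulation** — forward-in-time burn-in (Ne = 100, Haldane
  recombination) creating LD and a drifted allele-frequency spectrum; a
  multi-generation bull pedigree gene-dropped from the founders; trait
  architectures from "few large QTL" to polygenic with true breeding
  values rescaled to σ²ₐ; pseudo de-regressed proofs
  `y = TBV + ε`, `Var(ε) = σ²ₐ(1−r²)/r²` controlled by per-animal
  reliability r².
* **Marker QC** — MAF < 0.05, missing rate > 15 %, 1-df chi-square
  Hardy–Weinberg disequilibrium test at p < 1e-4, applied jointly.
* **Panel design** — per-chromosome allocation proportional to marker
  content, equal-length bins, max-MAF marker per bin (spacing/MAF
  compromise); presets scaled from the 6 k / 3 k / L1536 / L768 / L384
  panel sizes; masking; top-SNP augmentation.
* **Imputation** — a two-stage algorithm: Mendelian family imputation,
  then sliding-window haplotype matching against a reference library
  phased by trio logic plus iterative candidate matching. Accuracy =
  fraction of masked genotypes called correctly.
* **GBLUP** — VanRaden method-1 genomic relationship matrix
  `G = (M−P)(M−P)′ / (2Σp(1−p))`; mixed-model prediction of validation
  DGV; EM-REML variance components; an independent ridge-SNP-BLUP route
  kept as an algebraic cross-check.
* **Bayesian mixture model** — spike-and-slab prior
  `β_j ~ π N(0, τσ²_β) + (1−π) N(0, σ²_β)` with τ = 1e-4,
  Uniform(0,1) prior on π, scaled-inverse-χ² priors on σ²_β (v = 4) and
  σ²_e (v = 10) with scales derived from `E[X] = vS²/(v−2)`, Gibbs
  sampling (compiled sampler, seed-deterministic), and
  `DGV_i = Σ_j x_ij β̄_j`.
* **Scenario evaluation** — S0 (all full density), S1 (validation on the
  panel), S2/S3 (33 % / 66 % of training also on the panel, imputation
  reference shrunk correspondingly); Pearson DGV accuracy; accuracy
  tables; the two-largest-effect-SNP augmentation experiment.

## Worked example

```r
library(gpimpute)

cfg <- sim_config(n_chromosomes = 10, n_markers = 1000, n_founders = 150,
                  burn_in_generations = 200, effective_size = 100,
                  pedigree_generations = 3, sires_per_generation = 20,
                  dams_per_generation = 75, offspring_per_mating = 2,
                  seed = 1)
study <- simulate_study(cfg)   # QC'd genotypes, 2 traits, design split
study
#> gp_study: 600 animals x 489 markers; training 218 / validation 150 / reference 232

sizes <- panel_preset_sizes(ncol(study$geno$dosages))
panels <- list(`6k` = select_panel(study$geno, sizes[["6k"]], name = "6k"),
               L384 = select_panel(study$geno, sizes[["L384"]],
                                   name = "L384"))

res <- rbind(
  run_scenario(study, scenario("S0"), panels$`6k`, "sparse", "gblup",
               seed = 1),
  run_scenario(study, scenario("S0"), panels$`6k`, "sparse", "bayes",
               seed = 1),
  run_scenario_grid(study, scenarios = "S1", panels = panels,
                    traits = "sparse", seed = 1))
res[, c("scenario", "panel", "method", "imputation_accuracy",
        "dgv_accuracy", "pi_mean")]
#>   scenario panel method imputation_accuracy dgv_accuracy   pi_mean
#> 1       S0    6k  gblup                  NA    0.8007963        NA
#> 2       S0    6k  bayes                  NA    0.9986200 0.9843402
#> 3       S1    6k  gblup           0.7702716    0.6271690        NA
#> 4       S1    6k  bayes           0.7702716    0.6590089 0.9842553
#> 5       S1  L384  gblup           0.7102342    0.5301943        NA
#> 6       S1  L384  bayes           0.7102342    0.5484182 0.9842437
```

Reading the output: the `sparse` trait has 5 QTL, and the Bayesian
model's posterior π ≈ 0.98 correctly reports that almost all SNPs carry
no effect. At full density (S0) the Bayesian model far outperforms
GBLUP on this architecture (0.999 vs 0.801 correlation with true
breeding values). Once validation animals are genotyped on a low-density
panel and imputed (S1), imputation accuracy drops with panel density
(0.77 at 6 k-equivalent, 0.71 at L384-equivalent density) and both
methods lose accuracy — the Bayesian model loses *more* of its
advantage because its few selected SNPs are exactly the ones whose
imputed genotypes carry errors. `report_tables(res)` formats such grids
as "GBLUP (Bayesian)" matrices, and `top_snp_experiment()` shows how
much of the loss is recovered by genotyping the two largest-effect SNPs
directly on the panel.

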