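Package: gpimpute
Title: Genomic Prediction with Imputed Low-Density SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and evaluation toolkit for studying how genotype
    imputation errors affect genomic prediction in dairy cattle breeding
    schemes. Simulates multi-generation bull populations with linkage
    disequilibrium, quantitative trait architectures and
    reliability-controlled pseudo de-regressed proofs; designs low-density
    SNP panels that compromise between uniform spacing and high minor
    allele frequency; imputes masked genotypes back to the full map with a
    family step followed by sliding-window haplotype matching; and predicts
    direct genomic values with GBLUP (VanRaden genomic relationship matrix)
    and a spike-and-slab mixture-prior Bayesian regression fitted by Gibbs
    sampling. Scenario orchestration reproduces training/validation splits,
    panel sweeps and reference-population shrinkage designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
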