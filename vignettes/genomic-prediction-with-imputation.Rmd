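---
title: "Genomic prediction with imputed low-density genotypes: models and design"
author: "gpimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with imputed low-density genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package addresses

Dairy-cattle genomic selection trains a prediction equation on older,
progeny-tested bulls genotyped at ~50,000 SNPs and applies it to young
candidates. Genotyping every candidate at full density is expensive, so
candidates are typed on cheap low-density panels (384 to ~6,000 SNPs) and
their genotypes are *imputed* up to the full map before prediction.
Imputation makes errors, and the two workhorse prediction methods react
to those errors differently: GBLUP spreads signal over thousands of
small SNP effects, while Bayesian variable-selection models concentrate
it on a few large ones. `gpimpute` provides a self-contained simulation
and analysis pipeline to quantify that interaction: population
simulation, marker QC, panel design, two-stage imputation, GBLUP and a
spike-and-slab Bayesian regression, and the scenario bookkeeping that
ties them together.

# Models

## Phenotypes

The unit of analysis is a pseudo-phenotype in the style of a de-regressed
bull proof: `y_i = TBV_i + eps_i` with
`Var(eps_i) = sigma2_a (1 - r2_i) / r2_i`, where `r2_i` is the proof's
reliability. This makes `cor(y, TBV)^2 -> r2` by construction, which is
the operational meaning of reliability. Training animals have
`r2 ~ Uniform(0.80, 0.99)` (the usual 0.80 admission cut-off), animals
below the cut-off serve only as imputation reference, and validation
animals get `r2 = 0.99` so that their proofs are a near-noiseless
stand-in for later progeny-test results. Property tests correlate DGV
with the noise-free TBV directly (the default, switchable to proofs) to
keep Monte-Carlo noise out of method comparisons.

## GBLUP

`y = 1 mu + g + e`, `g ~ N(0, G sigma2_a)`, `e ~ N(0, I sigma2_E)` with
the VanRaden method-1 genomic relationship matrix
`G = (M - P)(M - P)' / (2 sum_j p_j (1 - p_j))`, centering by observed
frequencies in the combined genotyped set. Validation DGV is the
conditional mean `sigma2_a G_vt V_tt^{-1} (y - mu)`; the joint
mixed-model-equations route is implemented too and tested equal. GBLUP
is algebraically identical to ridge regression on SNPs with common
per-SNP variance `sigma2_a / (2 sum p(1-p))`; the package keeps an
independent `fit_snp_ridge()` implementation purely as a cross-check,
and the equivalence (max absolute DGV difference < 1e-6) is asserted in
the test suite. Residual variance is homogeneous — with a 0.80
reliability cut-off the per-animal noise variances differ little, so no
reliability weighting is applied. Variance components default to
plug-in simulator truth (with the residual implied by the training
reliabilities); an EM-REML estimator for the GRM animal model is
provided to mirror the usual preliminary REML step.

## Spike-and-slab Bayesian regression

`y_i = mu + sum_j x_ij beta_j + e_i` with the mixture prior

    beta_j ~ pi N(0, tau sigma2_beta) + (1 - pi) N(0, sigma2_beta)

The weight `pi` sits on the near-zero **spike**: a large posterior `pi`
means most SNPs carry (effectively) no effect, i.e. few large QTL. The
sentence-level sources on which this model is based are ambiguous about
which component carries `pi`; the results-level reading (large `pi` for
sparse traits) fixes the orientation, and a flag (`pi_on_spike`) keeps
the other convention available. `tau = 1e-4` *relative* to the shared
slab variance shrinks irrelevant effects towards zero without removing
them; a group variance (rather than BayesB-style locus variances)
preserves Bayesian learning. Priors: `pi ~ Uniform(0,1)`;
`sigma2_beta ~ ScaledInvChisq(v_beta = 4, S2_beta)`;
`sigma2_e ~ ScaledInvChisq(v_e = 10, S2_e)`; flat `mu`. The scales come
from the prior-mean identity `E[X] = v S2/(v-2)`: assuming SNPs capture
all additive variance, `E[sigma2_beta] = sigma2_a / (2 sum p(1-p))`, so
`S2_beta = E[sigma2_beta] (v_beta-2)/v_beta` (exactly `E/2` at
`v_beta = 4`) and `S2_e = 0.8 sigma2_E` at `v_e = 10`. No `pi`
adjustment enters the scale derivation.

Full conditionals were re-derived from the stated priors (they are
standard conjugate forms) and are validated against closed-form
conjugate posteriors in the tests: `mu | .` is normal;
`(delta_j, beta_j)` is updated jointly — `delta_j` from the two-point
marginal with `beta_j` integrated out (`rhs_j = x_j'r_j` is
`N(0, xx_j^2 v_c + xx_j sigma2_e)` under component `c`), then `beta_j`
normal given the component; `pi | delta ~ Beta(1 + n_spike, 1 + n_slab)`;
`sigma2_beta` pools `beta_j^2 / t_j` over both components
(`t_j = tau` or 1) into a scaled-inverse-chi-square with
`v_beta + m` degrees of freedom; `sigma2_e` likewise with `v_e + n`.
The residual vector is updated incrementally at every effect move and
refreshed from scratch every 1,000 sweeps; the largest deviation seen at
refresh points is returned and asserted below 1e-8. Chains are
seed-deterministic. Study-scale settings are 100,000 iterations with
20,000 burn-in; the desk-scale default used throughout the tests is
10,000 / 2,000, with burn-in adequacy checked by a Geweke-style
comparison of early and late chain segments rather than visual
inspection. Posterior means over all kept samples estimate the SNP
effects, and `DGV_i = sum_j x_ij beta_mean_j` (the population mean is
excluded; it shifts every DGV equally and cancels in Pearson accuracy).
Dosages are centered by `2 p_j`, consistent with the GRM; centering
affects only `mu`, not DGV correlations (tested).

# The simulator and what it stands for

No public data accompany the study design this package implements (bull
proofs and genotypes of this kind are proprietary), so the synthetic
population is a first-class module:

* **LD and allele-frequency spectrum** come from a neutral forward-in-time
  burn-in: `Ne = 100` individuals random-mating for 200 generations,
  markers starting at frequency 0.5, Haldane recombination (Poisson
  crossovers, no interference, 1 Morgan ~ 100 Mb of synthetic physical
  position). Drift produces a U-shaped frequency spectrum and LD that
  decays with map distance — the two features imputation feeds on. A
  coalescent simulator would be faster per sample but the forward
  burn-in is self-contained and transparent.
* **Pedigree**: discrete generations; each generation samples a small
  sire cohort (intense male selection pathway) and a large dam cohort
  from the previous generation. Founders take burn-in haplotype pairs;
  unknown parents contribute recombined gametes drawn from the founder
  pool, keeping allele frequencies stationary. Parentless individuals
  beyond the founder block (orphans planted in later generations) are
  treated the same way.
* **Traits**: QTL are sampled among segregating markers and effects are
  rescaled so the realized TBV variance equals `sigma2_a` (within 1%,
  enforced). The default contrast is a 5-QTL "sparse" trait (fat-%-like,
  where a single DGAT1-like locus may dominate under Gaussian effects)
  versus a 500-QTL "polygenic" trait (SCS-like), both `h2 = 0.5`.
  Gaussian effects are the default; an "equal" option (unit magnitudes,
  random signs) exists for sampler-recovery oracles, where every planted
  QTL must sit above the detection floor — with Gaussian draws the
  smallest of five effects routinely carries under 1% of the variance
  and is not recoverable at desk-scale sample sizes, which is a property
  of the architecture, not of the sampler.

What the simulator does **not** emulate: real bovine LD maps and chip
content (panel presets are density-scaled stand-ins), genotyping error,
CDN's de-regression mathematics, selection during burn-in, and
cow-genotype biases. Passing tests therefore demonstrate the *relative*
behaviour of the methods under controlled conditions, not the absolute
accuracies attainable on real 50 k data.

# Panel design, imputation, QC

* **QC**: MAF < 0.05, missing rate > 15%, Hardy-Weinberg
  disequilibrium p < 1e-4 (1-df chi-square goodness of fit, no
  continuity correction; the exact test variant is out of scope).
  Rules are evaluated jointly on the input matrix, so filtering is
  idempotent and order-independent. Monomorphic markers get p = 1 by
  convention and fail MAF anyway. No per-animal QC.
* **Panel selection** compromises between uniform spacing and high MAF:
  each chromosome receives SNPs proportionally to its marker content
  (largest remainder, ties to the lower-numbered chromosome), is split
  into that many equal-length bins, and the maximum-MAF marker per bin
  is selected (ties: nearest bin centre, then lowest index). The five
  presets (6 k / 3 k / L1536 / L768 / L384 = 6,177 / 2,480 / 1,536 /
  768 / 384 of 35,790 SNPs) are density-scaled to the synthetic map.
  Panels are designed independently, not nested. Masking keeps full-map
  coordinates (missing codes) so imputation targets stay well defined.
* **Imputation** is a deliberately simplified two-stage algorithm in the
  spirit of family-then-population haplotype imputation; no external
  imputation software is wrapped, and no HMM is used. The family step
  fills only Mendelian-forced genotypes (both parents genotyped and
  homozygous), logging conflicts. The population step phases the
  reference by trio logic plus window-by-window candidate matching
  (windows of 50 markers, 50% overlap; a refinement sweep re-phases
  ambiguous entries against the full first-sweep library), then imputes
  each target per window: library haplotypes compatible with at least
  97% of the target's observed homozygous sites vote on missing alleles,
  weighted by library frequency; expected dosages from overlapping
  windows are averaged and rounded to hard calls (`floor(2q + 0.5)`).
  If no haplotype is compatible the window shrinks by halving around its
  centre down to 5 markers; cells still unresolved take the reference
  major genotype. Observed genotypes are never altered, and all
  tie-breaks (frequency, then pool order) are deterministic.

# Scenarios and evaluation

S0: everyone at full density. S1: validation animals on the low-density
panel. S2/S3: additionally 33%/66% of training animals (uniform random,
seeded) on the panel, with the imputation-only reference shrunk by the
same proportion — "reduced correspondingly" is read as proportional
shrinkage rather than fixed counts, since the synthetic population sizes
differ from any particular data set. All full-density animals
(remaining reference plus unmasked training) form the imputation
reference. Imputation accuracy is the fraction of masked cells whose
hard call equals the truth; DGV accuracy is the Pearson correlation of
validation DGV with TBV (default) or with the high-reliability
validation proofs. The top-SNP experiment re-runs S1 with the `k = 2`
largest-|posterior-mean| SNPs' *actual* genotypes retained on the panel.

# Numerical choices and degenerate inputs

* Singular GBLUP systems get a 1e-8 ridge on the G diagonal (logged);
  the joint-MME route always adds it before inverting G.
* EM-REML iterates classical EM updates in the eigenbasis of G (each
  iteration O(n)); convergence is checked on the *proposed* update
  before accepting, so `tol = Inf` returns the initial values —
  a cheap identity check of the stopping rule. Variance floors at 1e-10
  keep the boundary case (`sigma2_a ~ 0`) inside the parameter space.
* Monomorphic columns are excluded from the GRM scale (with a warning)
  and skipped by the Gibbs sampler (`beta_j = 0` throughout); allele
  frequencies are computed over non-missing genotypes only, and an
  all-missing marker is flagged rather than silently zeroed.
* `gene_drop` requires parents to precede offspring and errors
  otherwise; a trait whose TBV variance is zero (e.g. all individuals
  identical at the QTL) cannot be rescaled and errors.
* Dosage rounding uses `floor(2q + 0.5)` so results do not depend on
  platform-specific round-half-to-even behaviour.

# Problem sizes used by the checks

The test suite runs everything at desk scale, chosen once: study
populations of 10 chromosomes x ~1,000 SNPs before QC (~500-950 after,
depending on drift), 150 founders plus three generations of 150
offspring (~600 animals; ~220 training, 150 validation, ~230
reference), 10,000-iteration chains, and 10 independent seeds for every
across-seed property (imputation monotonicity, pi architecture
sensitivity, method ranking, degradation interaction, top-SNP
augmentation). The sampler-oracle checks use single- and
two-orthogonal-SNP designs where the fixed-variance posterior is exact,
with Monte-Carlo tolerances of three batch-means standard errors.
`scripts/acceptance.R` runs the same pipeline end to end for one seed
and writes its main quantities as JSON.

# Known limitations

* Absolute imputation accuracies at desk scale (reference of a few
  hundred animals, ~500-marker maps) sit well below what a 7,000-animal
  50 k reference achieves; only orderings and interactions are asserted.
* The phasing/imputation heuristic has no genotype-likelihood model; it
  will not match HMM-based imputation on hard cases, and its window
  parameters (50 markers, 97% match) were chosen for the desk-scale map
  densities, configurable for others.
* The burn-in LD structure is a stand-in, not calibrated to Holstein
  LD; panel-density effects are therefore qualitative.
* One-random-effect models only: no single-step H-matrix, no multi-trait
  models, no reliability weighting of residuals.
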