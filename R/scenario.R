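#' Training / validation / reference study design
#'
#' Partitions the population by the bull-proof rules: animals born before
#' `cutoff_year` with reliability above `reliability_min` train the
#' models; animals born in or after `cutoff_year` with reliability above
#' the threshold form the validation set; everything else (older bulls
#' with less reliable proofs) is reference, used for genotype imputation
#' only.
#'
#' @param phenotypes data.frame (`individual_id`, `y`, `reliability`,
#'   `birth_year`).
#' @param cutoff_year first validation birth year.
#' @param reliability_min reliability threshold (default 0.80).
#' @return Object of class `study_design`: list with character id vectors
#'   `training`, `validation`, `reference` (a partition of the
#'   population), plus the rules used.
#' @export
make_design <- function(phenotypes, cutoff_year, reliability_min = 0.80) {
  stopifnot(all(c("individual_id", "reliability", "birth_year") %in%
                  names(phenotypes)))
  if (anyNA(phenotypes$birth_year)) stop("birth years must be present")
  id <- as.character(phenotypes$individual_id)
  pre <- phenotypes$birth_year < cutoff_year
  hi <- phenotypes$reliability > reliability_min
  training <- id[pre & hi]
  validation <- id[!pre & hi]
  reference <- setdiff(id, c(training, validation))
  if (!length(training)) stop("empty training group")
  if (!length(validation)) stop("empty validation group")
  structure(list(training = training, validation = validation,
                 reference = reference, cutoff_year = cutoff_year,
                 reliability_min = reliability_min),
            class = "study_design")
}

#' Low-density genotyping scenario presets
#'
#' S0: everyone has full-density genotypes. S1: all validation animals on
#' the low-density panel. S2/S3: additionally 33% / 66% of the training
#' set is low-density, and the imputation-only reference shrinks by the
#' same proportion so the share of full-density animals is preserved.
#'
#' @param name one of "S0", "S1", "S2", "S3".
#' @return list of class `scenario` with `name`,
#'   `fraction_training_low` and `validation_low`.
#' @export
scenario <- function(name = c("S0", "S1", "S2", "S3")) {
  name <- match.arg(name)
  frac <- c(S0 = 0, S1 = 0, S2 = 1 / 3, S3 = 2 / 3)[[name]]
  structure(list(name = name, fraction_training_low = frac,
                 validation_low = name != "S0"),
            class = "scenario")
}

#' Pearson accuracy of direct genomic values
#'
#' @param dgv predicted DGV vector.
#' @param proofs realised proofs (or true breeding values) in the same
#'   order.
#' @return Pearson correlation coefficient.
#' @export
dgv_accuracy <- function(dgv, proofs) {
  if (length(dgv) != length(proofs) || length(dgv) < 3)
    stop("need at least 3 paired values")
  if (sd(dgv) == 0 || sd(proofs) == 0)
    stop("zero variance; correlation undefined")
  cor(dgv, proofs)
}

#' Bundle a simulated study population
#'
#' Convenience wrapper that simulates pedigree, LD-bearing genotypes, QC,
#' trait architectures, reliabilities and pseudo-proofs, and builds the
#' study design. Pre-cutoff animals receive high reliability
#' (Uniform(0.80, 0.99), entering training) with probability
#' `high_rel_fraction` and low reliability (Uniform(0.30, 0.79), entering
#' the imputation-only reference) otherwise; validation animals (the last
#' generation) receive reliability 0.99 so their proofs are near-noiseless
#' stand-ins for later progeny-test results.
#'
#' @param cfg a [sim_config()].
#' @param arch_specs named list of architecture specs for [build_trait()]
#'   (default a 5-QTL "sparse" and a 500-QTL "polygenic" trait with
#'   heritability 0.5).
#' @param high_rel_fraction fraction of pre-cutoff animals with
#'   high-reliability proofs.
#' @param qc apply the standard marker QC filters first (default TRUE).
#' @param seed master seed (defaults to `cfg$seed`).
#' @return Object of class `gp_study`: list with `geno` (QC-passing truth
#'   genotypes), `haps` (true phased haplotypes on the same markers),
#'   `pedigree`, `freqs`, `traits` (per trait: `architecture`, `tbv`,
#'   `phenotypes`), `design`, `cfg`.
#' @export
simulate_study <- function(cfg,
                           arch_specs = list(
                             sparse = list(n_qtl = 5, sigma2_a = 1,
                                           sigma2_E = 1),
                             polygenic = list(n_qtl = 500, sigma2_a = 1,
                                              sigma2_E = 1)),
                           high_rel_fraction = 0.5, qc = TRUE,
                           seed = cfg$seed) {
  set.seed(seed)
  founders <- simulate_founder_haplotypes(cfg, seed = NULL)
  ped <- simulate_pedigree(cfg, seed = NULL)
  drop <- gene_drop(ped, founders, seed = NULL)
  g <- drop$geno
  haps <- drop$haps
  if (qc) {
    f <- apply_filters(g)
    keep <- which(f$report$pass)
    g <- f$geno
    haps <- haps[, keep, drop = FALSE]
  }
  freqs <- allele_frequencies(g)

  yrs <- ped$birth_year
  cutoff <- max(yrs)
  n <- nrow(ped)
  rel <- numeric(n)
  is_val <- yrs >= cutoff
  rel[is_val] <- 0.99
  pre <- which(!is_val)
  hi <- pre[runif(length(pre)) < high_rel_fraction]
  lo <- setdiff(pre, hi)
  rel[hi] <- runif(length(hi), 0.80, 0.99)
  rel[lo] <- runif(length(lo), 0.30, 0.79)

  # polygenic specs capped by the marker count actually available
  traits <- lapply(arch_specs, function(sp) {
    sp$n_qtl <- min(sp$n_qtl, sum(freqs > 0 & freqs < 1))
    tr <- build_trait(sp, g, seed = NULL)
    tr$phenotypes <- simulate_proofs(tr$tbv, rel, tr$architecture,
                                     birth_year = yrs, seed = NULL)
    tr
  })
  design <- make_design(traits[[1]]$phenotypes, cutoff_year = cutoff)
  structure(list(geno = g, haps = haps, pedigree = ped, freqs = freqs,
                 traits = traits, design = design, cfg = cfg),
            class = "gp_study")
}

#' @export
print.gp_study <- function(x, ...) {
  cat(sprintf(
    "gp_study: %d animals x %d markers; training %d / validation %d / reference %d\n",
    nrow(x$geno$dosages), ncol(x$geno$dosages),
    length(x$design$training), length(x$design$validation),
    length(x$design$reference)))
  invisible(x)
}

#' Draw a scenario's low-density and dropped-reference animals
#'
#' Seeded random selection of the training fraction genotyped on the
#' low-density panel and of the reference animals removed to shrink the
#' imputation reference correspondingly. Shared across panels within a
#' scenario so that sweeps are comparable.
#'
#' @inheritParams run_scenario
#' @return list with character id vectors `low_ids` (animals masked to
#'   the panel) and `ref_drop` (reference animals without genotypes).
#' @export
scenario_assignment <- function(study, sc, seed) {
  set.seed(seed)
  des <- study$design
  low_train <- character(0); ref_drop <- character(0)
  if (sc$fraction_training_low > 0) {
    low_train <- sample(des$training,
                        round(sc$fraction_training_low *
                                length(des$training)))
    ref_drop <- sample(des$reference,
                       round(sc$fraction_training_low *
                               length(des$reference)))
  }
  low_ids <- low_train
  if (sc$validation_low) low_ids <- c(low_ids, des$validation)
  list(low_ids = low_ids, ref_drop = ref_drop)
}

#' Imputation stage of a scenario run
#'
#' Draws the scenario's low-density animals and reference shrinkage,
#' masks their genotypes to the panel, imputes back to the full map with
#' every remaining full-density animal as reference, and scores the
#' imputation against the stored truth. Used on its own to study
#' imputation accuracy, and by [run_scenario()] as stage one.
#'
#' @inheritParams run_scenario
#' @param panel a `panel_spec`.
#' @return list with `geno` (working genotypes: actual where available,
#'   imputed elsewhere; reference animals dropped by the scenario are
#'   excluded), `imputation_accuracy` (overall, 1 when nothing was
#'   masked, `NA` under S0), `per_individual` and `assignment`.
#' @export
impute_for_scenario <- function(study, sc, panel, seed,
                                keep_unmasked = NULL,
                                window = list(size = 50, overlap = 0.5,
                                              min_match = 0.97, floor = 5)) {
  asg <- scenario_assignment(study, sc, seed)
  all_ids <- study$geno$sample_ids
  if (!length(asg$low_ids)) {
    return(list(geno = study$geno, imputation_accuracy = NA_real_,
                per_individual = NULL, assignment = asg))
  }
  ids_used <- setdiff(all_ids, asg$ref_drop)
  gsub <- subset_geno(study$geno, ids_used)
  masked <- mask_to_panel(gsub, panel, individuals = asg$low_ids,
                          keep_unmasked = keep_unmasked)
  refset <- setdiff(ids_used, asg$low_ids)
  lib <- build_library(subset_geno(study$geno, refset), study$pedigree,
                       window_size = window$size, overlap = window$overlap)
  imp <- impute_genotypes(masked, study$pedigree, lib, window)
  if (!any(imp$imputed_cells)) {      # full-map panel: nothing to impute
    return(list(geno = imp$geno, imputation_accuracy = 1,
                per_individual = NULL, assignment = asg))
  }
  acc <- imputation_accuracy(imp, gsub)
  list(geno = imp$geno, imputation_accuracy = acc$overall,
       per_individual = acc$per_individual, assignment = asg)
}

# fit one method on the working genotypes and score validation DGV
fit_and_score <- function(study, gwork, trait_name, method, seed,
                          gibbs = NULL, vc = NULL,
                          accuracy_against = "tbv") {
  tr <- study$traits[[trait_name]]
  des <- study$design
  ids <- gwork$sample_ids
  train_idx <- match(des$training, ids)
  valid_idx <- match(des$validation, ids)
  ph <- tr$phenotypes
  y <- ph$y[match(des$training, ph$individual_id)]
  if (is.null(vc)) {
    r2 <- ph$reliability[match(des$training, ph$individual_id)]
    vc <- variance_components(
      tr$architecture$sigma2_a,
      mean(tr$architecture$sigma2_a * (1 - r2) / r2))
  }
  pi_mean <- NA_real_
  if (method == "gblup") {
    keep <- c(train_idx, valid_idx)
    G <- compute_grm(subset_geno(gwork, keep))
    dgv <- fit_gblup(y, G, vc, seq_along(train_idx),
                     length(train_idx) + seq_along(valid_idx))
    fit <- NULL
  } else if (method == "bayes") {
    if (is.null(gibbs)) gibbs <- gibbs_config(10000, 2000, seed = seed)
    keep <- c(train_idx, valid_idx)
    cen <- center_dosages(subset_geno(gwork, keep))
    prior <- derive_hyperparameters(vc, cen$p[cen$p > 0 & cen$p < 1])
    Xtr <- cen$X[seq_along(train_idx), , drop = FALSE]
    fit <- gibbs_sample(y, Xtr, prior, gibbs)
    Xv <- cen$X[length(train_idx) + seq_along(valid_idx), , drop = FALSE]
    dgv <- predict_dgv(Xv, fit)
    pi_mean <- fit$pi_mean
  } else stop("unknown method: ", method)
  target <- if (accuracy_against == "tbv") {
    tr$tbv[des$validation]
  } else {
    ph$y[match(des$validation, ph$individual_id)]
  }
  list(dgv = dgv, accuracy = dgv_accuracy(dgv, target), pi_mean = pi_mean,
       fit = fit, vc = vc)
}

#' Run one scenario x panel x trait x method cell of the study
#'
#' Executes the full pipeline for one configuration: draw the low-density
#' animals and the reference shrinkage for the scenario, mask their
#' genotypes to the panel, impute back to the full map using every
#' remaining full-density animal as imputation reference, train the
#' prediction method on the training set (actual or imputed genotypes as
#' assigned), predict validation DGV, and record imputation and DGV
#' accuracy.
#'
#' @param study a [simulate_study()] object.
#' @param sc a [scenario()].
#' @param panel a `panel_spec` (ignored under S0).
#' @param trait_name name of a trait in `study$traits`.
#' @param method "gblup" or "bayes".
#' @param seed seed for this run (scenario draws + Gibbs chain).
#' @param gibbs optional [gibbs_config()] (default 10,000 iterations,
#'   2,000 burn-in, seeded from `seed`).
#' @param vc optional [variance_components()]; by default plug-in truth
#'   from the trait architecture with the residual variance implied by
#'   the training reliabilities.
#' @param accuracy_against "tbv" (noise-free true breeding values,
#'   default) or "proofs" (the validation animals' high-reliability
#'   pseudo-proofs).
#' @param keep_unmasked marker indices whose actual genotypes are never
#'   masked (top-SNP augmentation experiments).
#' @param window imputation window settings (see [population_impute()]).
#' @param imputed optional precomputed result of the imputation stage
#'   (used by [run_scenario_grid()] to share imputations across methods
#'   and traits).
#' @return One-row data.frame (`scenario`, `panel`, `trait`, `method`,
#'   `imputation_accuracy`, `dgv_accuracy`, `pi_mean`, `seed`) with the
#'   full fit objects attached as attribute `detail`.
#' @export
run_scenario <- function(study, sc, panel, trait_name, method, seed = 1,
                         gibbs = NULL, vc = NULL, accuracy_against = "tbv",
                         keep_unmasked = NULL,
                         window = list(size = 50, overlap = 0.5,
                                       min_match = 0.97, floor = 5),
                         imputed = NULL) {
  stopifnot(inherits(study, "gp_study"), inherits(sc, "scenario"))
  if (is.null(imputed))
    imputed <- impute_for_scenario(study, sc, panel, seed, keep_unmasked,
                                   window)
  scored <- fit_and_score(study, imputed$geno, trait_name, method, seed,
                          gibbs = gibbs, vc = vc,
                          accuracy_against = accuracy_against)
  out <- data.frame(scenario = sc$name,
                    panel = if (inherits(panel, "panel_spec")) panel$name
                            else NA_character_,
                    trait = trait_name, method = method,
                    imputation_accuracy = imputed$imputation_accuracy,
                    dgv_accuracy = scored$accuracy,
                    pi_mean = scored$pi_mean, seed = seed,
                    stringsAsFactors = FALSE)
  attr(out, "detail") <- list(dgv = scored$dgv, fit = scored$fit,
                              vc = scored$vc,
                              per_individual = imputed$per_individual,
                              assignment = imputed$assignment)
  out
}

#' Sweep scenarios, panels, traits and methods
#'
#' Runs every combination, sharing the expensive imputation stage across
#' traits and methods within each scenario x panel cell.
#'
#' @param study a [simulate_study()] object.
#' @param scenarios character vector of scenario names.
#' @param panels named list of `panel_spec`s.
#' @param traits trait names (default all in the study).
#' @param methods prediction methods.
#' @param seed run seed.
#' @inheritParams run_scenario
#' @return data.frame with one row per combination.
#' @export
run_scenario_grid <- function(study, scenarios = c("S1", "S2", "S3"),
                              panels, traits = names(study$traits),
                              methods = c("gblup", "bayes"), seed = 1,
                              gibbs = NULL, accuracy_against = "tbv",
                              window = list(size = 50, overlap = 0.5,
                                            min_match = 0.97, floor = 5)) {
  rows <- list()
  for (sn in scenarios) {
    sc <- scenario(sn)
    for (pn in names(panels)) {
      imputed <- impute_for_scenario(study, sc, panels[[pn]], seed,
                                     window = window)
      for (tn in traits) for (me in methods) {
        r <- run_scenario(study, sc, panels[[pn]], tn, me, seed = seed,
                          gibbs = gibbs, accuracy_against = accuracy_against,
                          window = window, imputed = imputed)
        rows[[length(rows) + 1]] <- r
      }
      if (sc$name == "S0") break      # panels are irrelevant under S0
    }
  }
  do.call(rbind, rows)
}

#' Top-SNP panel augmentation experiment
#'
#' Fits the Bayesian model on actual full-density genotypes to rank SNPs
#' by absolute estimated effect, then re-runs scenario S1 for the given
#' panel twice: as is, and with the `k` largest-effect SNPs' actual
#' genotypes always retained (never masked). Reports both methods'
#' accuracies with and without augmentation.
#'
#' @inheritParams run_scenario
#' @param panel low-density `panel_spec`.
#' @param k number of top SNPs to add (default 2).
#' @param effects optional per-SNP effect vector; when `NULL` a
#'   full-density Bayesian fit supplies the posterior-mean effects.
#' @return data.frame with rows for method x {plain, augmented} and an
#'   attribute `top_snps`.
#' @export
top_snp_experiment <- function(study, panel, trait_name, k = 2, seed = 1,
                               gibbs = NULL, effects = NULL,
                               accuracy_against = "tbv",
                               window = list(size = 50, overlap = 0.5,
                                             min_match = 0.97, floor = 5)) {
  if (k < 1) stop("k must be >= 1")
  if (k > ncol(study$geno$dosages)) stop("k exceeds number of markers")
  if (is.null(effects)) {
    s0 <- run_scenario(study, scenario("S0"), panel, trait_name, "bayes",
                       seed = seed, gibbs = gibbs,
                       accuracy_against = accuracy_against)
    effects <- attr(s0, "detail")$fit$beta_mean
  }
  top <- order(-abs(effects), seq_along(effects))[seq_len(k)]
  sc <- scenario("S1")
  rows <- list()
  imp_plain <- impute_for_scenario(study, sc, panel, seed, window = window)
  imp_aug <- impute_for_scenario(study, sc, panel, seed,
                                 keep_unmasked = top, window = window)
  for (me in c("gblup", "bayes")) {
    r0 <- run_scenario(study, sc, panel, trait_name, me, seed = seed,
                       gibbs = gibbs, accuracy_against = accuracy_against,
                       imputed = imp_plain)
    r1 <- run_scenario(study, sc, panel, trait_name, me, seed = seed,
                       gibbs = gibbs, accuracy_against = accuracy_against,
                       imputed = imp_aug)
    r0$variant <- "plain"; r1$variant <- "augmented"
    rows[[length(rows) + 1]] <- r0
    rows[[length(rows) + 1]] <- r1
  }
  out <- do.call(rbind, rows)
  attr(out, "top_snps") <- top
  out
}

#' Format scenario results as accuracy tables
#'
#' One matrix per trait, scenarios in rows and panels in columns, cells
#' formatted as "GBLUP (Bayesian)"; missing combinations render as NA.
#'
#' @param results data.frame from [run_scenario()] /
#'   [run_scenario_grid()] rows.
#' @param value which accuracy to tabulate.
#' @return Named list of character matrices, one per trait.
#' @export
report_tables <- function(results,
                          value = c("dgv_accuracy", "imputation_accuracy")) {
  value <- match.arg(value)
  if (!nrow(results)) stop("empty results")
  out <- list()
  for (tn in unique(results$trait)) {
    r <- results[results$trait == tn, ]
    scs <- unique(r$scenario); pns <- unique(r$panel)
    tab <- matrix(NA_character_, length(scs), length(pns),
                  dimnames = list(scs, pns))
    for (s in scs) for (p in pns) {
      gb <- r[r$scenario == s & r$panel %in% p & r$method == "gblup", value]
      by <- r[r$scenario == s & r$panel %in% p & r$method == "bayes", value]
      cell <- if (length(gb)) sprintf("%.2f", mean(gb)) else "NA"
      if (length(by)) cell <- paste0(cell, sprintf(" (%.2f)", mean(by)))
      tab[s, p] <- cell
    }
    out[[tn]] <- tab
  }
  out
}
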