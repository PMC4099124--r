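design_fixture <- function() {
  data.frame(individual_id = paste0("b", 1:6),
             y = rnorm(6),
             reliability = c(0.95, 0.5, 0.9, 0.99, 0.99, 0.7),
             birth_year = c(2001, 2002, 2003, 2004, 2005, 2001))
}

test_that("the design partitions by birth year and reliability", {
  ph <- design_fixture()
  d <- make_design(ph, cutoff_year = 2004)
  expect_setequal(d$training, c("b1", "b3"))
  expect_setequal(d$validation, c("b4", "b5"))
  expect_setequal(d$reference, c("b2", "b6"))      # low reliability
  expect_setequal(c(d$training, d$validation, d$reference),
                  ph$individual_id)
  # all validation-aged animals with reliability 1 partition by year only
  ph2 <- ph; ph2$reliability <- 1
  d2 <- make_design(ph2, 2004)
  expect_equal(length(d2$reference), 0)
  expect_error(make_design(ph, cutoff_year = 1990), "training")
})

test_that("scenario presets carry the study's masking fractions", {
  expect_equal(scenario("S0")$fraction_training_low, 0)
  expect_false(scenario("S0")$validation_low)
  expect_equal(scenario("S2")$fraction_training_low, 1 / 3)
  expect_equal(scenario("S3")$fraction_training_low, 2 / 3)
  expect_true(scenario("S3")$validation_low)
})

test_that("Pearson DGV accuracy matches longhand arithmetic", {
  expect_equal(dgv_accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(dgv_accuracy(c(1, 2, 3), -c(1, 2, 3)), -1)
  # longhand: centered x = (-1,0,1), y - 13/3 = (-7/3, -1/3, 8/3)
  r <- 5 / sqrt(2 * 114 / 9)
  expect_equal(dgv_accuracy(c(1, 2, 3), c(2, 4, 7)), r)
  expect_error(dgv_accuracy(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(dgv_accuracy(1:2, 1:2), "at least 3")
})

test_that("S0 equals a direct train/predict run and S1 on the full map
           changes nothing", {
  st <- fixture_study()
  pan_full <- suppressWarnings(select_panel(st$geno,
                                            ncol(st$geno$dosages)))
  r0 <- run_scenario(st, scenario("S0"), pan_full, "sparse", "gblup",
                     seed = 5)
  r1 <- run_scenario(st, scenario("S1"), pan_full, "sparse", "gblup",
                     seed = 5)
  expect_equal(r1$imputation_accuracy, 1)
  expect_equal(r0$dgv_accuracy, r1$dgv_accuracy, tolerance = 1e-12)

  # direct fit reproduces the S0 cell
  des <- st$design
  tr <- st$traits$sparse
  ids <- st$geno$sample_ids
  vc <- attr(r0, "detail")$vc
  keep <- c(match(des$training, ids), match(des$validation, ids))
  G <- compute_grm(subset_geno(st$geno, keep))
  y <- tr$phenotypes$y[match(des$training, tr$phenotypes$individual_id)]
  dgv <- fit_gblup(y, G, vc, seq_along(des$training),
                   length(des$training) + seq_along(des$validation))
  expect_equal(unname(dgv_accuracy(dgv, tr$tbv[des$validation])),
               r0$dgv_accuracy)
})

test_that("scenario runs are reproducible from their seed", {
  st <- fixture_study()
  pan <- select_panel(st$geno, 30)
  a <- run_scenario(st, scenario("S2"), pan, "sparse", "gblup", seed = 9)
  b <- run_scenario(st, scenario("S2"), pan, "sparse", "gblup", seed = 9)
  expect_identical(a$imputation_accuracy, b$imputation_accuracy)
  expect_identical(a$dgv_accuracy, b$dgv_accuracy)
})

test_that("the scenario grid shares imputations and reports all cells", {
  st <- fixture_study()
  panels <- list(p40 = select_panel(st$geno, 40),
                 p15 = select_panel(st$geno, 15))
  res <- run_scenario_grid(st, scenarios = c("S1", "S3"), panels = panels,
                           traits = "sparse", methods = "gblup", seed = 4)
  expect_equal(nrow(res), 4)
  expect_true(all(res$imputation_accuracy > 0 &
                    res$imputation_accuracy <= 1))
  # denser panel imputes better within a scenario
  s1 <- res[res$scenario == "S1", ]
  expect_gt(s1$imputation_accuracy[s1$panel == "P40"],
            s1$imputation_accuracy[s1$panel == "P15"])
  tabs <- report_tables(res)
  expect_equal(dim(tabs$sparse), c(2, 2))
  expect_false(anyNA(tabs$sparse))
})

test_that("missing grid combinations render as NA cells", {
  res <- data.frame(scenario = "S1", panel = "p", trait = "t",
                    method = "gblup", imputation_accuracy = 0.9,
                    dgv_accuracy = 0.5, pi_mean = NA, seed = 1)
  res2 <- rbind(res, transform(res, scenario = "S2", dgv_accuracy = NA))
  tabs <- report_tables(res2)
  expect_true(grepl("NA", tabs$t["S2", "p"]))
})
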