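test_that("parental PGS pairs reproduce the assortment parameter", {
  cfg0 <- sim_config(n_pairs_dz = 50000, n_pairs_mz = 0, r_assortment = 0,
                     include_covariates = FALSE, n_items_per_timepoint = 0,
                     seed = 101)
  p0 <- simulate_parents(cfg0)
  expect_lt(abs(cor(p0$pgs_mother, p0$pgs_father)), 0.01)

  cfg3 <- sim_config(n_pairs_dz = 50000, n_pairs_mz = 0, r_assortment = 0.3,
                     include_covariates = FALSE, n_items_per_timepoint = 0,
                     seed = 102)
  p3 <- simulate_parents(cfg3)
  expect_equal(cor(p3$pgs_mother, p3$pgs_father), 0.30, tolerance = 0.01 / 0.30)
  # single population: unit-variance, zero-mean parental scores
  expect_lt(abs(mean(p0$pgs_mother)), 0.02)
  expect_equal(var(p0$pgs_mother), 1, tolerance = 0.01)
})

test_that("offspring PGS has the pedigree correlation structure", {
  cfg <- lean_config(50000, seed = 103, n_pairs_mz = 2000)
  parents <- simulate_parents(cfg)
  kids <- simulate_offspring_pgs(parents, cfg)
  g1 <- kids$pgs[kids$twin_index == 1]
  g2 <- kids$pgs[kids$twin_index == 2]
  zyg <- kids$zygosity[kids$twin_index == 1]
  # MZ co-twins share one segregation draw
  expect_identical(g1[zyg == "MZ"], g2[zyg == "MZ"])
  expect_equal(cor(g1[zyg == "DZ"], g2[zyg == "DZ"]), 0.5, tolerance = 0.02)

  cfga <- sim_config(n_pairs_dz = 50000, n_pairs_mz = 0, r_assortment = 0.3,
                     include_covariates = FALSE, n_items_per_timepoint = 0,
                     seed = 104)
  pa <- simulate_parents(cfga)
  ka <- simulate_offspring_pgs(pa, cfga)
  r_dz <- cor(ka$pgs[ka$twin_index == 1], ka$pgs[ka$twin_index == 2])
  expect_gt(r_dz, 0.5)
  # segregation variance 1/2 implies corr (1 + r) / (2 + r) under assortment
  expect_equal(r_dz, (1 + 0.3) / (2 + 0.3), tolerance = 0.02)
})

test_that("invalid generator parameters are rejected", {
  expect_error(sim_config(r_assortment = 1.5), "r_assortment")
  expect_error(sim_config(s_contrast = 1), "s_contrast")
  expect_error(sim_config(var_c = -0.1), "var_c")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  cfg <- lean_config(10)
  parents <- simulate_parents(cfg)
  parents$zygosity[1] <- "XX"
  expect_error(simulate_offspring_pgs(parents, cfg), "zygosity")
})

test_that("cohort generation is reproducible and standardized", {
  cfg <- sim_config(n_pairs_dz = 400, n_pairs_mz = 200, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_true(all(table(a$family_id) == 2))
  expect_equal(mean(a$pgs), 0, tolerance = 1e-12)
  expect_equal(var(a$pgs), 1, tolerance = 1e-12)
  ph <- a$cp_age7_parent
  expect_equal(var(ph, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(mean(ph, na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("missingness is MCAR at the configured rate", {
  cfg <- sim_config(n_pairs_dz = 5000, n_pairs_mz = 0, missing_rate = 0.2,
                    ages = 9, reporters = "parent", n_items_per_timepoint = 0,
                    include_covariates = FALSE, seed = 9)
  co <- simulate_cohort(cfg)
  expect_equal(mean(is.na(co$cp_age9_parent)), 0.20, tolerance = 0.01 / 0.20)
})

test_that("family-level covariates are shared by co-twins and SES tracks the midparent PGS", {
  cfg <- sim_config(n_pairs_dz = 2000, n_pairs_mz = 1000, seed = 11,
                    conf_ses_loading = 0.4)
  co <- simulate_cohort(cfg)
  t1 <- co[co$twin_index == 1, ]; t2 <- co[co$twin_index == 2, ]
  expect_identical(t1$ses, t2$ses)
  expect_identical(t1$imd_decile, t2$imd_decile)
  expect_identical(t1$parenting_age4_item1, t2$parenting_age4_item1)
  mid <- (t1$sim_pgs_mother + t1$sim_pgs_father) / 2
  # theoretical cor = conf * sd(mid) / sd(ses)
  r_theory <- 0.4 * sd(mid) / sd(t1$ses)
  expect_lt(abs(cor(t1$ses, mid) - r_theory), 0.06)

  cfg0 <- sim_config(n_pairs_dz = 20000, n_pairs_mz = 0, seed = 12,
                     conf_ses_loading = 0, n_items_per_timepoint = 0,
                     ages = 9, reporters = "parent")
  co0 <- simulate_cohort(cfg0)
  f1 <- co0[co0$twin_index == 1, ]
  expect_lt(abs(cor(f1$ses, (f1$sim_pgs_mother + f1$sim_pgs_father) / 2)), 0.015)
})

test_that("a pure direct effect makes the phenotype the PGS itself", {
  cfg <- lean_config(1000, beta_direct = 1, seed = 13)
  cfg$var_e <- 0
  co <- simulate_cohort(cfg)
  expect_equal(co$cp_age9_parent, co$pgs, tolerance = 1e-12)
  fit <- fit_population_model(co, "cp_age9_parent", covariates = NULL)
  expect_equal(fit$beta_population, 1, tolerance = 1e-10)
  wb <- fit_within_between_model(co, "cp_age9_parent", covariates = NULL)
  expect_equal(wb$beta_within, 1, tolerance = 1e-10)
  expect_equal(wb$beta_between, 1, tolerance = 1e-10)
})

test_that("the contrast transform reshapes the pair covariance as (I-sB)^-1 Sigma (I-sB)^-T", {
  s <- -0.2
  cfg <- twin_config(20000, a2 = 0, c2 = 0, s_contrast = s, seed = 14)
  co <- simulate_cohort(cfg)
  cfg_raw <- twin_config(20000, a2 = 0, c2 = 0, s_contrast = s, seed = 14,
                         standardize = FALSE)
  raw <- simulate_cohort(cfg_raw)
  y1 <- raw$cp_age9_parent[raw$twin_index == 1]
  y2 <- raw$cp_age9_parent[raw$twin_index == 2]
  emp <- cov(cbind(y1, y2))
  Tm <- solve(diag(2) - s * matrix(c(0, 1, 1, 0), 2))
  expected <- Tm %*% diag(2) %*% t(Tm)   # pure-E: Sigma0 = I
  expect_equal(emp, expected, tolerance = 0.03, ignore_attr = TRUE)
})

test_that("per-age sampling fractions blank whole families at that wave", {
  cfg <- sim_config(n_pairs_dz = 2000, n_pairs_mz = 0, missing_rate = 0,
                    ages = c(7, 9), reporters = "parent",
                    n_items_per_timepoint = 2,
                    age_sampling_fraction = c("9" = 0.5), seed = 15)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(is.na(co$cp_age9_parent)) - 0.5), 0.03)
  expect_equal(mean(is.na(co$cp_age7_parent)), 0)
  # missing at age 9 is family-wise: co-twins agree
  t1 <- co[co$twin_index == 1, ]; t2 <- co[co$twin_index == 2, ]
  expect_identical(is.na(t1$cp_age9_parent), is.na(t2$cp_age9_parent))
  # items at the blanked wave are blanked for the same families
  expect_identical(is.na(t1$cp_age9_parent), is.na(t1$cp_age9_parent_item1))
})

test_that("cohorts round-trip through TSV with their YAML sidecar", {
  cfg <- sim_config(n_pairs_dz = 50, n_pairs_mz = 20, seed = 16)
  co <- simulate_cohort(cfg)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp, paste0(tmp, ".yaml"))), add = TRUE)
  write_cohort(co, tmp)
  back <- read_cohort(tmp)
  expect_equal(back$pgs, co$pgs, tolerance = 1e-9)
  expect_equal(attr(back, "sim_truth")$beta_direct, 0.12)
  expect_s3_class(attr(back, "sim_config"), "sim_config")
})
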