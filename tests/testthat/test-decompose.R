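toy_cohort <- function() {
  # 3 DZ families, hand-picked values
  data.frame(
    person_id = paste0("p", 1:6),
    family_id = rep(1:3, each = 2),
    twin_index = rep(1:2, 3),
    zygosity = "DZ",
    pgs = c(0.4, -0.2, 0.7, 0.1, -0.5, 0.3),
    y = c(0.2, -0.1, 0.9, 0.4, -0.6, 0.2)
  )
}

test_that("family scores follow the pair-mean / deviation definitions", {
  co <- toy_cohort()
  fs <- build_family_scores(co)
  expect_equal(fs$pgs_between[1:2], c(0.1, 0.1))
  expect_equal(fs$pgs_within[1:2], c(0.3, -0.3))
  # within deviations cancel exactly inside every family
  expect_equal(as.vector(tapply(fs$pgs_within, fs$family_id, sum)),
               rep(0, 3), tolerance = 1e-15)

  mz <- data.frame(person_id = c("a", "b"), family_id = 1, twin_index = 1:2,
                   zygosity = "MZ", pgs = c(0.7, 0.7))
  expect_message(fs_mz <- build_family_scores(mz), "identically zero")
  expect_equal(fs_mz$pgs_within, c(0, 0))

  # families without two genotyped members are excluded with a count
  co$pgs[6] <- NA
  expect_message(fs2 <- build_family_scores(co), "excluded 1 family")
  expect_equal(attr(fs2, "dropped_families"), 1)
  expect_false(3 %in% fs2$family_id)
})

test_that("regression coefficients match the normal-equations oracle", {
  co <- toy_cohort()
  co$cov1 <- c(1.2, -0.3, 0.5, 2.0, -1.1, 0.4)
  fit <- fit_population_model(co, "y", covariates = "cov1", min_n = 2)
  X <- cbind(1, scale(co$cov1)[, 1], scale(co$pgs)[, 1])
  yz <- scale(co$y)[, 1]
  expect_equal(unname(fit$coef), as.vector(ols_oracle(X, yz)), tolerance = 1e-8)

  wb <- fit_within_between_model(co, "y", covariates = NULL, min_n = 2)
  fs <- build_family_scores(co)
  Xw <- cbind(1, fs$pgs_within, fs$pgs_between)
  expect_equal(unname(wb$coef), as.vector(ols_oracle(Xw, yz)), tolerance = 1e-8)
})

test_that("within/between fit is an exact reparameterization of (own, family-mean)", {
  cfg <- lean_config(300, beta_direct = 0.2, eta_nurture = 0.1, seed = 21)
  co <- simulate_cohort(cfg)
  wb <- fit_within_between_model(co, "cp_age9_parent", covariates = NULL)
  # own-score + family-mean parameterization: y = b1*pgs + b2*mean + ...
  # maps to within = b1, between = b1 + b2
  fs <- build_family_scores(co)
  y <- scale(fs$cp_age9_parent)[, 1]
  X2 <- cbind(1, fs$pgs, fs$pgs_between)
  cf <- as.vector(ols_oracle(X2, y))
  expect_equal(wb$beta_within, cf[2], tolerance = 1e-10)
  expect_equal(wb$beta_between, cf[2] + cf[3], tolerance = 1e-10)
  # identical fitted values
  fitted_wb <- cbind(1, fs$pgs_within, fs$pgs_between) %*% unname(wb$coef)
  fitted_own <- X2 %*% cf
  expect_equal(as.vector(fitted_wb), as.vector(fitted_own), tolerance = 1e-10)
})

test_that("null and identity regressions behave as they must", {
  cfg <- lean_config(25000, beta_direct = 0, seed = 22)
  co <- simulate_cohort(cfg)
  fit <- fit_population_model(co, "cp_age9_parent", covariates = NULL)
  expect_lt(abs(fit$beta_population), 0.01)
  expect_lt(fit$r2_pgs, 0.001)

  # MZ-only input cannot identify the within effect
  cfgmz <- sim_config(n_pairs_dz = 0, n_pairs_mz = 100, ages = 9,
                      reporters = "parent", n_items_per_timepoint = 0,
                      var_specific = 0, missing_rate = 0,
                      include_covariates = FALSE, seed = 23)
  mzco <- simulate_cohort(cfgmz)
  expect_error(
    suppressMessages(fit_within_between_model(mzco, "cp_age9_parent", covariates = NULL)),
    "not identified")
})

test_that("indirect effect is between minus within, with its population share", {
  fit <- structure(list(model = "within_between", indirect = 0.04,
                        beta_within = 0.06, beta_between = 0.10),
                   class = "decomp_fit")
  out <- indirect_effect(fit, beta_population = 0.10)
  expect_equal(out$indirect, 0.04)
  expect_equal(out$share_of_population, 0.4)
  fit$indirect <- 0.05 - 0.08
  expect_equal(indirect_effect(fit)$indirect, -0.03)
})

test_that("estimator recovers direct and indirect effects with the 4/3 nurture factor", {
  # average over seeds so the check sits well outside Monte-Carlo noise
  fits <- lapply(1:4, function(sd_) {
    co <- simulate_cohort(lean_config(50000, beta_direct = 0.15,
                                      eta_nurture = 0.05, seed = 240 + sd_))
    fit_within_between_model(co, "cp_age9_parent", covariates = NULL)
  })
  expect_equal(mean(vapply(fits, `[[`, numeric(1), "beta_within")), 0.15,
               tolerance = 0.01 / 0.15)
  expect_equal(mean(vapply(fits, `[[`, numeric(1), "indirect")), 4 / 3 * 0.05,
               tolerance = 0.012 / 0.0667)

  # no nurture: within and between coincide
  cfg0 <- lean_config(50000, beta_direct = 0.15, seed = 25)
  co0 <- simulate_cohort(cfg0)
  wb0 <- fit_within_between_model(co0, "cp_age9_parent", covariates = NULL)
  expect_lt(abs(wb0$indirect), 0.01)
})

test_that("population stratification inflates the indirect effect and PCs absorb it", {
  cfg <- sim_config(n_pairs_dz = 20000, n_pairs_mz = 0,
                    beta_direct = 0.15, eta_nurture = 0,
                    n_strata = 2, strata_pgs_shift = 0.6, strata_env_shift = 0.6,
                    var_a_residual = 0, var_c = 0, var_e = 0.6,
                    var_specific = 0, missing_rate = 0,
                    ages = 9, reporters = "parent", n_items_per_timepoint = 0,
                    seed = 26)
  co <- simulate_cohort(cfg)
  naive <- fit_within_between_model(co, "cp_age9_parent", covariates = NULL)
  ctrl <- fit_within_between_model(co, "cp_age9_parent",
                                   covariates = paste0("pc", 1:10))
  expect_gt(naive$indirect, 0.05)
  expect_lt(abs(ctrl$indirect), 0.4 * naive$indirect)
})

test_that("incremental R2 has its closed form and guards its row contract", {
  cfg <- lean_config(25000, beta_direct = 0.15, seed = 27)
  co <- simulate_cohort(cfg)
  fit <- fit_population_model(co, "cp_age9_parent", covariates = NULL)
  expect_equal(fit$r2_pgs, 0.15^2, tolerance = 0.002 / 0.0225)

  co$cov1 <- rnorm(nrow(co))
  f_full <- fit_population_model(co, "cp_age9_parent", covariates = "cov1")
  co2 <- co[-(1:4), ]
  f_other <- fit_population_model(co2, "cp_age9_parent", covariates = "cov1")
  expect_error(variance_explained(f_full, f_other), "different rows")
})

test_that("orthogonality: family-level covariates cannot move the within coefficient", {
  cfg <- sim_config(n_pairs_dz = 1500, n_pairs_mz = 0, beta_direct = 0.2,
                    var_specific = 0, missing_rate = 0, ages = 9,
                    reporters = "parent", n_items_per_timepoint = 0, seed = 28)
  co <- simulate_cohort(cfg)
  with_cov <- fit_within_between_model(co, "cp_age9_parent",
                                       covariates = c("ses", "platform"))
  without <- fit_within_between_model(co, "cp_age9_parent", covariates = NULL)
  expect_equal(with_cov$beta_within, without$beta_within, tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly, naming the aliased column", {
  co <- toy_cohort()
  co$dup <- co$pgs
  expect_error(fit_population_model(co, "y", covariates = "dup", min_n = 2),
               "rank deficient.*(dup|pgs)")
  cfg <- lean_config(40, seed = 29)
  small <- simulate_cohort(cfg)[1:20, ]
  expect_error(fit_population_model(small, "cp_age9_parent", covariates = NULL),
               "refusing to fit")
})

test_that("controlling for SES removes an SES-mediated indirect effect", {
  cfg <- sim_config(n_pairs_dz = 15000, n_pairs_mz = 0,
                    beta_direct = 0.15, eta_nurture = 0,
                    beta_ses_pheno = 0.25, conf_ses_loading = 0.5,
                    var_a_residual = 0, var_c = 0, var_specific = 0,
                    missing_rate = 0, ages = 9, reporters = "parent",
                    n_items_per_timepoint = 0, seed = 30)
  co <- simulate_cohort(cfg)
  res <- control_for(co, "cp_age9_parent", "ses", covariates = NULL,
                     B = 500, seed = 31)
  expect_true(res$uncontrolled_indirect_significant)
  expect_false(res$controlled_indirect_significant)
  expect_lt(abs(res$attenuation_direct_pct), 10)
  # controlled indirect is zero in expectation: average point estimates over
  # seeds so the check sits at ~3 Monte-Carlo SEs
  ctrl_pts <- vapply(1:3, function(sd_) {
    cfg_i <- cfg; cfg_i$seed <- 300 + sd_
    co_i <- simulate_cohort(cfg_i)
    fit_within_between_model(co_i, "cp_age9_parent", covariates = "ses")$indirect
  }, numeric(1))
  expect_lt(abs(mean(ctrl_pts)), 0.015)

  # an irrelevant covariate leaves the estimates unchanged within 1 SE
  co$noise_cov <- rnorm(nrow(co))
  res2 <- control_for(co, "cp_age9_parent", "noise_cov", covariates = NULL,
                      B = 300, seed = 32)
  expect_lt(abs(res2$controlled$within_between$beta_within -
                  res2$uncontrolled$within_between$beta_within),
            res2$uncontrolled$boot$within$se)
})
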