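test_that("twin correlations match the generating variance components", {
  co <- simulate_cohort(twin_config(10000, a2 = 0.6, c2 = 0.2, e2 = 0.2,
                                    seed = 61))
  td <- make_twin_dataset(co, "cp_age9_parent", covariates = NULL)
  rc <- twin_correlations(td)
  expect_equal(rc$r[rc$zygosity == "MZ"], 0.80, tolerance = 0.02 / 0.8)
  expect_equal(rc$r[rc$zygosity == "DZ"], 0.50, tolerance = 0.025 / 0.5)

  # pure E: both correlations at zero
  co0 <- simulate_cohort(twin_config(10000, e2 = 1, seed = 62))
  rc0 <- twin_correlations(make_twin_dataset(co0, "cp_age9_parent", covariates = NULL))
  expect_lt(max(abs(rc0$r)), 0.02)

  # identical MZ phenotypes pin the correlation at 1
  co1 <- co[co$zygosity == "MZ", ]
  co1$cp_age9_parent <- ave(co1$cp_age9_parent, co1$family_id)
  co1 <- rbind(co1, co[co$zygosity == "DZ", ])
  rc1 <- twin_correlations(make_twin_dataset(co1, "cp_age9_parent", covariates = NULL))
  expect_equal(rc1$r[rc1$zygosity == "MZ"], 1)

  expect_error(
    twin_correlations(make_twin_dataset(co[1:40, ], "cp_age9_parent",
                                        covariates = NULL)),
    "need >= 30")
})

test_that("ACE versus ADE is chosen from the correlation pattern", {
  expect_equal(choose_model(0.8, 0.3), "ADE")
  expect_equal(choose_model(0.6, 0.4), "ACE")
  expect_equal(choose_model(0.6, 0.3), "ACE")  # boundary: C = D = 0
})

test_that("FIML recovers ACE components and matches the density oracle and Falconer", {
  fits <- lapply(1:2, function(r) {
    co <- simulate_cohort(twin_config(5000, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                                      seed = 620 + r))
    td <- make_twin_dataset(co, "cp_age9_parent", covariates = NULL)
    fit_twin_model(td, "ACE", seed = 64, n_restarts = 2)
  })
  expect_equal(mean(vapply(fits, `[[`, numeric(1), "a2")), 0.5, tolerance = 0.03 / 0.5)
  expect_equal(mean(vapply(fits, `[[`, numeric(1), "c2")), 0.2, tolerance = 0.03 / 0.2)
  expect_equal(mean(vapply(fits, `[[`, numeric(1), "e2")), 0.3, tolerance = 0.03 / 0.3)
  co <- simulate_cohort(twin_config(5000, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                                    seed = 621))
  td <- make_twin_dataset(co, "cp_age9_parent", covariates = NULL)
  fit <- fits[[1]]

  # Falconer moment estimates from the same correlations
  rc <- twin_correlations(td)
  rmz <- rc$r[rc$zygosity == "MZ"]; rdz <- rc$r[rc$zygosity == "DZ"]
  expect_equal(fit$a2, 2 * (rmz - rdz), tolerance = 0.04 / 0.5)
  expect_equal(fit$c2, 2 * rdz - rmz, tolerance = 0.05 / 0.2)

  # FIML log-likelihood equals the per-pair bivariate-normal oracle
  p <- fit$paths
  mu <- rep(fit$beta[1], length(td$y1))
  S_mz <- matrix(c(p$a^2 + p$c^2 + p$e^2, p$a^2 + p$c^2,
                   p$a^2 + p$c^2, p$a^2 + p$c^2 + p$e^2), 2)
  S_dz <- matrix(c(p$a^2 + p$c^2 + p$e^2, 0.5 * p$a^2 + p$c^2,
                   0.5 * p$a^2 + p$c^2, p$a^2 + p$c^2 + p$e^2), 2)
  ll_oracle <- twin_loglik_oracle(td, mu, mu, S_mz, S_dz)
  expect_equal(fit$loglik, ll_oracle, tolerance = 1e-8)
})

test_that("pure-E data yields e2 near one and tiny a2, c2", {
  co <- simulate_cohort(twin_config(10000, e2 = 1, seed = 65))
  td <- make_twin_dataset(co, "cp_age9_parent", covariates = NULL)
  fit <- fit_twin_model(td, "ACE", seed = 66)
  expect_gt(fit$e2, 0.97)
  expect_lt(fit$a2, 0.025)
  expect_lt(fit$c2, 0.025)
})

test_that("the FIML likelihood is monotone in model complexity", {
  co <- simulate_cohort(twin_config(2000, a2 = 0.4, c2 = 0.15, e2 = 0.45,
                                    seed = 67))
  td <- make_twin_dataset(co, "cp_age9_parent", covariates = NULL)
  ll <- vapply(c("E", "AE", "ACE"), function(m)
    fit_twin_model(td, m, seed = 68)$loglik, numeric(1))
  expect_true(ll["AE"] >= ll["E"] - 1e-6)
  expect_true(ll["ACE"] >= ll["AE"] - 1e-6)
})

test_that("likelihood-ratio comparison detects C and handles the boundary", {
  co <- simulate_cohort(twin_config(5000, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                                    seed = 69))
  td <- make_twin_dataset(co, "cp_age9_parent", covariates = NULL)
  full <- fit_twin_model(td, "ACE", seed = 70)
  red <- fit_twin_model(td, "AE", seed = 71)
  cmp <- compare_models(full, red)
  expect_equal(cmp$df, 1)
  expect_gt(cmp$minus2_delta_ll, 3.84)
  expect_lt(cmp$p_mixture, cmp$p_chisq + 1e-12)

  same <- compare_models(full, full)
  expect_equal(same$minus2_delta_ll, 0)
  expect_equal(same$p_chisq, 1)

  other <- simulate_cohort(twin_config(500, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                                       seed = 72))
  td2 <- make_twin_dataset(other, "cp_age9_parent", covariates = NULL)
  red2 <- fit_twin_model(td2, "AE", seed = 73)
  expect_error(compare_models(full, red2), "identical data")
})

test_that("dropping a truly absent C keeps the boundary-corrected rejections below nominal", {
  # c2 = 0 in truth: the LRT statistic sits on the boundary, so naive chi^2(1)
  # rejections fall below 5%; checked over seeded replicates
  rej <- vapply(1:40, function(r) {
    co <- simulate_cohort(twin_config(800, a2 = 0.5, c2 = 0, e2 = 0.5,
                                      seed = 7300 + r))
    td <- make_twin_dataset(co, "cp_age9_parent", covariates = NULL)
    full <- fit_twin_model(td, "ACE", seed = r, n_restarts = 2)
    red <- fit_twin_model(td, "AE", seed = r, n_restarts = 2)
    compare_models(full, red)$p_chisq < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.125)
})

test_that("sibling-interaction parameter is recovered", {
  co <- simulate_cohort(twin_config(8000, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                                    s_contrast = 0.2, seed = 74))
  td <- make_twin_dataset(co, "cp_age9_parent", covariates = NULL)
  fit <- fit_twin_model(td, "ACE", sibling_interaction = TRUE, seed = 75)
  expect_equal(fit$s, 0.2, tolerance = 0.05 / 0.2)
  expect_equal(fit$a2, 0.5, tolerance = 0.05 / 0.5)

  # with a contrast effect the MZ and DZ observed variances separate
  v_mz <- var(c(td$y1[td$zygosity == "MZ"], td$y2[td$zygosity == "MZ"]), na.rm = TRUE)
  v_dz <- var(c(td$y1[td$zygosity == "DZ"], td$y2[td$zygosity == "DZ"]), na.rm = TRUE)
  expect_gt(abs(v_mz - v_dz) / v_dz, 0.02)
})

test_that("FIML uses half-missing pairs and agrees with complete-case deletion under MCAR", {
  cfg <- twin_config(4000, a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 76,
                     missing_rate = 0.2)
  co <- simulate_cohort(cfg)
  td <- make_twin_dataset(co, "cp_age9_parent", covariates = NULL)
  expect_gt(td$n_pairs <- length(td$y1), sum(!is.na(td$y1) & !is.na(td$y2)))
  fit_fiml <- fit_twin_model(td, "ACE", seed = 77)

  cc <- co[!is.na(co$cp_age9_parent), ]
  keep <- names(which(table(cc$family_id) == 2))
  cc <- cc[cc$family_id %in% keep, ]
  td_cc <- make_twin_dataset(cc, "cp_age9_parent", covariates = NULL)
  fit_cc <- fit_twin_model(td_cc, "ACE", seed = 78)
  expect_lt(abs(fit_fiml$a2 - fit_cc$a2), 0.06)
  expect_lt(abs(fit_fiml$c2 - fit_cc$c2), 0.06)
})

test_that("covariates in the means model are estimated inside the likelihood", {
  cfg <- sim_config(n_pairs_dz = 3000, n_pairs_mz = 3000, beta_direct = 0,
                    var_a_residual = 0.5, var_c = 0.2, var_specific = 0,
                    missing_rate = 0, ages = 9, reporters = "parent",
                    n_items_per_timepoint = 0, seed = 79, standardize = FALSE)
  co <- simulate_cohort(cfg)
  co$cp_age9_parent <- co$cp_age9_parent + 0.5 * co$sex
  td <- make_twin_dataset(co, "cp_age9_parent", covariates = "sex")
  fit <- fit_twin_model(td, "ACE", seed = 80)
  expect_equal(unname(fit$beta["sex"]), 0.5, tolerance = 0.05 / 0.5)
  expect_equal(fit$a2, 0.5, tolerance = 0.1 / 0.5)
})

test_that("component confidence intervals are well-formed", {
  co <- simulate_cohort(twin_config(2000, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                                    seed = 81))
  td <- make_twin_dataset(co, "cp_age9_parent", covariates = NULL)
  fit <- fit_twin_model(td, "ACE", ci_method = "delta", seed = 82)
  ci <- fit$ci
  expect_setequal(ci$component, c("a2", "c2", "e2"))
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  expect_true(all(ci$lower >= 0 & ci$upper <= 1))
  expect_true(ci$lower[ci$component == "a2"] > 0)  # a2 = 0.5 well away from 0
})
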