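# Shared fixtures: lean single-cell cohorts for estimator-recovery checks, and
# the closed-form oracles the fits are compared against.

# One (age 9, parent) measure with no occasion noise, no covariates, no items,
# no missingness: the phenotype IS the core, so the within/between algebra has
# its closed form.
lean_config <- function(n_pairs_dz, beta_direct = 0, eta_nurture = 0,
                        n_pairs_mz = 0, seed = 1L, ...) {
  sim_config(n_pairs_dz = n_pairs_dz, n_pairs_mz = n_pairs_mz,
             beta_direct = beta_direct, eta_nurture = eta_nurture,
             r_assortment = 0, n_strata = 1,
             var_a_residual = 0, var_c = 0, var_specific = 0,
             missing_rate = 0, n_items_per_timepoint = 0,
             ages = 9, reporters = "parent",
             include_covariates = FALSE, seed = seed, ...)
}

# Twin-model generator: variance components only, both zygosities, one cell.
twin_config <- function(n_pairs, a2 = 0, c2 = 0, d2 = 0, e2 = NULL,
                        s_contrast = 0, seed = 1L, missing_rate = 0, ...) {
  sim_config(n_pairs_dz = n_pairs, n_pairs_mz = n_pairs,
             beta_direct = 0, eta_nurture = 0, r_assortment = 0,
             var_a_residual = a2, var_c = c2, var_d = d2, var_e = e2,
             var_specific = 0, s_contrast = s_contrast,
             missing_rate = missing_rate, n_items_per_timepoint = 0,
             ages = 9, reporters = "parent",
             include_covariates = FALSE, seed = seed, ...)
}

# Independent normal-equations OLS oracle (direct matrix algebra, no QR).
ols_oracle <- function(X, y) solve(t(X) %*% X) %*% (t(X) %*% y)

# Independent scalar-loop bivariate/univariate normal log-density oracle for
# the twin FIML likelihood.
twin_loglik_oracle <- function(data, mu1, mu2, Sigma_mz, Sigma_dz) {
  ll <- 0
  for (i in seq_along(data$y1)) {
    S <- if (data$zygosity[i] == "MZ") Sigma_mz else Sigma_dz
    y1 <- data$y1[i]; y2 <- data$y2[i]
    if (!is.na(y1) && !is.na(y2)) {
      r <- c(y1 - mu1[i], y2 - mu2[i])
      ll <- ll - log(2 * pi) - 0.5 * log(det(S)) -
        0.5 * as.numeric(t(r) %*% solve(S) %*% r)
    } else if (!is.na(y1)) {
      ll <- ll + dnorm(y1, mu1[i], sqrt(S[1, 1]), log = TRUE)
    } else if (!is.na(y2)) {
      ll <- ll + dnorm(y2, mu2[i], sqrt(S[2, 2]), log = TRUE)
    }
  }
  ll
}

# Closed-form multivariate normal log-likelihood oracle for the factor model
# on complete data.
mvn_loglik_oracle <- function(X, mu, Sigma) {
  k <- ncol(X)
  ll <- 0
  Si <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  for (i in seq_len(nrow(X))) {
    r <- as.numeric(X[i, ]) - mu
    ll <- ll - 0.5 * (k * log(2 * pi) + ld + as.numeric(t(r) %*% Si %*% r))
  }
  as.numeric(ll)
}
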