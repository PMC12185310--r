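#' Generative configuration for a synthetic twin cohort
#'
#' Bundles every parameter of the twin-cohort generator: sample sizes, the
#' direct genetic effect of the child's own polygenic score (PGS), the genetic
#' nurture path from each parent's PGS, spousal assortment, population
#' stratification, shared/non-shared environment, an optional sibling-contrast
#' effect, the longitudinal item measurement model, covariate confounding and
#' missingness. The defaults describe a plausible externalising-type phenotype:
#' a modest direct effect (about 1.4% of variance at the population level), a
#' small genetic-nurture path, mild assortment, and noisy cross-sectional
#' measures of a stable underlying trait.
#'
#' Variance accounting: the stable core of the phenotype is
#' `beta_direct * PGS + A_res + eta_nurture * (PGS_mother + PGS_father) +
#' stratum environmental offset + C + D + E`, with `A_res ~ N(0,
#' var_a_residual)` the PGS-untagged additive genetic deviation, `C ~ N(0,
#' var_c)` shared by co-twins, `D` the dominance deviation and `E ~ N(0,
#' var_e)` individual. When `var_e` is `NULL` it is completed so that the
#' theoretical core variance equals 1 (accounting for the variance induced by
#' nurture, assortment and any SES path). Each observed phenotype adds an
#' occasion/reporter-specific deviation with variance `var_specific`.
#'
#' @param n_pairs_dz,n_pairs_mz number of dizygotic / monozygotic twin pairs.
#' @param beta_direct standardized effect of a child's own PGS on the phenotype.
#' @param eta_nurture standardized effect of each parent's PGS on the child
#'   phenotype via the rearing environment (genetic nurture).
#' @param r_assortment spousal PGS correlation, in `[0, 0.99]`.
#' @param n_strata number of subpopulations.
#' @param strata_pgs_shift per-stratum parental-PGS mean offset; a scalar is
#'   expanded to centred, equally spaced offsets across strata.
#' @param strata_env_shift per-stratum phenotypic environmental offset, same
#'   expansion rule.
#' @param var_a_residual additive genetic variance of the phenotype core not
#'   captured by the measured PGS (the PGS is a weak proxy of the full
#'   breeding value: twin-model heritability can greatly exceed the variance
#'   the PGS explains). Shared fully by MZ co-twins, correlated 0.5 in DZ
#'   pairs, and independent of the parental PGS.
#' @param var_c shared-environment variance of the phenotype core.
#' @param var_d dominance variance (MZ share it fully, DZ share 1/4).
#' @param var_e non-shared variance of the core; `NULL` completes to unit core
#'   variance.
#' @param var_specific occasion/reporter-specific phenotype variance on top of
#'   the stable core.
#' @param s_contrast sibling-interaction (contrast) coefficient in `(-1, 1)`;
#'   each pair's phenotype vector is passed through `(I - sB)^{-1}` with `B`
#'   the co-twin swap matrix.
#' @param beta_ses_pheno environmental effect of the family SES variable on the
#'   phenotype core (used to build SES-mediated indirect effects).
#' @param trait short trait label used in column names (e.g. `"cp"`).
#' @param ages numeric vector of assessment ages (waves).
#' @param reporters character vector of reporters per wave.
#' @param n_items_per_timepoint items emitted per (age, reporter) cell.
#' @param loadings item factor loadings on the stable core; recycled to
#'   `n_items_per_timepoint`.
#' @param theta item uniqueness variances; `NULL` completes each item to unit
#'   variance given its loading and the reporter/age components (floored at
#'   0.05).
#' @param var_reporter,var_age variance of reporter-specific and age-specific
#'   item components (what makes reporter-/age-specific factors distinguishable
#'   from the common factor).
#' @param missing_rate MCAR missingness probability applied per phenotype and
#'   item entry.
#' @param age_sampling_fraction optional named vector of per-age family
#'   sampling fractions (e.g. `c("9" = 0.5)` halves the effective sample at
#'   age 9, mimicking a half-size wave).
#' @param conf_ses_loading effect of the midparent PGS on the family SES
#'   covariate (the gene-environment correlation carried by SES).
#' @param parenting_pgs_cor correlation of the latent parenting factor with the
#'   (standardized) midparent PGS.
#' @param n_parenting_items,parenting_loading parenting measurement model:
#'   items per parenting wave and their loading on the parenting factor.
#' @param include_covariates generate the covariate block (demographics, PCs,
#'   SES, deprivation, parenting items). Disable for large estimator-recovery
#'   simulations that fit covariate-free models.
#' @param standardize if `TRUE` (default), PGS and phenotype columns are
#'   z-scored on the generated sample.
#' @param seed integer seed making the whole cohort reproducible.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pairs_dz = 2000,
                       n_pairs_mz = 1000,
                       beta_direct = 0.12,
                       eta_nurture = 0.02,
                       r_assortment = 0.10,
                       n_strata = 1,
                       strata_pgs_shift = 0,
                       strata_env_shift = 0,
                       var_a_residual = 0.45,
                       var_c = 0.15,
                       var_d = 0,
                       var_e = NULL,
                       var_specific = 0.4,
                       s_contrast = 0,
                       beta_ses_pheno = 0,
                       trait = "cp",
                       ages = c(4, 7, 9),
                       reporters = c("parent", "teacher"),
                       n_items_per_timepoint = 4,
                       loadings = c(0.8, 0.7, 0.6, 0.5),
                       theta = NULL,
                       var_reporter = 0.10,
                       var_age = 0.10,
                       missing_rate = 0.10,
                       age_sampling_fraction = NULL,
                       conf_ses_loading = 0.25,
                       parenting_pgs_cor = 0.2,
                       n_parenting_items = 4,
                       parenting_loading = 0.7,
                       include_covariates = TRUE,
                       standardize = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_pairs_dz = n_pairs_dz, n_pairs_mz = n_pairs_mz,
    beta_direct = beta_direct, eta_nurture = eta_nurture,
    r_assortment = r_assortment,
    n_strata = n_strata,
    strata_pgs_shift = strata_pgs_shift,
    strata_env_shift = strata_env_shift,
    var_a_residual = var_a_residual,
    var_c = var_c, var_d = var_d, var_e = var_e,
    var_specific = var_specific,
    s_contrast = s_contrast,
    beta_ses_pheno = beta_ses_pheno,
    trait = trait, ages = ages, reporters = reporters,
    n_items_per_timepoint = n_items_per_timepoint,
    loadings = rep_len(loadings, n_items_per_timepoint),
    theta = if (!is.null(theta)) rep_len(theta, n_items_per_timepoint),
    var_reporter = var_reporter, var_age = var_age,
    missing_rate = missing_rate,
    age_sampling_fraction = age_sampling_fraction,
    conf_ses_loading = conf_ses_loading,
    parenting_pgs_cor = parenting_pgs_cor,
    n_parenting_items = n_parenting_items,
    parenting_loading = parenting_loading,
    include_covariates = isTRUE(include_covariates),
    standardize = isTRUE(standardize),
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$n_pairs_dz < 0 || cfg$n_pairs_mz < 0 ||
      cfg$n_pairs_dz + cfg$n_pairs_mz < 1) {
    stopf("need at least one twin pair")
  }
  if (cfg$r_assortment < 0 || cfg$r_assortment > 0.99) {
    stopf("r_assortment must lie in [0, 0.99], got %g", cfg$r_assortment)
  }
  if (abs(cfg$s_contrast) >= 1) {
    stopf("|s_contrast| must be < 1 for the reciprocal-interaction transform to be invertible, got %g",
          cfg$s_contrast)
  }
  for (v in c("var_a_residual", "var_c", "var_d", "var_specific", "var_reporter", "var_age")) {
    if (cfg[[v]] < 0) stopf("%s must be >= 0", v)
  }
  if (!is.null(cfg$var_e) && cfg$var_e < 0) stopf("var_e must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stopf("missing_rate must lie in [0, 1)")
  }
  if (cfg$n_strata < 1) stopf("n_strata must be >= 1")
  if (!is.null(cfg$seed) && (cfg$seed < 0 || cfg$seed > 2^31 - 100)) {
    stopf("seed must be a non-negative integer below 2^31 - 100")
  }
  if (is.null(cfg$var_e)) {
    ve <- 1 - core_structural_variance(cfg) - cfg$var_a_residual - cfg$var_c - cfg$var_d
    if (ve < 0) {
      stopf("var_e is NULL but structural + C + D variance exceeds 1 (%.3f); supply var_e explicitly",
            1 - ve)
    }
  }
  config
}

# Theoretical variance of the structural (genetic + nurture + SES-path) part of
# the phenotype core, used to complete var_e to a unit-variance core.
# With parental PGS variance 1 and spousal correlation r:
#   Var(child PGS)      = (1 + r)/2 + 1/2 = 1 + r/2
#   Var(PGS_m + PGS_f)  = 2 (1 + r)
#   Cov(child, m + f)   = 1 + r
# The SES path adds beta_ses^2 * Var(ses) + cross-covariances through the
# midparent PGS (ses = conf * midparent + noise, Var(ses) = conf^2*(1+r)/2 + 1).
core_structural_variance <- function(cfg) {
  b <- cfg$beta_direct; eta <- cfg$eta_nurture; r <- cfg$r_assortment
  g <- cfg$beta_ses_pheno; conf <- cfg$conf_ses_loading
  v_pgs <- 1 + r / 2
  v_mf <- 2 * (1 + r)
  c_pm <- 1 + r
  v_mid <- (1 + r) / 2
  v_ses <- conf^2 * v_mid + 1
  c_pgs_ses <- conf * v_mid          # Cov(child PGS, ses) via midparent
  c_mf_ses <- conf * (1 + r)         # Cov(m + f, ses)
  b^2 * v_pgs + eta^2 * v_mf + 2 * b * eta * c_pm +
    g^2 * v_ses + 2 * b * g * c_pgs_ses + 2 * eta * g * c_mf_ses
}

# Resolved non-shared core variance.
resolve_var_e <- function(cfg) {
  cfg$var_e %||%
    (1 - core_structural_variance(cfg) - cfg$var_a_residual - cfg$var_c - cfg$var_d)
}

expand_stratum_shift <- function(shift, n_strata) {
  if (length(shift) == n_strata) return(as.numeric(shift))
  if (length(shift) == 1) {
    if (n_strata == 1) return(0)
    idx <- seq_len(n_strata)
    return(as.numeric(shift) * (idx - mean(idx)))
  }
  stopf("stratum shift must have length 1 or n_strata (%d)", n_strata)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  pairs: %d DZ + %d MZ; trait '%s', ages {%s}, reporters {%s}\n",
              x$n_pairs_dz, x$n_pairs_mz, x$trait,
              paste(x$ages, collapse = ","), paste(x$reporters, collapse = ",")))
  cat(sprintf("  beta_direct=%.3f eta_nurture=%.3f r_assortment=%.2f n_strata=%d\n",
              x$beta_direct, x$eta_nurture, x$r_assortment, x$n_strata))
  cat(sprintf("  var_a_residual=%.3f var_c=%.3f var_d=%.3f var_e=%.3f var_specific=%.3f s_contrast=%.2f\n",
              x$var_a_residual, x$var_c, x$var_d, resolve_var_e(x), x$var_specific, x$s_contrast))
  cat(sprintf("  missing_rate=%.2f seed=%s\n", x$missing_rate,
              format(x$seed %||% "none")))
  invisible(x)
}
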