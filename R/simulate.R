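#' Simulate parental polygenic scores with assortment and stratification
#'
#' Draws one mother/father PGS pair per family from a bivariate normal with
#' spousal correlation `r_assortment` (unit marginal variances), then offsets
#' the means per stratum. Assortment is a one-generation spousal correlation on
#' the PGS scale, not iterated to mating equilibrium: one generation is what is
#' needed to inflate the between-family PGS variance that the within/between
#' decomposition must detect.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per family: `family_id`, `zygosity`,
#'   `stratum`, `pgs_mother`, `pgs_father`.
#' @export
simulate_parents <- function(config) {
  cfg <- validate_sim_config(config)
  n <- cfg$n_pairs_dz + cfg$n_pairs_mz
  r <- cfg$r_assortment
  with_seed(derive_seed(cfg$seed, 1L), {
    mother <- stats::rnorm(n)
    father <- r * mother + sqrt(1 - r^2) * stats::rnorm(n)
    stratum <- sample.int(cfg$n_strata, n, replace = TRUE)
    shift <- expand_stratum_shift(cfg$strata_pgs_shift, cfg$n_strata)
    mother <- mother + shift[stratum]
    father <- father + shift[stratum]
    zyg <- rep(c("DZ", "MZ"), c(cfg$n_pairs_dz, cfg$n_pairs_mz))
    data.frame(
      family_id = seq_len(n),
      zygosity = zyg,
      stratum = stratum,
      pgs_mother = mother,
      pgs_father = father
    )
  })
}

#' Simulate offspring polygenic scores from parental scores
#'
#' Each child's PGS is the midparent value plus an independent segregation
#' (Mendelian sampling) deviation with variance equal to half the population
#' additive variance. MZ co-twins share a single draw; DZ co-twins get
#' independent deviations, giving within-pair PGS correlations of 1 (MZ) and,
#' absent assortment, 0.5 (DZ). Under spousal correlation `r` the DZ
#' correlation rises to `(1 + r) / (2 + r)` because the midparent (covariance)
#' term gains variance `(1 + r)/2` while each child's total variance is
#' `1 + r/2`.
#'
#' @param parents output of [simulate_parents()].
#' @param config the same [sim_config()].
#' @return person-level data.frame (two rows per family): `person_id`,
#'   `family_id`, `twin_index`, `zygosity`, `pgs`, plus simulation-only
#'   ground-truth columns prefixed `sim_`.
#' @export
simulate_offspring_pgs <- function(parents, config) {
  cfg <- validate_sim_config(config)
  if (!all(c("family_id", "zygosity", "pgs_mother", "pgs_father") %in% names(parents))) {
    stopf("parents table is incomplete")
  }
  bad <- setdiff(unique(parents$zygosity), c("MZ", "DZ"))
  if (length(bad)) stopf("unknown zygosity label(s): %s", paste(bad, collapse = ", "))
  n <- nrow(parents)
  with_seed(derive_seed(cfg$seed, 2L), {
    mid <- (parents$pgs_mother + parents$pgs_father) / 2
    dev1 <- stats::rnorm(n, sd = sqrt(0.5))
    dev2 <- dev1                                   # MZ share the draw
    dz <- parents$zygosity == "DZ"
    dev2[dz] <- stats::rnorm(sum(dz), sd = sqrt(0.5))
    g1 <- mid + dev1
    g2 <- mid + dev2
    out <- data.frame(
      person_id = sprintf("F%06d_T%d", rep(parents$family_id, each = 2),
                          rep(1:2, n)),
      family_id = rep(parents$family_id, each = 2),
      twin_index = rep(1:2, n),
      zygosity = rep(parents$zygosity, each = 2),
      pgs = as.vector(rbind(g1, g2)),
      sim_stratum = rep(parents$stratum, each = 2),
      sim_pgs_mother = rep(parents$pgs_mother, each = 2),
      sim_pgs_father = rep(parents$pgs_father, each = 2)
    )
    out
  })
}

#' Simulate covariates: demographics, ancestry PCs, SES, deprivation, parenting
#'
#' Builds the covariate set consumed by the regression models: per-wave age
#' (family-level jitter around the nominal age), balanced sex, a binary
#' genotyping-platform indicator, ten ancestry principal components (PC1
#' carries the stratification signal when `n_strata > 1`), a family-level SES
#' variable loaded on the midparent PGS (`conf_ses_loading`, the
#' gene-environment correlation SES carries), a neighbourhood-deprivation
#' decile (ordinal 1-10 discretization of a latent negatively correlated with
#' SES), and family-level parenting items generated from a one-factor model
#' whose factor correlates with the midparent PGS.
#'
#' @inheritParams simulate_offspring_pgs
#' @param cohort person-level table from [simulate_offspring_pgs()].
#' @return `cohort` with covariate columns appended.
#' @export
simulate_covariates <- function(cohort, parents, config) {
  cfg <- validate_sim_config(config)
  n_fam <- nrow(parents)
  n <- nrow(cohort)
  with_seed(derive_seed(cfg$seed, 3L), {
    fam_of <- match(cohort$family_id, parents$family_id)
    mid <- (parents$pgs_mother + parents$pgs_father) / 2

    for (a in cfg$ages) {
      cohort[[paste0("age_", a)]] <- (a + stats::runif(n_fam, -0.5, 0.5))[fam_of]
    }
    cohort$sex <- stats::rbinom(n, 1, 0.5)
    cohort$platform <- stats::rbinom(n_fam, 1, 0.5)[fam_of]

    stratum_code <- parents$stratum - mean(parents$stratum)
    pc1 <- if (cfg$n_strata > 1 && stats::sd(stratum_code) > 0) {
      stratum_code / stats::sd(stratum_code) + stats::rnorm(n_fam, sd = 0.3)
    } else {
      stats::rnorm(n_fam)
    }
    cohort$pc1 <- pc1[fam_of]
    for (k in 2:10) {
      cohort[[paste0("pc", k)]] <- stats::rnorm(n_fam)[fam_of]
    }

    ses <- cfg$conf_ses_loading * mid + stats::rnorm(n_fam)
    cohort$ses <- ses[fam_of]
    ses_z <- (ses - mean(ses)) / stats::sd(ses)
    dep <- -0.6 * ses_z + sqrt(1 - 0.36) * stats::rnorm(n_fam)
    decile <- as.integer(cut(dep, stats::quantile(dep, probs = seq(0, 1, 0.1)),
                             include.lowest = TRUE, labels = FALSE))
    cohort$imd_decile <- decile[fam_of]

    rho <- cfg$parenting_pgs_cor
    mid_z <- (mid - mean(mid)) / stats::sd(mid)
    pfac <- rho * mid_z + sqrt(1 - rho^2) * stats::rnorm(n_fam)
    lam <- cfg$parenting_loading
    par_ages <- intersect(cfg$ages, c(4, 7, 9, 12))
    if (!length(par_ages)) par_ages <- cfg$ages[1]
    for (a in par_ages) {
      for (k in seq_len(cfg$n_parenting_items)) {
        item <- lam * pfac + sqrt(max(1 - lam^2, 0.05)) * stats::rnorm(n_fam)
        cohort[[sprintf("parenting_age%s_item%d", a, k)]] <- item[fam_of]
      }
    }
    cohort$sim_parenting_factor <- pfac[fam_of]
    cohort
  })
}

# Reciprocal sibling-interaction transform (I - sB)^{-1} applied to per-pair
# columns y1, y2 (B swaps co-twins).
contrast_transform <- function(y1, y2, s) {
  if (s == 0) return(list(y1 = y1, y2 = y2))
  d <- 1 - s^2
  list(y1 = (y1 + s * y2) / d, y2 = (y2 + s * y1) / d)
}

#' Simulate phenotypes with direct, nurture, environmental and contrast effects
#'
#' The stable phenotype core is
#' `beta_direct * PGS + A_res + eta_nurture * (PGS_m + PGS_f) +
#' beta_ses_pheno * ses + stratum offset + C + D + E` with `A_res` the
#' residual (PGS-untagged) additive genetic deviation (shared by MZ,
#' correlated 0.5 in DZ), `C` shared by co-twins, `D` a dominance deviation
#' (shared by MZ, correlated 1/4 in DZ) and `E` individual. Each
#' observed measure (trait x age x reporter) adds an independent specific
#' deviation with variance `var_specific`; when `s_contrast != 0` each pair's
#' measure vector is passed through the reciprocal-interaction transform
#' `(I - sB)^{-1}`. Measures are finally MCAR-masked at `missing_rate`
#' (plus any per-age family sampling fraction) and z-scored if
#' `config$standardize` is set. The true core is recorded in `sim_true_factor`.
#'
#' @inheritParams simulate_covariates
#' @return `cohort` with one phenotype column per (trait, age, reporter) cell.
#' @export
simulate_phenotypes <- function(cohort, parents, config) {
  cfg <- validate_sim_config(config)
  if (!"pgs" %in% names(cohort)) stopf("PGS column missing; run simulate_offspring_pgs first")
  if (cfg$beta_ses_pheno != 0 && !"ses" %in% names(cohort)) {
    stopf("beta_ses_pheno != 0 requires the ses covariate; run simulate_covariates first")
  }
  n_fam <- nrow(parents)
  with_seed(derive_seed(cfg$seed, 4L), {
    fam_of <- match(cohort$family_id, parents$family_id)
    i1 <- which(cohort$twin_index == 1)
    i2 <- which(cohort$twin_index == 2)

    env_shift <- expand_stratum_shift(cfg$strata_env_shift, cfg$n_strata)
    var_e <- resolve_var_e(cfg)

    n_row <- nrow(cohort)
    is_dz <- cohort$zygosity == "DZ"
    # genetic/environmental deviations with the pedigree correlation pattern:
    # shared value for MZ; partially shared for DZ (0.5 for residual additive,
    # 0.25 for dominance)
    share_component <- function(v, dz_share) {
      if (v == 0) return(0)
      fam_val <- stats::rnorm(n_fam, sd = sqrt(v))[fam_of]
      out <- fam_val
      ndz <- sum(is_dz)
      out[is_dz] <- sqrt(dz_share) * fam_val[is_dz] +
        sqrt(1 - dz_share) * stats::rnorm(ndz, sd = sqrt(v))
      out
    }
    C_fam <- stats::rnorm(n_fam, sd = sqrt(cfg$var_c))
    A_res <- share_component(cfg$var_a_residual, 0.5)
    D <- share_component(cfg$var_d, 0.25)
    E <- stats::rnorm(n_row, sd = sqrt(var_e))

    core <- A_res + cfg$beta_direct * cohort$pgs +
      cfg$eta_nurture * (cohort$sim_pgs_mother + cohort$sim_pgs_father) +
      env_shift[cohort$sim_stratum] +
      C_fam[fam_of] + D + E
    if (cfg$beta_ses_pheno != 0) core <- core + cfg$beta_ses_pheno * cohort$ses
    cohort$sim_true_factor <- core

    drop_age <- age_dropout_families(cfg, n_fam)
    for (a in cfg$ages) {
      for (rep_ in cfg$reporters) {
        col <- phenotype_column(cfg$trait, a, rep_)
        spec <- stats::rnorm(nrow(cohort), sd = sqrt(cfg$var_specific))
        y <- core + spec
        tr <- contrast_transform(y[i1], y[i2], cfg$s_contrast)
        y[i1] <- tr$y1; y[i2] <- tr$y2
        if (cfg$missing_rate > 0) {
          y[stats::runif(length(y)) < cfg$missing_rate] <- NA_real_
        }
        if (!is.null(drop_age[[as.character(a)]])) {
          y[fam_of %in% drop_age[[as.character(a)]]] <- NA_real_
        }
        if (cfg$standardize) y <- zscore(y)
        cohort[[col]] <- y
      }
    }
    cohort
  })
}

# Families dropped wholesale per age (half-size waves etc.); returns a list
# keyed by age of family indices to blank. Seeded on its own sub-stream so the
# phenotype and item stages blank the same families.
age_dropout_families <- function(cfg, n_fam) {
  fr <- cfg$age_sampling_fraction
  if (is.null(fr)) return(list())
  with_seed(derive_seed(cfg$seed, 6L), {
    out <- list()
    for (a in names(fr)) {
      keep <- fr[[a]]
      if (keep < 1) {
        out[[a]] <- sample.int(n_fam, size = round((1 - keep) * n_fam))
      }
    }
    out
  })
}

#' Simulate item-level responses loading on the stable latent trait
#'
#' Each item in cell (trait, age, reporter) is
#' `loading_k * latent + reporter component + age component + uniqueness`,
#' where the latent is the stable phenotype core, the reporter/age components
#' are person-level draws shared by all items of the same reporter/age (making
#' reporter- and age-specific factors distinguishable from the common factor),
#' and uniquenesses default to completing each item to unit variance. MCAR
#' missingness is applied per entry at `missing_rate`.
#'
#' @inheritParams simulate_covariates
#' @return `cohort` with item columns `<trait>_age<age>_<reporter>_item<k>`.
#' @export
simulate_items <- function(cohort, config) {
  cfg <- validate_sim_config(config)
  if (cfg$n_items_per_timepoint < 1) return(cohort)
  if (!"sim_true_factor" %in% names(cohort)) {
    stopf("latent trait missing; run simulate_phenotypes first")
  }
  if (length(cfg$loadings) != cfg$n_items_per_timepoint) {
    stopf("loadings length (%d) must equal n_items_per_timepoint (%d)",
          length(cfg$loadings), cfg$n_items_per_timepoint)
  }
  n <- nrow(cohort)
  lam <- cfg$loadings
  theta <- cfg$theta %||% pmax(1 - lam^2 - cfg$var_reporter - cfg$var_age, 0.05)
  with_seed(derive_seed(cfg$seed, 5L), {
    latent <- cohort$sim_true_factor
    rep_comp <- lapply(cfg$reporters, function(r)
      stats::rnorm(n, sd = sqrt(cfg$var_reporter)))
    names(rep_comp) <- cfg$reporters
    age_comp <- lapply(as.character(cfg$ages), function(a)
      stats::rnorm(n, sd = sqrt(cfg$var_age)))
    names(age_comp) <- as.character(cfg$ages)
    n_fam <- length(unique(cohort$family_id))
    drop_age <- age_dropout_families(cfg, n_fam)
    fam_of <- match(cohort$family_id, unique(cohort$family_id))
    for (a in cfg$ages) {
      for (rep_ in cfg$reporters) {
        for (k in seq_len(cfg$n_items_per_timepoint)) {
          item <- lam[k] * latent + rep_comp[[rep_]] + age_comp[[as.character(a)]] +
            stats::rnorm(n, sd = sqrt(theta[k]))
          if (cfg$missing_rate > 0) {
            item[stats::runif(n) < cfg$missing_rate] <- NA_real_
          }
          if (!is.null(drop_age[[as.character(a)]])) {
            item[fam_of %in% drop_age[[as.character(a)]]] <- NA_real_
          }
          cohort[[paste0(phenotype_column(cfg$trait, a, rep_), "_item", k)]] <- item
        }
      }
    }
    cohort
  })
}

#' Generate a complete synthetic twin cohort
#'
#' Composes [simulate_parents()], [simulate_offspring_pgs()],
#' [simulate_covariates()], [simulate_phenotypes()] and [simulate_items()].
#' The PGS column is z-scored on the generated sample when
#' `config$standardize` is `TRUE`. The configuration and generative ground
#' truth are attached as attributes `sim_config` and `sim_truth`; ground-truth
#' columns are prefixed `sim_` so estimators cannot silently pick them up.
#'
#' @param config a [sim_config()].
#' @return a cohort data.frame (two rows per family) of class `twin_cohort`.
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  parents <- simulate_parents(cfg)
  cohort <- simulate_offspring_pgs(parents, cfg)
  if (cfg$include_covariates) {
    cohort <- simulate_covariates(cohort, parents, cfg)
  }
  cohort <- simulate_phenotypes(cohort, parents, cfg)
  cohort <- simulate_items(cohort, cfg)
  if (cfg$standardize) cohort$pgs <- zscore(cohort$pgs)
  attr(cohort, "sim_config") <- cfg
  attr(cohort, "sim_truth") <- list(
    beta_direct = cfg$beta_direct,
    eta_nurture = cfg$eta_nurture,
    indirect_between_minus_within = 4 / 3 * cfg$eta_nurture,
    var_c = cfg$var_c, var_d = cfg$var_d, var_e = resolve_var_e(cfg),
    s_contrast = cfg$s_contrast
  )
  class(cohort) <- c("twin_cohort", "data.frame")
  cohort
}

phenotype_column <- function(trait, age, reporter) {
  sprintf("%s_age%s_%s", trait, age, reporter)
}

# Parse "<trait>_age<age>_<reporter>" into its tags (NULL if not a phenotype
# column name).
parse_phenotype_column <- function(col) {
  m <- regmatches(col, regexec("^([A-Za-z0-9]+)_age([0-9]+)_([A-Za-z]+)$", col))[[1]]
  if (!length(m)) return(NULL)
  list(trait = m[2], age = as.numeric(m[3]), reporter = m[4])
}

# Item columns for a trait, optionally restricted by age / reporter.
item_columns <- function(cohort, trait, ages = NULL, reporters = NULL) {
  cols <- grep(sprintf("^%s_age[0-9]+_[A-Za-z]+_item[0-9]+$", trait),
               names(cohort), value = TRUE)
  if (!is.null(ages)) {
    cols <- cols[grepl(sprintf("_age(%s)_", paste(ages, collapse = "|")), cols)]
  }
  if (!is.null(reporters)) {
    cols <- cols[grepl(sprintf("_(%s)_item", paste(reporters, collapse = "|")), cols)]
  }
  cols
}

#' Write / read a cohort as TSV with a YAML sidecar
#'
#' The sidecar (`<path>.yaml`) records the generating configuration and ground
#' truth, so a cohort on disk round-trips with its provenance.
#'
#' @param cohort a cohort data.frame.
#' @param path TSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort with attributes restored when the sidecar is present.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- attr(cohort, "sim_config")
  if (!is.null(cfg)) {
    side <- list(sim_config = unclass(cfg), sim_truth = attr(cohort, "sim_truth"))
    yaml::write_yaml(side, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  side_path <- paste0(path, ".yaml")
  if (file.exists(side_path)) {
    side <- yaml::read_yaml(side_path)
    if (!is.null(side$sim_config)) {
      cfg <- side$sim_config
      class(cfg) <- "sim_config"
      attr(cohort, "sim_config") <- cfg
    }
    attr(cohort, "sim_truth") <- side$sim_truth
  }
  class(cohort) <- c("twin_cohort", "data.frame")
  cohort
}
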