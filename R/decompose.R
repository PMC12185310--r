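#' Construct within- and between-family polygenic scores
#'
#' The between-family score is the twin-pair mean PGS; the within-family score
#' is the individual's PGS minus that mean, so for a DZ pair the two within
#' scores are equal and opposite. Families without exactly two genotyped
#' members are excluded (their count is reported in the
#' `dropped_families` attribute and a message).
#'
#' @param cohort person-level data.frame with `family_id` and `pgs`.
#' @return cohort restricted to usable families, with `pgs_between` and
#'   `pgs_within` columns; attribute `all_mz` flags a design where the within
#'   score is identically zero.
#' @export
build_family_scores <- function(cohort) {
  n <- nrow(cohort)
  # fast path: rows already come as complete genotyped consecutive pairs
  odd <- seq(1, n - 1, 2); even <- odd + 1L
  paired <- n %% 2 == 0 && !anyNA(cohort$pgs) &&
    all(cohort$family_id[odd] == cohort$family_id[even]) &&
    !anyDuplicated(cohort$family_id[odd])
  if (paired) {
    out <- cohort
    fmean <- rep((cohort$pgs[odd] + cohort$pgs[even]) / 2, each = 2)
    n_dropped <- 0L
  } else {
    has_pgs <- !is.na(cohort$pgs)
    cnt <- table(cohort$family_id[has_pgs])
    good <- names(cnt)[cnt == 2]
    n_dropped <- length(unique(cohort$family_id)) - length(good)
    if (n_dropped > 0) {
      message(sprintf("build_family_scores: excluded %d famil%s without exactly 2 genotyped members",
                      n_dropped, if (n_dropped == 1) "y" else "ies"))
    }
    out <- cohort[cohort$family_id %in% good & has_pgs, , drop = FALSE]
    fam <- factor(out$family_id, levels = unique(out$family_id))
    fmean <- stats::ave(out$pgs, fam)
  }
  out$pgs_between <- fmean
  out$pgs_within <- out$pgs - fmean
  attr(out, "dropped_families") <- n_dropped
  all_mz <- all(abs(out$pgs_within) < 1e-12)
  attr(out, "all_mz") <- all_mz
  if (all_mz) {
    message("build_family_scores: within-family score is identically zero (all pairs genetically identical)")
  }
  out
}

# Resolve the covariate specification into concrete columns plus interaction
# terms. `covariates = "default"` reproduces the standard adjustment set:
# age at the outcome's wave, sex, age x sex, genotyping platform and the first
# 10 ancestry principal components (whichever are present). Entries containing
# ":" are treated as product terms.
resolve_covariates <- function(cohort, outcome, covariates) {
  if (is.null(covariates)) return(character(0))
  if (identical(covariates, "default")) {
    tags <- parse_phenotype_column(outcome)
    age_col <- if (!is.null(tags)) paste0("age_", tags$age) else "age"
    cand <- c(age_col, "sex", "platform", paste0("pc", 1:10))
    cols <- intersect(cand, names(cohort))
    if (all(c(age_col, "sex") %in% cols)) {
      cols <- c(cols, paste0(age_col, ":sex"))
    }
    return(cols)
  }
  covariates
}

# Build the covariate block of the design matrix: continuous columns are
# z-scored on the analysis rows so slopes are on comparable scales; binary
# columns are left as-is; ":" entries become products of the (standardized)
# main-effect columns.
covariate_matrix <- function(frame, cov_spec) {
  if (!length(cov_spec)) {
    return(matrix(numeric(0), nrow = nrow(frame), ncol = 0))
  }
  main <- cov_spec[!grepl(":", cov_spec, fixed = TRUE)]
  inter <- cov_spec[grepl(":", cov_spec, fixed = TRUE)]
  std <- list()
  for (cl in main) {
    x <- frame[[cl]]
    if (is.null(x)) stopf("covariate column '%s' not found", cl)
    ux <- unique(x[!is.na(x)])
    std[[cl]] <- if (length(ux) > 2) zscore(x) else as.numeric(x)
  }
  for (term in inter) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    vals <- lapply(parts, function(p) {
      std[[p]] %||% {
        x <- frame[[p]]
        if (is.null(x)) stopf("covariate column '%s' not found", p)
        ux <- unique(x[!is.na(x)])
        if (length(ux) > 2) zscore(x) else as.numeric(x)
      }
    })
    std[[term]] <- Reduce(`*`, vals)
  }
  out <- do.call(cbind, std)
  colnames(out) <- names(std)
  out
}

# Shared preprocessing: resolve covariates, listwise-delete, z-score outcome,
# and assemble design pieces. `within_between` switches the PGS predictors.
prepare_decomposition <- function(cohort, outcome, covariates, within_between,
                                  min_n = 30) {
  if (!outcome %in% names(cohort)) stopf("outcome column '%s' not found", outcome)
  cov_spec <- resolve_covariates(cohort, outcome, covariates)
  if (within_between) {
    cohort <- build_family_scores(cohort)
    if (attr(cohort, "all_mz")) {
      stopf("design not identified: the within-family PGS score is identically zero (MZ-only input); the within/between model needs DZ pairs")
    }
  }
  main_cols <- unique(unlist(strsplit(cov_spec, ":", fixed = TRUE)))
  need <- c(outcome, "pgs", main_cols)
  ok <- stats::complete.cases(cohort[, need, drop = FALSE])
  frame <- cohort[ok, , drop = FALSE]
  if (nrow(frame) < min_n) {
    stopf("only %d complete persons for outcome '%s'; refusing to fit (need >= %d)",
          nrow(frame), outcome, min_n)
  }
  y <- zscore(frame[[outcome]])
  Z <- covariate_matrix(frame, cov_spec)
  list(frame = frame, y = y, Z = Z, cov_spec = cov_spec,
       dropped_families = attr(cohort, "dropped_families") %||% 0L)
}

new_decomp_fit <- function(...) structure(list(...), class = "decomp_fit")

#' Fit the population-level polygenic-score model
#'
#' Ordinary least squares of the (z-scored) outcome on the individual PGS plus
#' the covariate set, on complete cases. The PGS coefficient is the
#' population-level effect; `r2_pgs` is the incremental variance explained by
#' the PGS over the covariate-only model on the identical rows.
#'
#' @param cohort person-level data.frame (typically the DZ subset).
#' @param outcome phenotype column name.
#' @param covariates `"default"`, `NULL`, or a character vector of column
#'   names (use `"a:b"` for products).
#' @param min_n refuse to fit below this many complete persons.
#' @return a `decomp_fit` with `beta_population`, `r2_pgs`, coefficients,
#'   `n_persons`, `n_families` and the rows used.
#' @export
fit_population_model <- function(cohort, outcome, covariates = "default",
                                 min_n = 30) {
  prep <- prepare_decomposition(cohort, outcome, covariates,
                                within_between = FALSE, min_n = min_n)
  pgs <- zscore(prep$frame$pgs)
  X <- cbind(`(intercept)` = 1, prep$Z, pgs = pgs)
  fit <- ols_qr(X, prep$y)
  red <- ols_qr(X[, -ncol(X), drop = FALSE], prep$y)
  new_decomp_fit(
    model = "population", outcome = outcome,
    coef = fit$coef,
    beta_population = unname(fit$coef["pgs"]),
    r2_pgs = max(fit$r2 - red$r2, 0),
    r2_full = fit$r2, r2_covariates = red$r2,
    n_persons = nrow(X),
    n_families = length(unique(prep$frame$family_id)),
    rows = prep$frame$person_id %||% rownames(prep$frame),
    covariates = prep$cov_spec,
    X = X, y = prep$y, family = prep$frame$family_id
  )
}

#' Fit the within/between-family polygenic-score model
#'
#' Ordinary least squares of the (z-scored) outcome on the within-family and
#' between-family PGS plus covariates. The within coefficient estimates the
#' direct genetic effect; between minus within is the indirect genetic effect.
#'
#' @inheritParams fit_population_model
#' @return a `decomp_fit` with `beta_within`, `beta_between`, `indirect`.
#' @export
fit_within_between_model <- function(cohort, outcome, covariates = "default",
                                     min_n = 30) {
  prep <- prepare_decomposition(cohort, outcome, covariates,
                                within_between = TRUE, min_n = min_n)
  X <- cbind(`(intercept)` = 1, prep$Z,
             pgs_within = prep$frame$pgs_within,
             pgs_between = prep$frame$pgs_between)
  fit <- ols_qr(X, prep$y)
  bw <- unname(fit$coef["pgs_within"])
  bb <- unname(fit$coef["pgs_between"])
  red <- ols_qr(X[, seq_len(ncol(X) - 2), drop = FALSE], prep$y)
  new_decomp_fit(
    model = "within_between", outcome = outcome,
    coef = fit$coef,
    beta_within = bw, beta_between = bb, indirect = bb - bw,
    r2_pgs = max(fit$r2 - red$r2, 0),
    r2_full = fit$r2, r2_covariates = red$r2,
    n_persons = nrow(X),
    n_families = length(unique(prep$frame$family_id)),
    dropped_families = prep$dropped_families,
    rows = prep$frame$person_id %||% rownames(prep$frame),
    covariates = prep$cov_spec,
    X = X, y = prep$y, family = prep$frame$family_id
  )
}

#' Indirect genetic effect from a within/between fit
#'
#' Defined as the between-family coefficient minus the within-family (direct)
#' coefficient. When a population-level effect is supplied (or present), the
#' indirect share of the total prediction, `indirect / beta_population`, is
#' also returned.
#'
#' @param fit a `decomp_fit` from [fit_within_between_model()].
#' @param beta_population optional population-model effect for the share.
#' @return list with `indirect` and (when available) `share_of_population`.
#' @export
indirect_effect <- function(fit, beta_population = NULL) {
  stopifnot(inherits(fit, "decomp_fit"))
  if (is.null(fit$indirect)) stopf("fit has no within/between coefficients")
  bp <- beta_population %||% fit$beta_population
  out <- list(indirect = fit$indirect)
  if (!is.null(bp) && is.finite(bp) && bp != 0) {
    out$share_of_population <- fit$indirect / bp
  }
  out
}

#' Incremental variance explained between two nested OLS fits
#'
#' `R^2(full) - R^2(reduced)`, floored at zero. Both fits must have been
#' estimated on the identical rows (identical listwise deletion), otherwise an
#' error is raised.
#'
#' @param fit_full,fit_reduced `decomp_fit` objects on the same rows.
#' @export
variance_explained <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "decomp_fit"), inherits(fit_reduced, "decomp_fit"))
  if (!identical(fit_full$rows, fit_reduced$rows)) {
    stopf("fits use different rows; incremental R^2 requires identical complete-case sets")
  }
  max(fit_full$r2_full - fit_reduced$r2_full, 0)
}

#' @export
print.decomp_fit <- function(x, ...) {
  cat(sprintf("<decomp_fit: %s model for '%s'>\n", x$model, x$outcome))
  if (x$model == "population") {
    cat(sprintf("  beta_population = %.4f, incremental R2(PGS) = %.4f\n",
                x$beta_population, x$r2_pgs))
  } else {
    cat(sprintf("  beta_within = %.4f, beta_between = %.4f, indirect = %.4f\n",
                x$beta_within, x$beta_between, x$indirect))
  }
  cat(sprintf("  n = %d persons in %d families; covariates: %s\n",
              x$n_persons, x$n_families,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none"))
  invisible(x)
}
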