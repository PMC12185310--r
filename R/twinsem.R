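#' Assemble a per-pair twin dataset for variance-component modelling
#'
#' Reshapes a person-level cohort into one record per twin pair: the two
#' phenotype values (either may be missing) and each twin's covariate row for
#' the means model. Pairs with both phenotypes missing are dropped. The default
#' means-model covariates are age at the outcome's wave, sex, and their
#' product.
#'
#' @param cohort person-level data.frame.
#' @param outcome phenotype column name.
#' @param covariates character vector of covariate columns for the means model
#'   (`"a:b"` entries become products); `"default"` resolves to age, sex and
#'   age x sex at the outcome's wave; `NULL` for an intercept-only means model.
#' @return object of class `twin_dataset`.
#' @export
make_twin_dataset <- function(cohort, outcome, covariates = "default") {
  if (!outcome %in% names(cohort)) stopf("outcome column '%s' not found", outcome)
  if (identical(covariates, "default")) {
    tags <- parse_phenotype_column(outcome)
    age_col <- if (!is.null(tags)) paste0("age_", tags$age) else "age"
    covariates <- intersect(c(age_col, "sex"), names(cohort))
    if (all(c(age_col, "sex") %in% covariates)) {
      covariates <- c(covariates, paste0(age_col, ":sex"))
    }
  }
  cov_spec <- covariates %||% character(0)
  ord <- order(cohort$family_id, cohort$twin_index)
  ch <- cohort[ord, , drop = FALSE]
  i1 <- which(ch$twin_index == 1); i2 <- which(ch$twin_index == 2)
  if (length(i1) != length(i2) || any(ch$family_id[i1] != ch$family_id[i2])) {
    stopf("cohort must contain exactly two rows per family (twin_index 1 and 2)")
  }
  Xall <- cbind(`(intercept)` = 1,
                covariate_matrix(ch, cov_spec))
  # complete covariates required; phenotype may be missing for one twin
  cov_ok <- stats::complete.cases(as.data.frame(Xall))
  y1 <- ch[[outcome]][i1]; y2 <- ch[[outcome]][i2]
  ok <- (!is.na(y1) | !is.na(y2)) & cov_ok[i1] & cov_ok[i2]
  structure(list(
    y1 = y1[ok], y2 = y2[ok],
    X1 = Xall[i1, , drop = FALSE][ok, , drop = FALSE],
    X2 = Xall[i2, , drop = FALSE][ok, , drop = FALSE],
    zygosity = ch$zygosity[i1][ok],
    family_id = ch$family_id[i1][ok],
    outcome = outcome, covariates = cov_spec
  ), class = "twin_dataset")
}

#' Twin correlations by zygosity
#'
#' Pearson correlations of co-twin phenotypes computed per zygosity on
#' pairwise-complete, single-entry pairs (double entry available as an
#' option), with Fisher-z confidence intervals.
#'
#' @param data a `twin_dataset` from [make_twin_dataset()].
#' @param double_entry if `TRUE`, each pair contributes both orderings.
#' @param conf confidence level for the Fisher-z interval.
#' @return data.frame with one row per zygosity: `r`, `n_pairs`, CI bounds.
#' @export
twin_correlations <- function(data, double_entry = FALSE, conf = 0.95) {
  stopifnot(inherits(data, "twin_dataset"))
  out <- lapply(c("MZ", "DZ"), function(z) {
    sel <- data$zygosity == z & !is.na(data$y1) & !is.na(data$y2)
    n <- sum(sel)
    if (n < 30) {
      stopf("only %d complete %s pairs; need >= 30 for a stable correlation", n, z)
    }
    a <- data$y1[sel]; b <- data$y2[sel]
    if (double_entry) {
      r <- stats::cor(c(a, b), c(b, a))
    } else {
      r <- stats::cor(a, b)
    }
    z_se <- 1 / sqrt(n - 3)
    zr <- atanh(min(max(r, -0.999999), 0.999999))
    crit <- stats::qnorm(1 - (1 - conf) / 2)
    data.frame(zygosity = z, r = r, n_pairs = n,
               lower = tanh(zr - crit * z_se), upper = tanh(zr + crit * z_se))
  })
  do.call(rbind, out)
}

#' Choose between ACE and ADE from the twin correlations
#'
#' ADE when the MZ correlation exceeds twice the DZ correlation (a pattern
#' additive + shared environment cannot produce), otherwise ACE; the boundary
#' `rMZ = 2 rDZ` (where C = D = 0) resolves to ACE.
#'
#' @param r_mz,r_dz MZ and DZ twin correlations.
#' @return `"ADE"` or `"ACE"`.
#' @export
choose_model <- function(r_mz, r_dz) {
  stopifnot(is.finite(r_mz), is.finite(r_dz))
  if (r_mz > 2 * r_dz) "ADE" else "ACE"
}

# Expected 2x2 covariance of a twin pair before any sibling interaction.
# paths: list with a, c, d, e (absent components 0).
twin_sigma0 <- function(paths, zygosity) {
  a2 <- paths$a^2; c2 <- paths$c^2; d2 <- paths$d^2; e2 <- paths$e^2
  v <- a2 + c2 + d2 + e2
  cv <- if (zygosity == "MZ") a2 + c2 + d2 else 0.5 * a2 + c2 + 0.25 * d2
  matrix(c(v, cv, cv, v), 2, 2)
}

# Negative FIML log-likelihood over pairs. Vectorized over four groups:
# complete pairs and single-phenotype pairs per zygosity. With sibling
# interaction s, both the covariance and the means are passed through
# T = (I - sB)^{-1}.
twin_negll <- function(par, layout, data) {
  paths <- list(a = 0, c = 0, d = 0, e = 0)
  for (nm in layout$path_names) paths[[nm]] <- par[layout$idx[[nm]]]
  s <- if (layout$sib) par[layout$idx$s] else 0
  beta <- par[layout$idx$beta]
  if (abs(s) >= 0.99) return(1e10)

  M1 <- as.vector(data$X1 %*% beta)
  M2 <- as.vector(data$X2 %*% beta)
  if (s != 0) {
    d <- 1 - s^2
    m1 <- (M1 + s * M2) / d
    m2 <- (M2 + s * M1) / d
    M1 <- m1; M2 <- m2
  }
  Tm <- matrix(c(1, s, s, 1) / (1 - s^2), 2, 2)
  nll <- 0
  for (z in c("MZ", "DZ")) {
    S0 <- twin_sigma0(paths, z)
    S <- if (s != 0) Tm %*% S0 %*% t(Tm) else S0
    det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (!is.finite(det_s) || det_s <= 0 || S[1, 1] <= 0) return(1e10)
    zi <- data$zygosity == z
    both <- zi & !is.na(data$y1) & !is.na(data$y2)
    if (any(both)) {
      r1 <- data$y1[both] - M1[both]
      r2 <- data$y2[both] - M2[both]
      w11 <- S[2, 2] / det_s; w22 <- S[1, 1] / det_s; w12 <- -S[1, 2] / det_s
      q <- w11 * r1^2 + 2 * w12 * r1 * r2 + w22 * r2^2
      nll <- nll + sum(q) / 2 + sum(both) * (log(2 * pi) + 0.5 * log(det_s))
    }
    one1 <- zi & !is.na(data$y1) & is.na(data$y2)
    if (any(one1)) {
      r <- data$y1[one1] - M1[one1]
      nll <- nll + 0.5 * sum(r^2) / S[1, 1] +
        sum(one1) * 0.5 * (log(2 * pi) + log(S[1, 1]))
    }
    one2 <- zi & is.na(data$y1) & !is.na(data$y2)
    if (any(one2)) {
      r <- data$y2[one2] - M2[one2]
      nll <- nll + 0.5 * sum(r^2) / S[2, 2] +
        sum(one2) * 0.5 * (log(2 * pi) + log(S[2, 2]))
    }
  }
  nll
}

twin_layout <- function(model, sibling_interaction, p_beta) {
  path_names <- switch(model,
    ACE = c("a", "c", "e"),
    ADE = c("a", "d", "e"),
    AE = c("a", "e"),
    E = "e",
    stopf("model must be one of ACE, ADE, AE, E"))
  idx <- list()
  k <- 0L
  for (nm in path_names) { k <- k + 1L; idx[[nm]] <- k }
  sib <- isTRUE(sibling_interaction)
  if (sib) { k <- k + 1L; idx$s <- k }
  idx$beta <- k + seq_len(p_beta)
  list(path_names = path_names, sib = sib, idx = idx,
       n_par = k + p_beta, model = model)
}

#' Fit a univariate twin variance-component model by FIML
#'
#' Maximizes the full-information maximum-likelihood over twin pairs, summing
#' per-pair bivariate-normal log-densities with zygosity-specific expected
#' covariance (ACE: MZ covariance a2 + c2, DZ 0.5 a2 + c2; ADE: MZ a2 + d2,
#' DZ 0.5 a2 + 0.25 d2). Pairs with one missing phenotype contribute their
#' univariate marginal density. Covariates enter the means model as fixed
#' effects inside the likelihood. With `sibling_interaction = TRUE` a
#' reciprocal contrast path s is estimated: the pair's expected mean and
#' covariance are transformed through `(I - sB)^{-1}` with B the co-twin swap
#' matrix. Variance components are parameterized as squared paths (so
#' non-negative by construction) and standardized by the pre-interaction total
#' variance.
#'
#' Confidence intervals for the standardized components (and s) come from the
#' observed information matrix via the delta method (`ci_method = "delta"`),
#' or from a nonparametric pair-level bootstrap (`ci_method = "boot"`).
#'
#' @param data a `twin_dataset` from [make_twin_dataset()].
#' @param model `"ACE"`, `"ADE"`, `"AE"` or `"E"` (C and D are never fit
#'   jointly: not identified with twins alone).
#' @param sibling_interaction estimate the contrast path s.
#' @param ci_method `"delta"`, `"boot"` or `"none"`.
#' @param n_boot pair-level bootstrap replicates when `ci_method = "boot"`.
#' @param n_restarts jittered optimizer restarts.
#' @param seed seed for restarts jitter / bootstrap.
#' @param conf confidence level.
#' @return object of class `twin_fit` with standardized components `a2`,
#'   `c2`/`d2`, `e2`, `s`, raw paths, mean-model coefficients,
#'   log-likelihood, counts, and component CIs.
#' @export
fit_twin_model <- function(data, model = c("ACE", "ADE", "AE", "E"),
                           sibling_interaction = FALSE,
                           ci_method = c("delta", "boot", "none"),
                           n_boot = 500, n_restarts = 5, seed = 1L,
                           conf = 0.95) {
  stopifnot(inherits(data, "twin_dataset"))
  model <- match.arg(model)
  ci_method <- match.arg(ci_method)
  p_beta <- ncol(data$X1)
  layout <- twin_layout(model, sibling_interaction, p_beta)

  yall <- c(data$y1, data$y2)
  v <- stats::var(yall, na.rm = TRUE)
  m <- mean(yall, na.rm = TRUE)
  start <- numeric(layout$n_par)
  eq <- sqrt(v / length(layout$path_names))
  for (nm in layout$path_names) start[layout$idx[[nm]]] <- eq
  if (layout$sib) start[layout$idx$s] <- 0
  start[layout$idx$beta[1]] <- m

  lower <- rep(-Inf, layout$n_par); upper <- rep(Inf, layout$n_par)
  if (layout$sib) { lower[layout$idx$s] <- -0.95; upper[layout$idx$s] <- 0.95 }

  fits <- with_seed(seed, {
    lapply(seq_len(max(1, n_restarts)), function(k) {
      st <- if (k == 1) start else start * stats::runif(length(start), 0.6, 1.4) +
        stats::rnorm(length(start), sd = 0.05 * sqrt(v))
      st <- pmin(pmax(st, lower + 1e-3), upper - 1e-3)
      tryCatch(
        stats::nlminb(st, twin_negll, layout = layout, data = data,
                      lower = lower, upper = upper,
                      control = list(iter.max = 500, eval.max = 1000,
                                     rel.tol = 1e-12)),
        error = function(e) NULL)
    })
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$objective), fits)
  if (!length(fits)) stopf("twin model optimization failed in all %d restarts", n_restarts)
  objs <- vapply(fits, `[[`, numeric(1), "objective")
  best <- fits[[which.min(objs)]]
  if (min(objs) >= 1e9) {
    stopf("twin model did not reach a valid optimum; optimizer messages: %s",
          paste(unique(vapply(fits, `[[`, character(1), "message")), collapse = "; "))
  }

  par <- best$par
  paths <- list(a = 0, c = 0, d = 0, e = 0)
  for (nm in layout$path_names) paths[[nm]] <- abs(par[layout$idx[[nm]]])
  s_hat <- if (layout$sib) par[layout$idx$s] else 0
  tot <- paths$a^2 + paths$c^2 + paths$d^2 + paths$e^2
  std <- c(a2 = paths$a^2 / tot,
           c2 = if (model == "ACE") paths$c^2 / tot else if (model %in% c("AE", "E")) 0 else NA_real_,
           d2 = if (model == "ADE") paths$d^2 / tot else NA_real_,
           e2 = paths$e^2 / tot)

  ci <- NULL
  hess_warning <- NULL
  if (ci_method == "delta") {
    ci <- tryCatch(
      twin_delta_ci(par, layout, data, conf),
      error = function(e) { hess_warning <<- conditionMessage(e); NULL })
    if (is.null(ci) && !is.null(hess_warning)) {
      warnf("delta-method CIs unavailable (%s); consider ci_method = 'boot'", hess_warning)
    }
  } else if (ci_method == "boot") {
    ci <- twin_boot_ci(data, model, sibling_interaction, n_boot,
                       derive_seed(seed, 23L), conf)
  }

  structure(list(
    model = model, sibling_interaction = layout$sib,
    a2 = unname(std["a2"]), c2 = unname(std["c2"]), d2 = unname(std["d2"]),
    e2 = unname(std["e2"]), s = s_hat,
    paths = paths,
    beta = stats::setNames(par[layout$idx$beta], colnames(data$X1)),
    loglik = -best$objective,
    n_par = layout$n_par,
    n_pairs = length(data$y1),
    n_complete_pairs = sum(!is.na(data$y1) & !is.na(data$y2)),
    convergence = best$convergence, message = best$message,
    ci = ci, ci_method = ci_method, conf = conf,
    outcome = data$outcome,
    par = par, layout = layout,
    data_checksum = twin_data_checksum(data)
  ), class = "twin_fit")
}

twin_data_checksum <- function(data) {
  sum(c(data$y1, data$y2), na.rm = TRUE) + 13 * length(data$y1) +
    sum(data$zygosity == "MZ")
}

# Map raw parameters to the reported quantities (standardized components + s);
# used for delta-method CIs and the pair bootstrap.
twin_std_map <- function(par, layout) {
  paths <- list(a = 0, c = 0, d = 0, e = 0)
  for (nm in layout$path_names) paths[[nm]] <- par[layout$idx[[nm]]]
  tot <- paths$a^2 + paths$c^2 + paths$d^2 + paths$e^2
  out <- c(a2 = paths$a^2 / tot)
  if (layout$model == "ACE") out <- c(out, c2 = paths$c^2 / tot)
  if (layout$model == "ADE") out <- c(out, d2 = paths$d^2 / tot)
  out <- c(out, e2 = paths$e^2 / tot)
  if (layout$sib) out <- c(out, s = par[layout$idx$s])
  out
}

twin_delta_ci <- function(par, layout, data, conf) {
  H <- stats::optimHess(par, twin_negll, layout = layout, data = data)
  V <- solve(H)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Hessian not positive definite at the optimum")
  g0 <- twin_std_map(par, layout)
  k <- length(g0)
  J <- matrix(0, k, length(par))
  h <- pmax(abs(par), 1) * 1e-6
  for (j in seq_along(par)) {
    pp <- par; pp[j] <- pp[j] + h[j]
    pm <- par; pm[j] <- pm[j] - h[j]
    J[, j] <- (twin_std_map(pp, layout) - twin_std_map(pm, layout)) / (2 * h[j])
  }
  se <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
  crit <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(component = names(g0), estimate = unname(g0), se = se,
             lower = pmax(unname(g0) - crit * se,
                          ifelse(names(g0) == "s", -1, 0)),
             upper = pmin(unname(g0) + crit * se,
                          ifelse(names(g0) == "s", 1, 1)),
             method = "delta")
}

twin_boot_ci <- function(data, model, sib, n_boot, seed, conf) {
  n <- length(data$y1)
  reps <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      d2 <- data
      d2$y1 <- data$y1[idx]; d2$y2 <- data$y2[idx]
      d2$X1 <- data$X1[idx, , drop = FALSE]; d2$X2 <- data$X2[idx, , drop = FALSE]
      d2$zygosity <- data$zygosity[idx]; d2$family_id <- data$family_id[idx]
      f <- tryCatch(fit_twin_model(d2, model, sib, ci_method = "none",
                                   n_restarts = 2, seed = b),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      twin_std_map(f$par, f$layout)
    })
  })
  reps <- do.call(rbind, Filter(Negate(is.null), reps))
  alpha <- (1 - conf) / 2
  qs <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  est <- colMeans(reps, na.rm = TRUE)
  data.frame(component = colnames(reps), estimate = unname(est),
             se = apply(reps, 2, stats::sd, na.rm = TRUE),
             lower = qs[1, ], upper = qs[2, ], method = "boot")
}

#' Likelihood-ratio comparison of nested twin models
#'
#' Computes -2 * (logLik reduced - logLik full), its degrees of freedom, the
#' naive chi-square p-value and a boundary-corrected p-value using the 50:50
#' chi-square mixture appropriate when the dropped parameter is a variance
#' component tested on the boundary of its space.
#'
#' @param fit_full,fit_reduced `twin_fit` objects on identical data (checked),
#'   with the reduced model nested in the full one.
#' @return data.frame with `minus2_delta_ll`, `df`, `p_chisq`, `p_mixture`.
#' @export
compare_models <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "twin_fit"), inherits(fit_reduced, "twin_fit"))
  if (!isTRUE(all.equal(fit_full$data_checksum, fit_reduced$data_checksum))) {
    stopf("model comparison requires identical data rows in both fits")
  }
  df <- fit_full$n_par - fit_reduced$n_par
  if (df < 0) stopf("the 'reduced' model has more parameters than the 'full' model")
  stat <- max(-2 * (fit_reduced$loglik - fit_full$loglik), 0)
  p_chisq <- if (df == 0) as.numeric(stat <= 0) else stats::pchisq(stat, df, lower.tail = FALSE)
  p_mix <- if (df == 0) {
    as.numeric(stat <= 0)
  } else if (df == 1) {
    if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
  } else {
    0.5 * stats::pchisq(stat, df, lower.tail = FALSE) +
      0.5 * stats::pchisq(stat, df - 1, lower.tail = FALSE)
  }
  data.frame(minus2_delta_ll = stat, df = df, p_chisq = p_chisq, p_mixture = p_mix)
}

#' @export
print.twin_fit <- function(x, ...) {
  comp <- if (x$model == "ACE") sprintf("c2 = %.3f", x$c2)
          else if (x$model == "ADE") sprintf("d2 = %.3f", x$d2)
          else "no C/D"
  cat(sprintf("<twin_fit: %s%s for '%s'>\n", x$model,
              if (x$sibling_interaction) " + sibling interaction" else "",
              x$outcome %||% "outcome"))
  cat(sprintf("  a2 = %.3f, %s, e2 = %.3f%s; logLik = %.2f (%d pairs)\n",
              x$a2, comp, x$e2,
              if (x$sibling_interaction) sprintf(", s = %.3f", x$s) else "",
              x$loglik, x$n_pairs))
  invisible(x)
}
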