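# Bootstrap inference for the polygenic-score decomposition: both regression
# models share one set of family resamples, so the population, direct
# (within), between, indirect and incremental-R^2 statistics are computed on
# identical resampled cohorts.

# Align a per-family sufficient-statistic matrix onto a common family index,
# inserting zero rows for families absent from this design (they contribute
# nothing to its cross-products).
align_famstats <- function(mat, fams_present, fams_all) {
  out <- matrix(0, length(fams_all), ncol(mat))
  out[match(fams_present, fams_all), ] <- mat
  out
}

# Family resample counts: equivalent in distribution to sampling n_fam
# families with replacement.
resample_counts <- function(n_fam, b) {
  # ceiling(runif * k) is a uniform draw on 1..k; one vectorized call covers
  # all b replicates
  idx <- as.integer(ceiling(stats::runif(n_fam * b) * n_fam)) +
    rep.int((seq_len(b) - 1L) * n_fam, rep.int(n_fam, b))
  matrix(tabulate(idx, n_fam * b), n_fam, b)
}

# Vector-statistic BCa bootstrap sharing one stream of family resamples.
bootstrap_bca_multi <- function(famstats, statistic, stat_names, B, seed,
                                conf = 0.95, points = NULL) {
  n_fam <- nrow(famstats)
  k <- length(stat_names)
  totals <- colSums(famstats)
  pt <- statistic(totals)
  if (!is.null(points)) pt <- points
  tf <- t(famstats)
  reps <- matrix(NA_real_, B, k)
  done <- 0L
  with_seed(seed, {
    while (done < B) {
      b <- min(1000L, B - done)
      tots <- tf %*% resample_counts(n_fam, b)
      for (j in seq_len(b)) reps[done + j, ] <- statistic(tots[, j])
      done <- done + b
    }
  })
  jack <- matrix(NA_real_, n_fam, k)
  for (i in seq_len(n_fam)) jack[i, ] <- statistic(totals - famstats[i, ])
  out <- lapply(seq_len(k), function(j) {
    res <- bca_from_jack(pt[j], reps[, j], jack[, j], conf, "bca")
    res$B <- B; res$seed <- seed
    class(res) <- "bca_boot"
    res
  })
  names(out) <- stat_names
  out
}

# Lean closure evaluating all requested decomposition statistics from the
# concatenated totals of the two designs; index maps are precomputed so one
# call is a handful of small solves.
make_decomposition_statistic <- function(p1, p2, n1, want) {
  map1 <- if (!is.null(p1)) vech_map(p1)
  map2 <- vech_map(p2)
  nv1 <- if (!is.null(p1)) p1 * (p1 + 1) / 2
  nv2 <- p2 * (p2 + 1) / 2
  function(tot) {
    out <- numeric(length(want))
    names(out) <- want
    if (!is.null(p1)) {
      t1 <- tot[seq_len(n1)]
      XtX <- matrix(t1[map1], p1, p1)
      Xty <- t1[nv1 + seq_len(p1)]
      yty <- t1[nv1 + p1 + 1]
      n <- t1[nv1 + p1 + 2]
      coef <- solve(XtX, Xty)
      bpop <- coef[p1]
      if ("population" %in% want) out["population"] <- bpop
      if ("r2_pgs" %in% want) {
        rss <- yty - sum(coef * Xty)
        keep <- seq_len(p1 - 1)
        coef_r <- solve(XtX[keep, keep], Xty[keep])
        rss_r <- yty - sum(coef_r * Xty[keep])
        tss <- yty - Xty[1]^2 / n
        out["r2_pgs"] <- max((rss_r - rss) / tss, 0)
      }
      t2 <- tot[-seq_len(n1)]
    } else {
      t2 <- tot
      bpop <- NA_real_
    }
    XtX2 <- matrix(t2[map2], p2, p2)
    Xty2 <- t2[nv2 + seq_len(p2)]
    coef2 <- solve(XtX2, Xty2)
    bw <- coef2[p2 - 1]; bb <- coef2[p2]
    if ("within" %in% want) out["within"] <- bw
    if ("between" %in% want) out["between"] <- bb
    if ("indirect" %in% want) out["indirect"] <- bb - bw
    if ("share" %in% want) {
      out["share"] <- if (is.finite(bpop) && bpop != 0) (bb - bw) / bpop else NA_real_
    }
    out
  }
}

#' Full polygenic-score decomposition with BCa bootstrap inference
#'
#' Fits the population-level model and the within/between-family model for one
#' outcome, then bootstraps the requested estimates (population, direct =
#' within, between, indirect = between - within, the indirect share of the
#' population effect, and the incremental R^2 of the PGS) by resampling
#' families with replacement, with bias-corrected accelerated 95% intervals.
#'
#' @inheritParams fit_population_model
#' @param B bootstrap replications (default 10,000).
#' @param seed RNG seed for the resampling.
#' @param conf confidence level.
#' @param boot_stats which statistics to bootstrap; trimming the list (e.g. to
#'   `"indirect"` in large calibration studies) skips the unneeded
#'   cross-products.
#' @return object of class `decomposition`: the two fits plus a `boot` list of
#'   [bootstrap_bca()] results per requested estimate.
#' @export
decompose <- function(cohort, outcome, covariates = "default",
                      B = 10000, seed = NULL, conf = 0.95,
                      boot_stats = c("population", "within", "between",
                                     "indirect", "share", "r2_pgs")) {
  boot_stats <- match.arg(boot_stats, several.ok = TRUE)
  fit_pop <- fit_population_model(cohort, outcome, covariates)
  fit_wb <- fit_within_between_model(cohort, outcome, covariates)

  need_pop <- any(c("population", "share", "r2_pgs") %in% boot_stats)
  p2 <- ncol(fit_wb$X)
  fs2 <- family_ols_stats(fit_wb$X, fit_wb$y, fit_wb$family)
  fams2 <- unique(fit_wb$family)
  if (need_pop) {
    p1 <- ncol(fit_pop$X)
    fs1 <- family_ols_stats(fit_pop$X, fit_pop$y, fit_pop$family)
    fams1 <- unique(fit_pop$family)
    fams <- union(fams1, fams2)
    FS <- cbind(align_famstats(fs1, fams1, fams),
                align_famstats(fs2, fams2, fams))
    n1 <- ncol(fs1)
  } else {
    p1 <- NULL; n1 <- 0L
    FS <- fs2
  }

  statistic <- make_decomposition_statistic(p1, p2, n1, boot_stats)
  point_all <- c(
    population = fit_pop$beta_population,
    within = fit_wb$beta_within, between = fit_wb$beta_between,
    indirect = fit_wb$indirect,
    share = if (fit_pop$beta_population != 0)
      fit_wb$indirect / fit_pop$beta_population else NA_real_,
    r2_pgs = fit_pop$r2_pgs)
  boots <- bootstrap_bca_multi(FS, statistic, boot_stats,
                               B = B, seed = seed, conf = conf,
                               points = unname(point_all[boot_stats]))
  structure(list(
    outcome = outcome,
    population = fit_pop, within_between = fit_wb,
    boot = boots, B = B, seed = seed, conf = conf
  ), class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition of '%s'> (B = %d family-level BCa bootstrap)\n",
              x$outcome, x$B))
  for (nm in intersect(c("population", "within", "between", "indirect"),
                       names(x$boot))) {
    b <- x$boot[[nm]]
    cat(sprintf("  %-10s %8.4f  SE %.4f  95%% CI [%8.4f, %8.4f]\n",
                nm, b$point, b$se, b$lower, b$upper))
  }
  if ("r2_pgs" %in% names(x$boot)) {
    cat(sprintf("  r2_pgs     %8.4f  95%% CI [%8.4f, %8.4f]\n",
                x$boot$r2_pgs$point, x$boot$r2_pgs$lower, x$boot$r2_pgs$upper))
  }
  invisible(x)
}

#' Rerun the decomposition controlling for an additional covariate
#'
#' Appends `extra_covariate` (SES, neighbourhood-deprivation decile, or a
#' latent parenting factor score) to the covariate set, refits both models,
#' and reports how much the direct and indirect estimates attenuate relative
#' to the uncontrolled fit. Attenuation is reported as a percentage of the
#' uncontrolled estimate. When `extra_covariate = "parenting_factor"` and no
#' such column exists, the parenting factor is scored from the parenting items
#' via [parenting_factor()] first.
#'
#' @inheritParams decompose
#' @param extra_covariate column name of the control variable.
#' @return object of class `control_fit` with elements `uncontrolled`,
#'   `controlled`, `attenuation_direct_pct`, `attenuation_indirect_pct` and
#'   CI-based significance flags.
#' @export
control_for <- function(cohort, outcome, extra_covariate,
                        covariates = "default", B = 10000, seed = NULL) {
  if (extra_covariate == "parenting_factor" && !"parenting_factor" %in% names(cohort)) {
    sc <- parenting_factor(cohort)
    cohort$parenting_factor <- sc$score
  }
  if (!extra_covariate %in% names(cohort)) {
    stopf("control variable '%s' not found in cohort", extra_covariate)
  }
  cov_res <- resolve_covariates(cohort, outcome, covariates)
  base <- decompose(cohort, outcome, cov_res, B = B, seed = seed)
  ctrl <- decompose(cohort, outcome, c(cov_res, extra_covariate),
                    B = B, seed = derive_seed(seed, 17L))
  att <- function(b0, b1) {
    if (!is.finite(b0) || b0 == 0) return(NA_real_)
    100 * (1 - b1 / b0)
  }
  structure(list(
    outcome = outcome, control = extra_covariate,
    uncontrolled = base, controlled = ctrl,
    attenuation_direct_pct = att(base$within_between$beta_within,
                                 ctrl$within_between$beta_within),
    attenuation_indirect_pct = att(base$within_between$indirect,
                                   ctrl$within_between$indirect),
    uncontrolled_indirect_significant =
      base$boot$indirect$lower > 0 || base$boot$indirect$upper < 0,
    controlled_indirect_significant =
      ctrl$boot$indirect$lower > 0 || ctrl$boot$indirect$upper < 0
  ), class = "control_fit")
}

#' @export
print.control_fit <- function(x, ...) {
  cat(sprintf("<control_fit: '%s' controlling for %s>\n", x$outcome, x$control))
  cat(sprintf("  indirect: %.4f [%.4f, %.4f] -> %.4f [%.4f, %.4f]\n",
              x$uncontrolled$boot$indirect$point,
              x$uncontrolled$boot$indirect$lower, x$uncontrolled$boot$indirect$upper,
              x$controlled$boot$indirect$point,
              x$controlled$boot$indirect$lower, x$controlled$boot$indirect$upper))
  cat(sprintf("  direct attenuation: %.1f%%; indirect attenuation: %.1f%%\n",
              x$attenuation_direct_pct, x$attenuation_indirect_pct))
  invisible(x)
}
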