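#' Bias-corrected accelerated (BCa) bootstrap over family-level resamples
#'
#' Resamples whole families (twin pairs kept intact, preserving the within-pair
#' dependence) with replacement, and returns the BCa 95% interval of a scalar
#' statistic together with the bootstrap SE, the bias-correction `z0` and the
#' jackknife acceleration `a`.
#'
#' The statistic is expressed as a function of summed per-family sufficient
#' statistics: `famstats` has one row per family, and `statistic(totals)` maps
#' the column sums of any family resample to the scalar of interest. All
#' OLS-based statistics factor this way exactly (cross-products are additive
#' over families; see [family_ols_stats]), which also makes the leave-one-out
#' jackknife for the acceleration a vectorized subtraction. For statistics that
#' do not factor through sums, use [bootstrap_bca_cohort()].
#'
#' @param famstats numeric matrix, one row per family.
#' @param statistic function mapping a totals vector (column sums of a family
#'   resample) to a scalar.
#' @param B number of bootstrap replications (default 10,000); BCa intervals
#'   are refused below `B = 200` (use `ci_type = "percentile"` there).
#' @param seed RNG seed for the resampling.
#' @param conf confidence level.
#' @param ci_type `"bca"` (default) or `"percentile"`.
#' @return object of class `bca_boot`: point estimate, `B`, `se`, `lower`,
#'   `upper`, `z0`, `a`, `seed`, `replicates`.
#' @export
bootstrap_bca <- function(famstats, statistic, B = 10000, seed = NULL,
                          conf = 0.95, ci_type = c("bca", "percentile")) {
  ci_type <- match.arg(ci_type)
  if (ci_type == "bca" && B < 200) {
    stopf("B = %d is too small for a stable BCa interval; use B >= 200 or ci_type = 'percentile'", B)
  }
  famstats <- as.matrix(famstats)
  n_fam <- nrow(famstats)
  point <- unname(statistic(colSums(famstats)))
  reps <- with_seed(seed, {
    replicate_totals_stat(famstats, statistic, B)
  })
  res <- bca_from_replicates(point, reps, famstats, statistic, conf, ci_type)
  res$B <- B
  res$seed <- seed
  class(res) <- "bca_boot"
  res
}

# Draw B family resamples as multinomial count vectors and evaluate the
# statistic on each column-sum; chunked so the count matrix stays small.
replicate_totals_stat <- function(famstats, statistic, B, chunk = 1000L) {
  n_fam <- nrow(famstats)
  tf <- t(famstats)
  out <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    totals <- tf %*% resample_counts(n_fam, b)  # (ncol famstats) x b
    out[done + seq_len(b)] <- unname(apply(totals, 2, statistic))
    done <- done + b
  }
  out
}

bca_from_replicates <- function(point, reps, famstats, statistic, conf, ci_type) {
  # acceleration from a leave-one-family-out jackknife (vectorized: totals
  # minus each family's row)
  jack <- if (ci_type == "bca") {
    totals <- colSums(famstats)
    apply(sweep(-famstats, 2, totals, `+`), 1, statistic)
  } else NULL
  bca_from_jack(point, reps, jack, conf, ci_type)
}

#' @export
print.bca_boot <- function(x, ...) {
  cat(sprintf("BCa bootstrap: point %.4f, SE %.4f, 95%% CI [%.4f, %.4f] (B = %d, z0 = %.3f, a = %.4f)\n",
              x$point, x$se, x$lower, x$upper, x$B,
              x$z0 %||% NA, x$a %||% NA))
  invisible(x)
}

#' BCa bootstrap of an arbitrary cohort-level statistic
#'
#' Generic (slower) companion to [bootstrap_bca()]: the statistic is any
#' function of a cohort data.frame returning a scalar; resampling is still by
#' family.
#'
#' @param cohort person-level data.frame with a `family_id` column.
#' @param statistic function of a cohort returning a scalar.
#' @inheritParams bootstrap_bca
#' @export
bootstrap_bca_cohort <- function(cohort, statistic, B = 10000, seed = NULL,
                                 conf = 0.95, ci_type = c("bca", "percentile")) {
  ci_type <- match.arg(ci_type)
  if (ci_type == "bca" && B < 200) {
    stopf("B = %d is too small for a stable BCa interval; use B >= 200 or ci_type = 'percentile'", B)
  }
  fam_ids <- unique(cohort$family_id)
  n_fam <- length(fam_ids)
  rows_of <- split(seq_len(nrow(cohort)), factor(cohort$family_id, levels = fam_ids))
  point <- unname(statistic(cohort))
  # resampled families are relabelled so a family drawn twice stays two
  # distinct pairs (family identity, not the label, is what is resampled)
  resample <- function() {
    fams <- sample.int(n_fam, replace = TRUE)
    idx <- unlist(rows_of[fams], use.names = FALSE)
    ch <- cohort[idx, , drop = FALSE]
    sizes <- lengths(rows_of)[fams]
    ch$family_id <- rep(seq_along(fams), sizes)
    ch
  }
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) unname(statistic(resample())), numeric(1))
  })
  jack <- vapply(seq_len(n_fam), function(i) {
    unname(statistic(cohort[-rows_of[[i]], , drop = FALSE]))
  }, numeric(1))
  res <- bca_from_jack(point, reps, jack, conf, ci_type)
  res$B <- B
  res$seed <- seed
  class(res) <- "bca_boot"
  res
}

bca_from_jack <- function(point, reps, jack, conf, ci_type) {
  point <- unname(point)
  reps_ok <- reps[is.finite(reps)]
  se <- stats::sd(reps_ok)
  alpha <- (1 - conf) / 2
  if (length(unique(reps_ok)) == 1L && reps_ok[1] == point) {
    warnf("statistic is constant across all bootstrap replicates; interval collapses to the point estimate")
    return(list(point = point, se = 0, lower = point, upper = point,
                z0 = 0, a = 0, replicates = reps))
  }
  if (ci_type == "percentile") {
    qs <- stats::quantile(reps_ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
    return(list(point = point, se = se, lower = qs[1], upper = qs[2],
                z0 = NA_real_, a = NA_real_, replicates = reps))
  }
  prop_below <- mean(reps_ok < point) + 0.5 * mean(reps_ok == point)
  prop_below <- min(max(prop_below, 1 / (length(reps_ok) + 1)),
                    length(reps_ok) / (length(reps_ok) + 1))
  z0 <- stats::qnorm(prop_below)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  a <- if (den > 0) num / den else 0
  zlo <- stats::qnorm(alpha); zhi <- stats::qnorm(1 - alpha)
  a1 <- stats::pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
  a2 <- stats::pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
  qs <- unname(stats::quantile(reps_ok, c(a1, a2), names = FALSE, type = 7))
  if (point < qs[1] || point > qs[2]) {
    warnf("BCa interval does not bracket the point estimate (heavily skewed bootstrap distribution)")
  }
  list(point = point, se = se, lower = qs[1], upper = qs[2],
       z0 = z0, a = a, replicates = reps)
}
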