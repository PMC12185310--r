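#' One-factor confirmatory factor model estimated by FIML
#'
#' Fits the single-common-factor model `x = mu + lambda * f + u`,
#' `f ~ N(0, 1)`, `u ~ N(0, diag(theta))`, by full-information maximum
#' likelihood: rows are grouped by missing-data pattern and each group
#' contributes the marginal multivariate-normal log-density of its observed
#' items. The factor variance is fixed to 1 for identification, so loadings
#' are on the item scale and scores are scale-free; the sign convention makes
#' the first loading positive. Uniquenesses are bounded below at `1e-4`
#' (Heywood floor) with a warning when the bound is active.
#'
#' @param items numeric matrix or data.frame of item responses (>= 3 columns
#'   for identification); per-person missingness allowed, rows with no
#'   observed item are ignored for fitting.
#' @param n_restarts jittered optimizer restarts.
#' @param seed seed for the restart jitter.
#' @return object of class `factor_model`: `loadings`, `theta` (uniqueness
#'   variances), `mu`, `loglik`, `n_used`, `convergence`, `items` (labels).
#' @export
fit_one_factor <- function(items, n_restarts = 2, seed = 1L) {
  X <- as.matrix(items)
  if (!is.numeric(X)) stopf("items must be numeric")
  k <- ncol(X)
  if (k < 3) stopf("a one-factor model needs >= 3 items for identification, got %d", k)
  labels <- colnames(X) %||% paste0("item", seq_len(k))
  obs_any <- rowSums(!is.na(X)) > 0
  X <- X[obs_any, , drop = FALSE]
  n <- nrow(X)
  if (n < k + 2) stopf("too few rows (%d) to fit a %d-item factor model", n, k)

  # Pattern-level sufficient statistics, padded to the full k-item space so
  # every missing-data pattern is processed in one set of G x k matrix
  # operations (G = number of patterns): count, padded column sums, padded
  # cross-product diagonal, and the stacked padded cross-product matrices.
  pat <- apply(!is.na(X), 1, function(r) paste(as.integer(r), collapse = ""))
  upat <- unique(pat)
  G <- length(upat)
  M <- matrix(0, G, k)            # observation mask per pattern
  Ng <- integer(G)
  Smat <- matrix(0, G, k)         # padded column sums
  dCmat <- matrix(0, G, k)        # padded diag of cross-products
  CC <- matrix(0, G * k, k)       # stacked padded cross-product blocks
  for (g in seq_len(G)) {
    rows <- which(pat == upat[g])
    obs <- which(strsplit(upat[g], "")[[1]] == "1")
    Y <- X[rows, obs, drop = FALSE]
    M[g, obs] <- 1
    Ng[g] <- length(rows)
    Smat[g, obs] <- colSums(Y)
    Cg <- crossprod(Y)
    dCmat[g, obs] <- diag(Cg)
    CC[(g - 1L) * k + obs, obs] <- Cg
  }
  ko_g <- rowSums(M)

  theta_floor <- 1e-4
  # Negative FIML log-likelihood and its analytic gradient wrt (mu, lambda,
  # theta). For each observed block, d nll / d Sigma = n/2 W - W S W / 2 with
  # W = Sigma^{-1} and S the centred cross-product, chained through
  # Sigma = lambda lambda' + diag(theta). The one-factor structure lets every
  # pattern be handled with the Woodbury identity (W is never formed):
  #   W = D^{-1} - c u u',  u = lambda / theta,  c = 1 / (1 + lambda' u),
  #   log|Sigma| = sum(log theta) - log(c),  W lambda = c u,
  # and the zero padding makes all per-pattern sums plain matrix products.
  colscale <- function(mat, v) mat * rep(v, each = nrow(mat))
  eval_fiml <- function(par, want_grad = FALSE) {
    mu <- par[seq_len(k)]
    lam <- par[k + seq_len(k)]
    th <- par[2 * k + seq_len(k)]
    if (any(th <= 0)) return(if (want_grad) NULL else 1e10)
    u <- lam / th
    Umat <- colscale(M, u)
    cc <- 1 / (1 + as.vector(M %*% (lam * u)))          # per pattern
    logdet <- as.vector(M %*% log(th)) - log(cc)
    Momat <- colscale(M, mu)
    Cu <- matrix(CC %*% u, G, k, byrow = TRUE)
    su <- as.vector(Smat %*% u)
    mou <- as.vector(M %*% (mu * u))
    uCu <- as.vector(Cu %*% u)
    uSgu <- uCu - 2 * su * mou + Ng * mou^2
    Sg_dg <- dCmat - 2 * Smat * Momat + Ng * Momat^2
    trWSg <- as.vector(Sg_dg %*% (1 / th)) - cc * uSgu
    nll <- 0.5 * sum(Ng * (ko_g * log(2 * pi) + logdet) + trWSg)
    if (!want_grad) return(if (is.finite(nll)) nll else 1e10)

    Sgu <- Cu - Smat * mou - Momat * (su - Ng * mou)
    WSgu <- colscale(Sgu, 1 / th) - (cc * uSgu) * Umat
    g_lam <- 2 * colSums(0.5 * cc * (Ng * Umat - WSgu))
    Wdg <- colscale(M, 1 / th) - cc * Umat^2
    WSgW_dg <- colscale(Sg_dg, 1 / th^2) - 2 * cc * Umat * colscale(Sgu, 1 / th) +
      (cc^2 * uSgu) * Umat^2
    g_th <- colSums(0.5 * (Ng * Wdg - WSgW_dg))
    Vmat <- Smat - Ng * Momat
    vu <- as.vector(Vmat %*% u)
    g_mu <- -colSums(colscale(Vmat, 1 / th) - (cc * vu) * Umat)
    c(g_mu, g_lam, g_th)
  }
  negll <- function(par) eval_fiml(par, want_grad = FALSE)
  negll_grad <- function(par) {
    gr <- eval_fiml(par, want_grad = TRUE)
    if (is.null(gr)) rep(0, length(par)) else gr
  }

  mu0 <- colMeans(X, na.rm = TRUE)
  v0 <- apply(X, 2, stats::var, na.rm = TRUE)
  v0[!is.finite(v0) | v0 <= 0] <- 1
  # principal-axis start from the pairwise-complete covariance: close enough
  # to the FIML optimum that the quasi-Newton step count stays small
  lam0 <- sqrt(0.5 * v0); th0 <- 0.5 * v0
  S0 <- tryCatch(stats::cov(X, use = "pairwise.complete.obs"),
                 error = function(e) NULL)
  if (!is.null(S0) && !anyNA(S0)) {
    e1 <- eigen(S0, symmetric = TRUE)
    if (e1$values[1] > 0) {
      cand <- e1$vectors[, 1] * sqrt(e1$values[1])
      if (cand[1] < 0) cand <- -cand
      lam0 <- cand
      th0 <- pmax(diag(S0) - cand^2, theta_floor * 10)
    }
  }
  start <- c(mu0, lam0, th0)
  lower <- c(rep(-Inf, 2 * k), rep(theta_floor, k))

  fits <- with_seed(seed, {
    lapply(seq_len(max(1, n_restarts)), function(r) {
      st <- if (r == 1) start else {
        s <- start
        s[k + seq_len(k)] <- s[k + seq_len(k)] * stats::runif(k, 0.5, 1.5)
        s[2 * k + seq_len(k)] <- pmax(s[2 * k + seq_len(k)] *
                                        stats::runif(k, 0.5, 1.5), theta_floor * 2)
        s
      }
      tryCatch(stats::nlminb(st, negll, gradient = negll_grad, lower = lower,
                             control = list(iter.max = 1000, eval.max = 2000,
                                            rel.tol = 1e-12)),
               error = function(e) NULL)
    })
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$objective), fits)
  if (!length(fits)) stopf("factor model optimization failed")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]

  mu <- best$par[seq_len(k)]
  lam <- best$par[k + seq_len(k)]
  th <- best$par[2 * k + seq_len(k)]
  if (lam[1] < 0) lam <- -lam
  if (any(th <= theta_floor * 1.01)) {
    warnf("Heywood case: %d uniqueness variance(s) at the lower floor (%g)",
          sum(th <= theta_floor * 1.01), theta_floor)
  }
  structure(list(
    items = labels, loadings = stats::setNames(lam, labels),
    theta = stats::setNames(th, labels), mu = stats::setNames(mu, labels),
    factor_variance = 1,
    loglik = -best$objective, n_used = n,
    convergence = best$convergence, message = best$message
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model: %d items, n = %d, logLik = %.2f>\n",
              length(x$items), x$n_used, x$loglik))
  print(round(rbind(loading = x$loadings, uniqueness = x$theta), 3))
  invisible(x)
}

#' Regression-method factor scores
#'
#' Scores each person with the posterior mean of the factor given their
#' observed items: `score = lambda_O' Sigma_O^{-1} (x_O - mu_O)` using
#' pattern-specific weights, where O is the person's observed item set.
#' Persons with no observed item receive `NA` (their count is messaged).
#' Under unit factor variance the score variance never exceeds 1.
#'
#' @param model a `factor_model`.
#' @param items data with the model's item columns (extra columns ignored).
#' @param person_id optional identifier vector to attach.
#' @return data.frame of class `factor_scores`: `score`,
#'   `fraction_items_observed` (plus `person_id` when given); scoring method
#'   recorded in the `method` attribute.
#' @export
score_factor <- function(model, items, person_id = NULL) {
  stopifnot(inherits(model, "factor_model"))
  items <- as.data.frame(items)
  missing_cols <- setdiff(model$items, names(items))
  if (length(missing_cols)) {
    stopf("items table lacks model columns: %s", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(items[, model$items, drop = FALSE])
  k <- length(model$items)
  n <- nrow(X)
  score <- rep(NA_real_, n)
  pat <- apply(!is.na(X), 1, function(r) paste(as.integer(r), collapse = ""))
  for (pp in unique(pat)) {
    obs <- which(strsplit(pp, "")[[1]] == "1")
    rows <- which(pat == pp)
    if (!length(obs)) next
    lam <- model$loadings[obs]
    S <- tcrossprod(lam) + diag(model$theta[obs], length(obs))
    w <- solve(S, lam)
    R <- sweep(X[rows, obs, drop = FALSE], 2, model$mu[obs])
    score[rows] <- as.vector(R %*% w)
  }
  n_missing <- sum(is.na(score))
  if (n_missing > 0) {
    message(sprintf("score_factor: %d person(s) with no observed items scored as NA", n_missing))
  }
  out <- data.frame(score = score,
                    fraction_items_observed = rowMeans(!is.na(X)))
  if (!is.null(person_id)) out <- cbind(person_id = person_id, out)
  attr(out, "method") <- "regression"
  attr(out, "model") <- model
  class(out) <- c("factor_scores", "data.frame")
  out
}

#' Fit and score common, reporter-specific or age-specific factors
#'
#' Selects the item subset for the requested view of a trait's item battery
#' (all items for `"common"`; per-reporter or per-age subsets otherwise), fits
#' a one-factor model per subset and scores everyone. `drop_ages` removes all
#' items at the listed ages before fitting (the sensitivity analysis for
#' unevenly sampled waves).
#'
#' @param cohort cohort data.frame with tagged item columns
#'   (`<trait>_age<age>_<reporter>_item<k>`).
#' @param trait trait label.
#' @param view `"common"`, `"by_reporter"` or `"by_age"`.
#' @param drop_ages ages whose items are excluded.
#' @inheritParams fit_one_factor
#' @return for `"common"`, a `factor_scores` data.frame; otherwise a named
#'   list of `factor_scores` per reporter / age.
#' @export
build_factor_views <- function(cohort, trait,
                               view = c("common", "by_reporter", "by_age"),
                               drop_ages = NULL, n_restarts = 3, seed = 1L) {
  view <- match.arg(view)
  cols <- item_columns(cohort, trait)
  if (!is.null(drop_ages) && length(drop_ages)) {
    cols <- setdiff(cols, item_columns(cohort, trait, ages = drop_ages))
  }
  if (!length(cols)) stopf("no item columns found for trait '%s'", trait)
  fit_and_score <- function(cc) {
    m <- fit_one_factor(cohort[, cc, drop = FALSE], n_restarts, seed)
    score_factor(m, cohort, person_id = cohort$person_id)
  }
  if (view == "common") return(fit_and_score(cols))
  tag <- function(cc, what) {
    vapply(cc, function(x) {
      p <- parse_phenotype_column(sub("_item[0-9]+$", "", x))
      if (what == "reporter") p$reporter else as.character(p$age)
    }, character(1))
  }
  key <- tag(cols, if (view == "by_reporter") "reporter" else "age")
  lapply(split(cols, key), fit_and_score)
}

#' Latent parenting factor scores
#'
#' One-factor FIML fit over the family-level parenting items (columns matching
#' `parenting_age<age>_item<k>`), scored per person; co-twins share the score
#' because the items are family-level. Intended as the parenting control
#' covariate for [control_for()].
#'
#' @param cohort cohort data.frame with parenting item columns.
#' @inheritParams fit_one_factor
#' @return a `factor_scores` data.frame aligned with `cohort` rows.
#' @export
parenting_factor <- function(cohort, n_restarts = 3, seed = 1L) {
  cols <- grep("^parenting_age[0-9]+_item[0-9]+$", names(cohort), value = TRUE)
  if (length(cols) < 3) {
    stopf("need >= 3 parenting item columns (parenting_age<age>_item<k>), found %d",
          length(cols))
  }
  m <- fit_one_factor(cohort[, cols, drop = FALSE], n_restarts, seed)
  score_factor(m, cohort, person_id = cohort$person_id)
}
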