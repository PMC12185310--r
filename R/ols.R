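# Internal OLS machinery shared by the decomposition models and the bootstrap.
# Coefficients come from a QR factorisation; rank deficiency is an error that
# names the aliased columns rather than silently dropping them, because a
# collinear covariate would corrupt the within/between construction.

ols_qr <- function(X, y) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stopf("design is rank deficient; aliased column(s): %s",
          paste(bad, collapse = ", "))
  }
  coef <- qr.coef(q, y)
  fitted <- as.vector(X %*% coef)
  resid <- y - fitted
  tss <- sum((y - mean(y))^2)
  rss <- sum(resid^2)
  list(coef = coef, fitted = fitted, residuals = resid,
       r2 = if (tss > 0) 1 - rss / tss else NA_real_,
       n = length(y))
}

# Half-vectorisation index helpers for packing symmetric cross-product
# matrices into per-family sufficient-statistic rows.
vech_index <- function(p) which(lower.tri(diag(p), diag = TRUE))

# index map K with Sigma[i, j] = vech[K[i, j]]; makes unpacking a symmetric
# matrix from its half-vectorisation a single indexing operation
vech_map <- function(p) {
  K <- matrix(0L, p, p)
  K[lower.tri(K, diag = TRUE)] <- seq_len(p * (p + 1) / 2)
  K[upper.tri(K)] <- t(K)[upper.tri(K)]
  K
}

unvech <- function(v, p, map = vech_map(p)) {
  matrix(v[map], p, p)
}

# Per-family sufficient statistics for an OLS design: each row holds
# vech(Xj' Xj), Xj' yj, yj' yj and nj for family j. Cross-products are
# additive over families, so any resample of families maps to column sums,
# which is what makes family-level bootstrapping of OLS statistics exact and
# fast.
family_ols_stats <- function(X, y, family) {
  p <- ncol(X)
  idx <- vech_index(p)
  fam <- factor(family, levels = unique(family))
  prod_cols <- matrix(0, nrow(X), length(idx))
  k <- 1L
  for (j in seq_len(p)) {
    for (i in j:p) {
      prod_cols[, k] <- X[, i] * X[, j]
      k <- k + 1L
    }
  }
  XtX_rows <- rowsum(prod_cols, fam)
  Xty_rows <- rowsum(X * y, fam)
  yty_rows <- rowsum(y^2, fam)
  n_rows <- rowsum(rep(1, length(y)), fam)
  out <- cbind(XtX_rows, Xty_rows, yty_rows, n_rows)
  attr(out, "p") <- p
  attr(out, "colnames_X") <- colnames(X)
  out
}

# Solve the normal equations from summed sufficient statistics.
ols_from_totals <- function(tot, p, map = vech_map(p)) {
  nv <- p * (p + 1) / 2
  XtX <- unvech(tot[seq_len(nv)], p, map)
  Xty <- tot[nv + seq_len(p)]
  yty <- tot[nv + p + 1]
  n <- tot[nv + p + 2]
  coef <- tryCatch(solve(XtX, Xty), error = function(e) rep(NA_real_, p))
  rss <- yty - sum(coef * Xty)
  sum_y <- Xty[1]                       # column 1 of X is the intercept
  tss <- yty - sum_y^2 / n
  list(coef = unname(coef),
       r2 = if (is.finite(tss) && tss > 0) 1 - rss / tss else NA_real_,
       n = unname(n), XtX = XtX, Xty = Xty, yty = yty)
}

# Incremental R^2 of the last q columns of the design, from the same totals
# (the reduced model's cross-products are a sub-block of the full model's).
incremental_r2_from_totals <- function(tot, p, q = 1L) {
  full <- ols_from_totals(tot, p)
  keep <- seq_len(p - q)
  XtX_r <- full$XtX[keep, keep, drop = FALSE]
  Xty_r <- full$Xty[keep]
  coef_r <- tryCatch(solve(XtX_r, Xty_r), error = function(e) rep(NA_real_, length(keep)))
  rss_r <- full$yty - sum(coef_r * Xty_r)
  tss <- full$yty - full$Xty[1]^2 / full$n
  r2_r <- if (is.finite(tss) && tss > 0) 1 - rss_r / tss else NA_real_
  max(full$r2 - r2_r, 0)
}
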