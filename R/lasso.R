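# Cross-validated lasso in covariance (Gram) form, vectorised over many
# response columns that share one design matrix. The genome-wide screen
# solves one small lasso per marker per fold per repetition; batching the
# coordinate-descent updates across markers turns ~10^5 independent fits
# into a handful of (p x M) matrix operations. glmnet solves the identical
# objective for a single response and serves as the oracle in the tests.

# Coordinate descent over a decreasing per-response penalty path.
# G: p x p Gram matrix X'X/n of the standardised design (unit diagonal).
# C: p x M matrix X'D/n for M centred responses.
# lambda: M x L matrix of penalties, decreasing along columns (warm starts).
# Returns a p x M x L array of coefficients on the standardised scale.
lasso_path_cov <- function(G, C, lambda, tol = 1e-7, max_sweep = 1000L) {
  p <- nrow(C); M <- ncol(C); L <- ncol(lambda)
  B <- matrix(0, p, M)
  out <- array(0, dim = c(p, M, L))
  for (l in seq_len(L)) {
    lam <- lambda[, l]
    for (s in seq_len(max_sweep)) {
      delta <- 0
      for (j in seq_len(p)) {
        r <- C[j, ] - as.numeric(G[j, ] %*% B) + B[j, ]  # G[j, j] == 1
        bj <- sign(r) * pmax(abs(r) - lam, 0)
        delta <- max(delta, max(abs(bj - B[j, ])))
        B[j, ] <- bj
      }
      if (delta < tol) break
    }
    out[, , l] <- B
  }
  out
}

# population-sd column standardisation: makes diag(X'X/n) exactly 1, so the
# covariance-form coordinate updates solve glmnet's objective exactly
std_pop <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  xc <- sweep(x, 2L, center, "-")
  if (is.null(scale)) {
    scale <- sqrt(colMeans(xc^2))
    scale[scale < .Machine$double.eps^0.5] <- 1
  }
  list(x = sweep(xc, 2L, scale, "/"), center = center, scale = scale)
}

# Fit lasso with internal K-fold cross-validated penalty for every column of
# D regressed on X. Per-response geometric lambda path from each response's
# own lambda_max; the selected index is the first (largest) lambda attaining
# the minimal CV mean squared error, glmnet's lambda.min convention.
fit_lasso_cv <- function(x, d, nfolds = 5L, nlambda = 20L,
                         lambda_min_ratio = 1e-3, seed = 1L) {
  x <- as.matrix(x); d <- as.matrix(d)
  n <- nrow(x); M <- ncol(d)
  sx <- std_pop(x)
  dbar <- colMeans(d)
  dc <- sweep(d, 2L, dbar, "-")
  ratios <- 10^seq(0, log10(lambda_min_ratio), length.out = nlambda)
  lam_max <- pmax(apply(abs(crossprod(sx$x, dc) / n), 2L, max), 1e-10)
  lambda <- outer(lam_max, ratios)

  folds <- fold_assign(n, nfolds, seed)
  cvm <- matrix(0, M, nlambda)
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    xf <- std_pop(x[tr, , drop = FALSE])
    df_bar <- colMeans(d[tr, , drop = FALSE])
    dfc <- sweep(d[tr, , drop = FALSE], 2L, df_bar, "-")
    nf <- sum(tr)
    G <- crossprod(xf$x) / nf
    diag(G) <- 1
    C <- crossprod(xf$x, dfc) / nf
    paths <- lasso_path_cov(G, C, lambda)
    xv <- std_pop(x[!tr, , drop = FALSE],
                  center = xf$center, scale = xf$scale)$x
    dv <- d[!tr, , drop = FALSE]
    for (l in seq_len(nlambda)) {
      pred <- sweep(xv %*% paths[, , l], 2L, df_bar, "+")
      cvm[, l] <- cvm[, l] + colSums((dv - pred)^2)
    }
  }
  cvm <- cvm / n
  sel <- max.col(-cvm, ties.method = "first")

  G <- crossprod(sx$x) / n
  diag(G) <- 1
  C <- crossprod(sx$x, dc) / n
  paths <- lasso_path_cov(G, C, lambda)
  beta <- matrix(0, ncol(x), M)
  for (m in seq_len(M)) beta[, m] <- paths[, m, sel[m]]
  list(beta = beta, x_center = sx$center, x_scale = sx$scale,
       d_center = dbar, lambda = lambda, lambda_index = sel, cvm = cvm)
}

predict_lasso <- function(fit, xnew) {
  xs <- std_pop(as.matrix(xnew), center = fit$x_center,
                scale = fit$x_scale)$x
  sweep(xs %*% fit$beta, 2L, fit$d_center, "+")
}

# Cross-fit the two nuisance functions of the partially linear model:
# g(X) ~ E[y | X] and m(X) ~ E[d | X], each with lasso-CV, predictions made
# on the held-out fold only. Returns stacked out-of-fold residuals.
crossfit_nuisance <- function(y, d, x, n_folds = 5L, seed = 1L) {
  y <- as.numeric(y); d <- as.matrix(d); x <- as.matrix(x)
  n <- length(y)
  if (nrow(d) != n || nrow(x) != n) stopf("y, d, X row counts differ")
  folds <- fold_assign(n, n_folds, seed)
  ytil <- numeric(n)
  nu <- matrix(0, n, ncol(d))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit_g <- fit_lasso_cv(x[tr, , drop = FALSE], y[tr],
                          seed = seed + 7919L * f)
    fit_m <- fit_lasso_cv(x[tr, , drop = FALSE], d[tr, , drop = FALSE],
                          seed = seed + 7919L * f + 104729L)
    ytil[!tr] <- y[!tr] - as.numeric(predict_lasso(fit_g, x[!tr, , drop = FALSE]))
    nu[!tr, ] <- d[!tr, , drop = FALSE] -
      predict_lasso(fit_m, x[!tr, , drop = FALSE])
  }
  list(ytil = ytil, nu = nu, folds = folds)
}
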