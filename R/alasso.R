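# Closed-form ridge fit on standardized columns via the kernel identity
# beta = Xs' (Xs Xs'/n + lambda I)^{-1} (y - mean(y)) / n, which costs
# O(n^2 p) and is exact for any p >= n. Used only to produce the
# preliminary estimate for adaptive-lasso weights.
ridge_solve <- function(Xs, yc, lambda) {
  n <- nrow(Xs)
  G <- tcrossprod(Xs) / n
  e <- eigen(G, symmetric = TRUE)
  q <- crossprod(e$vectors, yc)
  alpha <- e$vectors %*% (q / (pmax(e$values, 0) + lambda))
  as.numeric(crossprod(Xs, alpha)) / n
}

# 10-fold CV for the ridge penalty over a log-spaced grid (entry point
# max|Xs'(y - ybar)| / (n * 0.001), the convention glmnet applies at
# alpha near zero; same e^-6 span as the main path).
ridge_cv <- function(Xs, y, K = 10L, L = 100L, seed = NULL) {
  n <- nrow(Xs)
  K <- min(K, n)
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xs, yc))) / (n * 0.001)
  lam <- make_lambda_path(lmax, L)$values
  folds <- with_seed(seed, sample(rep_len(seq_len(K), n)))
  err <- matrix(0, K, length(lam))
  for (k in seq_len(K)) {
    tr <- folds != k
    Xtr <- Xs[tr, , drop = FALSE]
    ytr <- y[tr]
    ntr <- nrow(Xtr)
    G <- tcrossprod(Xtr) / ntr
    e <- eigen(G, symmetric = TRUE)
    q <- crossprod(e$vectors, ytr - mean(ytr))
    P <- (Xs[!tr, , drop = FALSE] %*% t(Xtr) / ntr) %*% e$vectors
    for (l in seq_along(lam)) {
      pred <- mean(ytr) + P %*% (q / (pmax(e$values, 0) + lam[l]))
      err[k, l] <- mean((y[!tr] - pred)^2)
    }
  }
  cvm <- colMeans(err)
  best <- which.min(cvm)   # ties resolve to the largest penalty
  list(lambda = lam[best], cvm = cvm,
       beta = ridge_solve(Xs, yc, lam[best]))
}

#' Adaptive lasso path with ridge-derived weights
#'
#' Implements the adaptive lasso via the weighted-column reduction. A
#' preliminary ridge estimate is computed on the standardized design
#' (its penalty chosen by 10-fold cross-validation over a log-spaced
#' grid), per-covariate weights are set to `w_j = 1 / |beta_ridge_j|`
#' with `|beta_ridge_j|` floored at 1e-8 (so `w_j <= 1e8`; covariates at
#' the floor are so heavily penalized that they are effectively
#' excluded), and the weighted l1 problem is solved as a plain lasso on
#' the rescaled columns `x_j / w_j`, with coefficients mapped back by
#' `beta_j = b_j / w_j`.
#'
#' @inheritParams fit_path
#' @param weights optional precomputed weights (skips the ridge stage;
#'   used internally by cross-validation so that every fold shares the
#'   full-data weights).
#' @param seed seed for the ridge fold assignment.
#' @return an `elsa_coef_path` whose `spec$weights` records the weights
#'   used.
#' @export
fit_adaptive_lasso_path <- function(X, y, path = NULL, L = 100L, seed = NULL,
                                    weights = NULL) {
  X <- assert_finite_matrix(X, y)
  p <- ncol(X)
  if (p == 0L) {
    path <- path %||% make_lambda_path(1, L)
    return(new_coef_path(matrix(0, 0, path$L), rep(mean(y), path$L),
                         penalty_spec("alasso"), path,
                         meta = list(backend = "intercept-only")))
  }
  m <- std_moments(X)
  Xs <- standardize_columns(X, m)
  if (is.null(weights)) {
    ridge <- ridge_cv(Xs, y, seed = seed)
    weights <- 1 / pmax(abs(ridge$beta), 1e-8)
  }
  stopifnot(length(weights) == p, all(is.finite(weights)), all(weights > 0))
  spec <- penalty_spec("alasso", weights = weights)
  if (is.null(path)) {
    path <- make_lambda_path(compute_lambda_max(X, y, spec), L)
  } else {
    path <- as_lambda_path(path)
  }
  Xw <- sweep(Xs, 2L, weights, "/")
  if (p == 1L) {
    # exact weighted univariate solution (no re-standardization of the
    # weighted column): minimize (v/2) b^2 - z b + lambda |b|
    yc <- y - mean(y)
    z <- sum(Xw[, 1] * yc) / nrow(X)
    v <- sum(Xw[, 1]^2) / nrow(X)
    b_w <- matrix(sign(z) * pmax(abs(z) - path$values, 0) / max(v, 1e-300),
                  1, path$L)
  } else {
    fit <- glmnet::glmnet(Xw, y, family = "gaussian", alpha = 1,
                          lambda = path$values, standardize = FALSE)
    b_w <- as.matrix(fit$beta)
  }
  b_std <- b_w / weights
  b_std[m$zero, ] <- 0
  sc <- ifelse(m$zero, 1, m$scale)
  betas <- b_std / sc
  intercepts <- mean(y) - as.numeric(crossprod(betas, m$center))
  new_coef_path(betas, intercepts, spec, path,
                meta = list(backend = "alasso-glmnet"))
}
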