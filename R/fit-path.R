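new_coef_path <- function(betas, intercepts, spec, path, meta = list()) {
  dimnames(betas) <- NULL
  structure(list(
    betas = betas,
    intercepts = as.numeric(intercepts),
    spec = spec,
    path = path,
    support_counts = colSums(abs(betas) > 1e-12),
    meta = meta
  ), class = "elsa_coef_path")
}

#' Fit a full regularization path
#'
#' Fits the chosen penalty family at every value of a descending penalty
#' path, warm-started along the path, and returns the coefficients on
#' the original covariate scale together with per-path intercepts.
#' Covariates are standardized internally (mean zero, unit standard
#' deviation with the 1/n denominator); the response is centered through
#' the intercept. Lasso and elastic net are solved by coordinate descent
#' via \pkg{glmnet} (the lasso is the `alpha = 1` code path of the
#' elastic net), the adaptive lasso by the weighted-column reduction
#' (see [fit_adaptive_lasso_path()]), SCAD by a dedicated coordinate
#' descent solver ([fit_scad_path()]) and LARS by its forward trajectory
#' ([fit_lars_path()]).
#'
#' @param X numeric design matrix (n x p).
#' @param y numeric response.
#' @param spec a [penalty_spec()] or family name.
#' @param path a [make_lambda_path()] object; computed from
#'   [compute_lambda_max()] when `NULL`. Ignored by LARS, which is
#'   indexed by `L` evenly spaced points along its trajectory.
#' @param L path length used when `path` is `NULL`.
#' @param seed seed for family-internal randomness (the adaptive lasso's
#'   ridge cross-validation); unused otherwise.
#' @return an `elsa_coef_path` with fields `betas` (p x L), `intercepts`,
#'   `spec`, `path`, `support_counts` and `meta`.
#' @seealso [cv_select()], [predict.elsa_coef_path()]
#' @export
fit_path <- function(X, y, spec = penalty_spec("lasso"), path = NULL,
                     L = 100L, seed = NULL) {
  spec <- as_penalty_spec(spec)
  X <- assert_finite_matrix(X, y)
  switch(spec$family,
    lasso = ,
    elnet = fit_glmnet_path(X, y, spec, path, L),
    alasso = fit_adaptive_lasso_path(X, y, path = path, L = L, seed = seed,
                                     weights = spec$weights),
    scad = fit_scad_path(X, y, a = spec$a, path = path, L = L),
    lars = fit_lars_path(X, y, L = if (!is.null(path)) path$L else L)
  )
}

fit_glmnet_path <- function(X, y, spec, path = NULL, L = 100L) {
  p <- ncol(X)
  if (p == 0L) {
    path <- path %||% make_lambda_path(1, L)
    return(new_coef_path(matrix(0, 0, path$L), rep(mean(y), path$L), spec, path,
                         meta = list(backend = "intercept-only")))
  }
  if (is.null(path)) {
    path <- make_lambda_path(compute_lambda_max(X, y, spec), L)
  } else {
    path <- as_lambda_path(path)
  }
  if (p == 1L) return(fit_univariate_path(X, y, spec, path))

  m <- std_moments(X)
  keep <- !m$zero
  fit <- glmnet::glmnet(X[, keep, drop = FALSE], y, family = "gaussian",
                        alpha = spec$alpha, lambda = path$values,
                        standardize = TRUE)
  betas <- matrix(0, p, path$L)
  betas[keep, ] <- as.matrix(fit$beta)
  new_coef_path(betas, as.numeric(fit$a0), spec, path,
                meta = list(backend = "glmnet", dropped_constant = sum(!keep)))
}

# Exact elastic-net solution for a single covariate: on the standardized
# scale beta(lambda) = S(z, lambda * alpha) / (1 + lambda * (1 - alpha))
# with z the covariance between the standardized column and centered y.
fit_univariate_path <- function(X, y, spec, path) {
  m <- std_moments(X)
  n <- nrow(X)
  lam <- path$values
  if (m$zero[1]) {
    b_std <- rep(0, path$L)
  } else {
    xs <- (X[, 1] - m$center[1]) / m$scale[1]
    z <- sum(xs * (y - mean(y))) / n
    b_std <- sign(z) * pmax(abs(z) - lam * spec$alpha, 0) /
      (1 + lam * (1 - spec$alpha))
  }
  sc <- if (m$zero[1]) 1 else m$scale[1]
  betas <- matrix(b_std / sc, 1, path$L)
  intercepts <- mean(y) - betas[1, ] * m$center[1]
  new_coef_path(betas, intercepts, spec, path, meta = list(backend = "closed-form"))
}

#' Predictions along a fitted path
#'
#' @param object an `elsa_coef_path`.
#' @param newx matrix of new observations (columns in the order used for
#'   fitting).
#' @param ... unused.
#' @return an `nrow(newx) x L` matrix of per-path-point predictions.
#' @export
predict.elsa_coef_path <- function(object, newx, ...) {
  newx <- if (is.matrix(newx)) newx else matrix(newx, nrow = 1L)
  if (ncol(newx) != nrow(object$betas)) {
    stop("newx has ", ncol(newx), " columns; fit used ", nrow(object$betas),
         call. = FALSE)
  }
  sweep(newx %*% object$betas, 2L, object$intercepts, "+")
}

#' @export
print.elsa_coef_path <- function(x, ...) {
  cat(sprintf("coefficient path: %s, p = %d, L = %d, support %d..%d\n",
              x$spec$family, nrow(x$betas), length(x$intercepts),
              min(x$support_counts), max(x$support_counts)))
  invisible(x)
}

#' Export a coefficient path as CSV
#'
#' Writes the intercepts and coefficients (rows = intercept then
#' covariates, columns = path index) for inspection outside R.
#'
#' @param fit an `elsa_coef_path`.
#' @param file output path.
#' @export
write_coef_path_csv <- function(fit, file) {
  stopifnot(inherits(fit, "elsa_coef_path"))
  tab <- rbind(`(Intercept)` = fit$intercepts, fit$betas)
  rownames(tab) <- c("(Intercept)",
                     rownames(fit$betas) %||% paste0("x", seq_len(nrow(fit$betas))))
  colnames(tab) <- paste0("l", seq_len(ncol(tab)))
  write.csv(tab, file)
  invisible(file)
}
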