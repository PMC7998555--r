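#' SCAD penalty derivative
#'
#' First derivative of the smoothly clipped absolute deviation penalty at
#' `x >= 0`: equal to `lambda` on (0, lambda], linearly decreasing to
#' zero on (lambda, a*lambda], and zero beyond, so large coefficients are
#' left nearly unbiased.
#'
#' @param x nonnegative numeric vector.
#' @param lambda penalty level (> 0).
#' @param a shape parameter (> 2), default 3.7.
#' @return numeric vector of derivatives.
#' @export
scad_deriv <- function(x, lambda, a = 3.7) {
  stopifnot(lambda > 0, a > 2)
  x <- abs(x)
  lambda * (x <= lambda) + pmax(a * lambda - x, 0) / (a - 1) * (x > lambda)
}

#' Univariate SCAD thresholding
#'
#' Minimizer of `(1/2) * (b - z)^2 + SCAD(|b|; lambda, a)` for a
#' unit-scaled coordinate: soft-thresholding for `|z| <= 2*lambda`, the
#' interpolating middle piece for `2*lambda < |z| <= a*lambda`, and the
#' unshrunken `z` beyond `a*lambda`. This is the coordinate update used
#' by [fit_scad_path()].
#'
#' @param z numeric vector of unpenalized univariate solutions.
#' @inheritParams scad_deriv
#' @return numeric vector of thresholded values.
#' @export
scad_threshold <- function(z, lambda, a = 3.7) {
  stopifnot(lambda > 0, a > 2)
  .scad_update_cpp(as.numeric(z), lambda, a)
}

#' SCAD regularization path by coordinate descent
#'
#' Cyclic coordinate descent with the univariate SCAD thresholding rule,
#' warm-started along a descending penalty path. The path entry point is
#' the lasso `lambda_max` (the all-zero vector is stationary for SCAD
#' there because the penalty derivative equals `lambda` near zero).
#' Iterations stop when the largest coefficient change falls below `tol`;
#' a path point that fails to converge within `max_iter` sweeps is
#' flagged in `meta$converged` and its last iterate kept. The SCAD
#' objective is nonconvex, so the solver returns a stationary point, not
#' a certified global minimum.
#'
#' @inheritParams fit_path
#' @param a SCAD shape parameter (> 2).
#' @param max_iter maximum coordinate-descent sweeps per path point.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @return an `elsa_coef_path`.
#' @export
fit_scad_path <- function(X, y, a = 3.7, path = NULL, L = 100L,
                          max_iter = 10000L, tol = 1e-7) {
  spec <- penalty_spec("scad", a = a)
  X <- assert_finite_matrix(X, y)
  if (ncol(X) == 0L) {
    path <- path %||% make_lambda_path(1, L)
    return(new_coef_path(matrix(0, 0, path$L), rep(mean(y), path$L), spec, path,
                         meta = list(backend = "intercept-only")))
  }
  if (is.null(path)) {
    path <- make_lambda_path(compute_lambda_max(X, y, spec), L)
  } else {
    path <- as_lambda_path(path)
  }
  m <- std_moments(X)
  Xs <- standardize_columns(X, m)
  yc <- y - mean(y)
  res <- .scad_cd_path_cpp(Xs, yc, path$values, a, as.integer(max_iter), tol)
  b_std <- res$betas
  b_std[m$zero, ] <- 0
  sc <- ifelse(m$zero, 1, m$scale)
  betas <- b_std / sc
  intercepts <- mean(y) - as.numeric(crossprod(betas, m$center))
  if (!all(res$converged)) {
    warning(sum(!res$converged), " SCAD path point(s) did not converge within max_iter")
  }
  new_coef_path(betas, intercepts, spec, path,
                meta = list(backend = "scad-cd", converged = res$converged,
                            iters = res$iters))
}
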