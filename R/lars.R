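#' LARS coefficient trajectory evaluated on an even grid
#'
#' Runs least angle regression (pure forward LARS, no lasso
#' modification) on standardized covariates and returns the coefficient
#' trajectory evaluated at `L` evenly spaced points along it. LARS is
#' indexed by steps rather than by a penalty value, so the path-of-`L`
#' convention used by the other families maps here to `L` points from
#' the null model (grid point 1, mirroring the all-zero fit at
#' `lambda_max`) to the final step at `min(n - 1, p)` active variables;
#' the piecewise-linear trajectory is interpolated linearly in the step
#' index between knots. A candidate variable that is numerically
#' collinear with the active set is dropped with a warning and the count
#' recorded in `meta$dropped`.
#'
#' @inheritParams fit_path
#' @param L number of evaluation points along the trajectory.
#' @return an `elsa_coef_path` whose `path` field holds the fraction grid
#'   (`$values` in [0, 1], increasing) instead of penalty values.
#' @export
fit_lars_path <- function(X, y, L = 100L) {
  X <- assert_finite_matrix(X, y)
  spec <- penalty_spec("lars")
  L <- as.integer(L)
  stopifnot(L >= 1L)
  p <- ncol(X)
  if (p == 0L) {
    grid <- list(values = seq(0, 1, length.out = max(L, 2L))[seq_len(L)], L = L)
    return(new_coef_path(matrix(0, 0, L), rep(mean(y), L), spec, grid,
                         meta = list(backend = "intercept-only")))
  }
  m <- std_moments(X)
  Xs <- standardize_columns(X, m)
  yc <- y - mean(y)
  maxs <- min(nrow(X) - 1L, p)
  res <- .lars_path_cpp(Xs, yc, maxs)
  if (res$dropped > 0L) {
    warning(res$dropped, " collinear candidate variable(s) dropped from the LARS path")
  }
  knots <- res$betas                       # p x (nsteps + 1), knot k = step k-1
  nsteps <- res$nsteps
  # interpolate the trajectory at L evenly spaced step positions
  pos <- if (L == 1L) 0 else seq(0, nsteps, length.out = L)
  lo <- pmin(floor(pos), max(nsteps - 1, 0))
  wfrac <- pos - lo
  b_std <- knots[, lo + 1L, drop = FALSE] * rep(1 - wfrac, each = p) +
    knots[, pmin(lo + 2L, nsteps + 1L), drop = FALSE] * rep(wfrac, each = p)
  sc <- ifelse(m$zero, 1, m$scale)
  betas <- b_std / sc
  intercepts <- mean(y) - as.numeric(crossprod(betas, m$center))
  grid <- list(values = if (nsteps > 0) pos / nsteps else pos, L = L)
  new_coef_path(betas, intercepts, spec, grid,
                meta = list(backend = "lars", nsteps = nsteps,
                            dropped = res$dropped,
                            active = res$active + 1L))
}
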