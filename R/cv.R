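#' Select a penalty by K-fold cross-validation
#'
#' Randomly partitions the rows into `K` folds (seeded), fits the full
#' path on each training complement, and averages the per-fold mean
#' squared validation errors at every path point. The selected point
#' minimizes this curve; ties resolve to the smallest index, i.e. the
#' largest (most parsimonious) penalty. The returned coefficients are
#' the full-data path refit at the selected point. For LARS the "path"
#' is the grid of trajectory fractions, and the fraction index is
#' cross-validated instead of a penalty value. For the adaptive lasso
#' the ridge weights are computed once on the full data and shared by
#' every fold fit.
#'
#' @inheritParams fit_path
#' @param K number of folds (default 10); must not exceed n.
#' @param seed seed for the fold assignment.
#' @param full_fit optional precomputed full-data `elsa_coef_path` (must
#'   match `spec` and `path`); avoids refitting when the caller already
#'   has it.
#' @return a list with `lambda` (selected penalty, or trajectory
#'   fraction for LARS), `index`, `beta`, `intercept`, `cvm` (the CV
#'   curve), `fit` (the full-data path) and `folds`.
#' @export
cv_select <- function(X, y, spec = penalty_spec("lasso"), path = NULL,
                      K = 10L, seed = NULL, L = 100L, full_fit = NULL) {
  spec <- as_penalty_spec(spec)
  X <- assert_finite_matrix(X, y)
  n <- nrow(X)
  K <- as.integer(K)
  if (K < 2L || K > n) stop("K must lie in [2, n]", call. = FALSE)

  if (is.null(full_fit)) {
    full_fit <- fit_path(X, y, spec, path = path, L = L, seed = seed)
  }
  path <- full_fit$path
  spec <- full_fit$spec          # adaptive lasso: now carries the weights
  Lp <- length(full_fit$intercepts)

  folds <- with_seed(seed, sample(rep_len(seq_len(K), n)))
  err <- matrix(NA_real_, K, Lp)
  for (k in seq_len(K)) {
    tr <- folds != k
    fit_k <- if (spec$family == "lars") {
      fit_lars_path(X[tr, , drop = FALSE], y[tr], L = Lp)
    } else {
      fit_path(X[tr, , drop = FALSE], y[tr], spec, path = path)
    }
    pred <- predict(fit_k, X[!tr, , drop = FALSE])
    err[k, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(err)
  index <- which.min(cvm)
  list(lambda = path$values[index], index = index,
       beta = full_fit$betas[, index], intercept = full_fit$intercepts[index],
       cvm = cvm, fit = full_fit, folds = folds)
}
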