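# Internal helpers: seeded evaluation and column standardization.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards. `seed = NULL` leaves the RNG
# stream untouched (results then depend on the global RNG state).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds (kept below 2^31) for sub-tasks of a seeded
# computation, so that e.g. each ensemble member or replicate has its own
# independent stream.
child_seeds <- function(seed, k) {
  if (is.null(seed)) return(vector("list", k))
  as.list(with_seed(seed, sample.int(2147483646L, k, replace = FALSE)))
}

# Column means and 1/n standard deviations (glmnet's internal convention;
# using the n-1 denominator would put lambda_max below glmnet's KKT
# threshold and leave a nonzero coefficient at the top of the path).
std_moments <- function(X) {
  center <- colMeans(X)
  scale <- sqrt(colMeans(X^2) - center^2)
  list(center = center, scale = scale, zero = scale < 1e-12)
}

# Standardize columns to mean 0, mean-square 1; zero-variance columns are
# left at zero (their coefficients are forced to zero downstream).
standardize_columns <- function(X, m = std_moments(X)) {
  Xs <- sweep(X, 2L, m$center, "-")
  sc <- ifelse(m$zero, 1, m$scale)
  sweep(Xs, 2L, sc, "/")
}

assert_finite_matrix <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 observations", call. = FALSE)
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a
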