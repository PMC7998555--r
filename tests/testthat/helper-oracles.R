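# Independent oracles and small data builders shared by the tests.

# Closed-form SCAD penalty (the integral of its derivative), used by the
# 1-D grid-search oracle against which the solver's thresholding rule is
# checked.
scad_penalty <- function(b, lambda, a = 3.7) {
  ab <- abs(b)
  ifelse(ab <= lambda, lambda * ab,
         ifelse(ab <= a * lambda,
                -(ab^2 - 2 * a * lambda * ab + lambda^2) / (2 * (a - 1)),
                (a + 1) * lambda^2 / 2))
}

# Grid-search minimizer of (1/2)(b - z)^2 + SCAD(b): the independent
# univariate oracle (accuracy ~ grid spacing).
scad_grid_oracle <- function(z, lambda, a = 3.7, lim = 10, npts = 1e5) {
  grid <- seq(-lim, lim, length.out = npts)
  grid[which.min(0.5 * (grid - z)^2 + scad_penalty(grid, lambda, a))]
}

# Soft-thresholding closed form for the lasso on a design whose
# standardized columns are exactly orthonormal in the 1/n inner product.
soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# n x p design whose centered, 1/n-standardized columns are exactly
# orthogonal: build from the Q of a QR decomposition, then rescale.
orthonormal_design <- function(n, p, seed = 1) {
  stopifnot(p < n)
  withr::with_seed(seed, {
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 1)), n, p + 1))))[, -1, drop = FALSE]
    Q <- Q[, seq_len(p), drop = FALSE]          # columns orthogonal, mean ~0
    sweep(Q, 2, sqrt(colMeans(Q^2)), "/")       # 1/n norm exactly 1
  })
}

# Small correlated regression toy with a known sparse signal.
toy_regression <- function(n = 40, p = 12, r = 3, noise_sd = 0.5, seed = 1,
                           beta_value = 2) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- c(rep(beta_value, r), rep(0, p - r))
    y <- as.numeric(X %*% beta + rnorm(n, 0, noise_sd))
    list(X = X, y = y, beta = beta)
  })
}
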