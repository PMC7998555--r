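#' Specify a sparse linear simulation model
#'
#' Describes the generative model used by the random-design studies: a
#' multivariate normal design `X ~ N(mu, Sigma)` whose mean vector,
#' covariance entries and regression coefficients are themselves drawn
#' at random, plus Gaussian noise. Coordinates of `mu` are i.i.d.
#' normal; off-diagonal `Sigma` entries are i.i.d. uniform (symmetric)
#' and diagonal entries uniform on `diag_range`; the true coefficient
#' vector has exactly `r` nonzeros, i.i.d. uniform on `beta_range`,
#' occupying one contiguous block whose start is drawn uniformly.
#'
#' Normal spreads (`mu_spread`, `noise`) are read as variances by
#' default, matching the variance-based covariance notation of the
#' design model; set `gaussian_second_arg = "sd"` to read them as
#' standard deviations instead.
#'
#' @param p number of covariates.
#' @param r number of relevant covariates (0 <= r <= p).
#' @param n training-set size.
#' @param mu_mean,mu_spread mean and spread of the coordinate means
#'   (defaults 5 and 2).
#' @param cov_range off-diagonal uniform range (default `c(0.4, 0.6)`,
#'   strongly correlated covariates; use `c(0, 0.2)` for the weakly
#'   correlated variant).
#' @param diag_range diagonal uniform range (default `c(0.8, 1.2)`).
#' @param beta_range uniform range of the nonzero coefficients (default
#'   `c(-2, 2)`; `c(2, 3)` gives all-strong signals, `c(-0.2, 0.2)`
#'   all-weak).
#' @param noise noise spread (default 0.15).
#' @param gaussian_second_arg `"variance"` (default) or `"sd"`.
#' @return an object of class `elsa_sim_model`.
#' @seealso [sim_preset()] for the named study configurations.
#' @export
sim_model <- function(p, r, n, mu_mean = 5, mu_spread = 2,
                      cov_range = c(0.4, 0.6), diag_range = c(0.8, 1.2),
                      beta_range = c(-2, 2), noise = 0.15,
                      gaussian_second_arg = c("variance", "sd")) {
  gaussian_second_arg <- match.arg(gaussian_second_arg)
  stopifnot(p >= 1, r >= 0, r <= p, n >= 2, noise >= 0,
            length(cov_range) == 2L, length(diag_range) == 2L,
            length(beta_range) == 2L)
  structure(list(p = as.integer(p), r = as.integer(r), n = as.integer(n),
                 mu_mean = mu_mean, mu_spread = mu_spread,
                 cov_range = cov_range, diag_range = diag_range,
                 beta_range = beta_range, noise = noise,
                 gaussian_second_arg = gaussian_second_arg),
            class = "elsa_sim_model")
}

#' Named simulation presets
#'
#' The four random-design study configurations:
#' \describe{
#'   \item{`strong_corr`}{strong and weak signals, strongly correlated
#'     covariates: `beta ~ U(-2, 2)`, off-diagonals `U(0.4, 0.6)`,
#'     noise variance 0.15.}
#'   \item{`weak_corr`}{same signals, weak correlations: off-diagonals
#'     `U(0, 0.2)`.}
#'   \item{`strong_beta`}{strong signals only, weak correlations:
#'     `beta ~ U(2, 3)`.}
#'   \item{`weak_beta`}{weak signals, weak correlations:
#'     `beta ~ U(-0.2, 0.2)`.}
#' }
#'
#' @param name preset name.
#' @param p,r,n dimensions passed to [sim_model()].
#' @param ... overrides for the remaining [sim_model()] fields.
#' @return an `elsa_sim_model`.
#' @export
sim_preset <- function(name = c("strong_corr", "weak_corr", "strong_beta",
                                "weak_beta"),
                       p = 1000L, r, n = 180L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    strong_corr = list(),
    weak_corr = list(cov_range = c(0.0, 0.2)),
    strong_beta = list(cov_range = c(0.0, 0.2), beta_range = c(2, 3)),
    weak_beta = list(cov_range = c(0.0, 0.2), beta_range = c(-0.2, 0.2))
  )
  do.call(sim_model, utils::modifyList(c(list(p = p, r = r, n = n), args),
                                       list(...)))
}

#' Draw a random covariance matrix with positive-definiteness repair
#'
#' Draws a symmetric matrix with i.i.d. uniform off-diagonal entries and
#' uniform diagonal entries, then repairs possible indefiniteness (which
#' occurs routinely at large `p`) by clipping eigenvalues at `eps_pd`
#' and reassembling. The eigen decomposition of the repaired matrix is
#' attached as attribute `"eig"` so samplers can reuse it; the raw
#' minimum eigenvalue and the implied pre-repair correlation range are
#' attached as `"min_eigenvalue_raw"` and `"corr_range"`.
#'
#' @param p dimension.
#' @param cov_range,diag_range uniform ranges as in [sim_model()].
#' @param eps_pd eigenvalue floor (default 1e-6).
#' @param seed optional seed.
#' @return a p x p symmetric matrix with attributes described above.
#' @export
draw_covariance <- function(p, cov_range = c(0.4, 0.6),
                            diag_range = c(0.8, 1.2), eps_pd = 1e-6,
                            seed = NULL) {
  stopifnot(p >= 1)
  with_seed(seed, {
    S <- matrix(0, p, p)
    if (p > 1L) {
      up <- upper.tri(S)
      S[up] <- runif(sum(up), cov_range[1], cov_range[2])
      S <- S + t(S)
    }
    diag(S) <- runif(p, diag_range[1], diag_range[2])
    corr <- if (p > 1L) {
      d <- sqrt(diag(S))
      range((S / tcrossprod(d))[upper.tri(S)])
    } else {
      c(NA_real_, NA_real_)
    }
    e <- eigen(S, symmetric = TRUE)
    vals <- pmax(e$values, eps_pd)
    repaired <- e$vectors %*% (vals * t(e$vectors))
    repaired <- (repaired + t(repaired)) / 2
    structure(repaired,
              eig = list(values = vals, vectors = e$vectors),
              min_eigenvalue_raw = min(e$values),
              corr_range = corr)
  })
}

norm_spread <- function(spread, how) if (how == "sd") spread else sqrt(spread)

# Draw the sparse coefficient vector: r nonzeros in one contiguous block
# starting after a uniformly drawn offset j0 in {0, ..., p - r}.
draw_beta <- function(model) {
  beta <- numeric(model$p)
  if (model$r > 0L) {
    j0 <- if (model$r == model$p) 0L else sample.int(model$p - model$r, 1L)
    beta[j0 + seq_len(model$r)] <- runif(model$r, model$beta_range[1],
                                         model$beta_range[2])
  }
  beta
}

#' Generate a dataset from a simulation model
#'
#' Draws `mu`, a repaired covariance, the sparse coefficient block and
#' `n_rows` observations `y = X beta + eps`. The model parameters are
#' redrawn on every call, matching the study protocol in which each
#' replicate is an independent draw of the whole generating mechanism.
#'
#' @param model an [sim_model()].
#' @param n_rows number of rows to generate (defaults to `model$n`).
#' @param seed optional seed; a given seed reproduces the dataset
#'   bit-identically.
#' @param keep_sigma store the full covariance matrix in the result
#'   (disable at large `p` to save memory).
#' @return a list of class `elsa_dataset` with `X`, `y`, `beta`, `mu`,
#'   `Sigma` (or `NULL`), `sigma_eig_range`, `noise_sd` and `seed`.
#' @export
generate <- function(model, n_rows = model$n, seed = NULL, keep_sigma = TRUE) {
  stopifnot(inherits(model, "elsa_sim_model"), n_rows >= 1)
  with_seed(seed, {
    mu <- rnorm(model$p, model$mu_mean,
                norm_spread(model$mu_spread, model$gaussian_second_arg))
    Sigma <- draw_covariance(model$p, model$cov_range, model$diag_range)
    eig <- attr(Sigma, "eig")
    beta <- draw_beta(model)
    Z <- matrix(rnorm(n_rows * model$p), n_rows, model$p)
    X <- sweep(Z %*% (sqrt(eig$values) * t(eig$vectors)), 2L, mu, "+")
    noise_sd <- norm_spread(model$noise, model$gaussian_second_arg)
    y <- as.numeric(X %*% beta + rnorm(n_rows, 0, noise_sd))
    structure(list(X = X, y = y, beta = beta, mu = mu,
                   Sigma = if (keep_sigma) Sigma else NULL,
                   sigma_eig_range = range(eig$values),
                   min_eigenvalue_raw = attr(Sigma, "min_eigenvalue_raw"),
                   noise_sd = noise_sd, model = model, seed = seed),
              class = "elsa_dataset")
  })
}

#' Simulate responses on a fixed design
#'
#' Regenerates only the response on a fixed (e.g. real) design matrix:
#' a contiguous block of `r` coefficients `U(beta_range)` at a random
#' offset and Gaussian noise (default variance 0.4, suited to designs
#' with standardized columns).
#'
#' @param X fixed n x p design matrix.
#' @param r number of relevant covariates (<= p).
#' @param noise noise spread (variance by default).
#' @param beta_range uniform range of nonzero coefficients.
#' @param gaussian_second_arg `"variance"` (default) or `"sd"`.
#' @param seed optional seed.
#' @return a list with `y` and `beta`.
#' @export
generate_fixed_design_response <- function(X, r, noise = 0.4,
                                           beta_range = c(-2, 2),
                                           gaussian_second_arg = c("variance", "sd"),
                                           seed = NULL) {
  gaussian_second_arg <- match.arg(gaussian_second_arg)
  stopifnot(is.matrix(X), r >= 0, r <= ncol(X))
  model <- sim_model(p = ncol(X), r = r, n = max(nrow(X), 2L),
                     beta_range = beta_range, noise = noise,
                     gaussian_second_arg = gaussian_second_arg)
  with_seed(seed, {
    beta <- draw_beta(model)
    sdn <- norm_spread(noise, gaussian_second_arg)
    y <- as.numeric(X %*% beta + rnorm(nrow(X), 0, sdn))
    list(y = y, beta = beta)
  })
}

#' Synthetic gene-expression-like fixed design
#'
#' A deterministic (per seed) stand-in for a real expression matrix:
#' block-correlated Gaussian columns (blocks of correlated probes with
#' block-specific correlation drawn from `rho_range`), standardized to
#' mean zero and unit sample standard deviation. Synthetic: it emulates
#' only the correlation structure, not any real expression values.
#'
#' @param n,p dimensions (defaults 120 x 200).
#' @param block_size number of columns per correlated block.
#' @param rho_range range of within-block correlations.
#' @param seed seed (default 1) making the design reproducible.
#' @return an n x p matrix with standardized columns.
#' @export
make_synthetic_gene_design <- function(n = 120L, p = 200L, block_size = 20L,
                                       rho_range = c(0.3, 0.8), seed = 1L) {
  with_seed(seed, {
    nblocks <- ceiling(p / block_size)
    X <- matrix(0, n, p)
    for (b in seq_len(nblocks)) {
      cols <- ((b - 1L) * block_size + 1L):min(b * block_size, p)
      rho <- runif(1, rho_range[1], rho_range[2])
      shared <- rnorm(n)
      X[, cols] <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(rnorm(n * length(cols)), n)
    }
    scale(X)[, , drop = FALSE]
  })
}
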