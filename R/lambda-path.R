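#' Smallest penalty with an all-zero fit
#'
#' Computes the entry point of the penalty path: the smallest `lambda`
#' for which every slope coefficient of the penalized fit is zero. On
#' internally standardized columns this is
#' `max_j |<x_j, y - mean(y)>| / (n * alpha)` for the l1-containing
#' families (with `alpha = 1` for lasso, adaptive lasso and SCAD; the
#' adaptive lasso uses weighted columns `x_j / w_j`). The all-zero
#' solution is also stationary for SCAD at this value because its
#' penalty derivative equals `lambda` near the origin.
#'
#' @param X numeric design matrix (n x p).
#' @param y numeric response of length n.
#' @param spec a [penalty_spec()] (or family name).
#' @return positive scalar.
#' @details Zero-variance columns carry no signal and are excluded from
#'   the maximum with a warning. A constant response is an error: there
#'   is no signal to threshold.
#' @examples
#' X <- cbind(c(1, -1)); y <- c(1, -1)
#' compute_lambda_max(X, y, "lasso")  # = 1
#' @export
compute_lambda_max <- function(X, y, spec = penalty_spec("lasso")) {
  spec <- as_penalty_spec(spec)
  X <- assert_finite_matrix(X, y)
  if (ncol(X) < 1L) stop("need at least one covariate", call. = FALSE)
  if (sd(y) < 1e-12 * (1 + abs(mean(y)))) {
    stop("degenerate response: y is constant", call. = FALSE)
  }
  m <- std_moments(X)
  if (any(m$zero)) {
    warning(sum(m$zero), " zero-variance column(s) excluded from lambda_max")
    if (all(m$zero)) stop("all columns have zero variance", call. = FALSE)
  }
  Xs <- standardize_columns(X, m)
  if (spec$family == "alasso" && !is.null(spec$weights)) {
    Xs <- sweep(Xs, 2L, spec$weights, "/")
  }
  n <- nrow(X)
  g <- abs(crossprod(Xs, y - mean(y))) / n
  g[m$zero] <- 0
  max(g) / spec$alpha
}

#' Log-spaced penalty path
#'
#' A descending geometric sequence of `L` penalty values from
#' `lambda_max` down to `lambda_max * exp(-6)`, equally spaced on the log
#' scale (consecutive ratio `exp(-6 / (L - 1))`).
#'
#' @param lambda_max positive scalar, usually from [compute_lambda_max()].
#' @param L number of path values (default 100).
#' @return an object of class `elsa_lambda_path` with fields `values`,
#'   `lambda_max` and `L`.
#' @examples
#' make_lambda_path(1, L = 5)$values
#' @export
make_lambda_path <- function(lambda_max, L = 100L) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      !is.finite(lambda_max) || lambda_max <= 0) {
    stop("lambda_max must be a positive number", call. = FALSE)
  }
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("L must be at least 2", call. = FALSE)
  values <- lambda_max * exp(seq(0, -6, length.out = L))
  structure(list(values = values, lambda_max = lambda_max, L = L),
            class = "elsa_lambda_path")
}

#' @export
print.elsa_lambda_path <- function(x, ...) {
  cat(sprintf("penalty path: %d values, %.6g down to %.6g (ratio e^-6)\n",
              x$L, x$lambda_max, x$values[x$L]))
  invisible(x)
}

as_lambda_path <- function(path) {
  if (inherits(path, "elsa_lambda_path")) return(path)
  stop("path must be built with make_lambda_path()", call. = FALSE)
}
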