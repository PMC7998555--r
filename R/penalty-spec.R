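#' Describe a penalty family
#'
#' A `penalty_spec` names one of the five supported penalty families and
#' carries its family-specific parameters: the elastic-net mixing weight
#' `alpha` (the lasso is `alpha = 1`), the SCAD shape parameter `a`
#' (default 3.7, the value usually recommended for linear models), and,
#' for the adaptive lasso, per-covariate penalty weights. Weights are
#' derived from a preliminary ridge fit by [fit_adaptive_lasso_path()],
#' not set by the user.
#'
#' @param family one of `"lasso"`, `"elnet"`, `"alasso"`, `"lars"`,
#'   `"scad"`.
#' @param alpha elastic-net mixing weight in (0, 1]; ignored (fixed at 1)
#'   for the other families.
#' @param a SCAD shape parameter, must exceed 2.
#' @param weights optional nonnegative per-covariate penalty weights
#'   (adaptive lasso only; normally filled in internally).
#' @return an object of class `elsa_penalty_spec`.
#' @examples
#' penalty_spec("elnet", alpha = 0.25)
#' penalty_spec("scad")
#' @export
penalty_spec <- function(family = c("lasso", "elnet", "alasso", "lars", "scad"),
                         alpha = 1, a = 3.7, weights = NULL) {
  family <- match.arg(family)
  if (family != "elnet") alpha <- 1
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(a) || length(a) != 1L || a <= 2) {
    stop("SCAD shape parameter a must exceed 2", call. = FALSE)
  }
  if (!is.null(weights)) {
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      stop("penalty weights must be finite and positive", call. = FALSE)
    }
  }
  structure(list(family = family, alpha = alpha, a = a, weights = weights),
            class = "elsa_penalty_spec")
}

#' @export
print.elsa_penalty_spec <- function(x, ...) {
  extra <- switch(x$family,
    elnet = sprintf(" (alpha = %g)", x$alpha),
    scad = sprintf(" (a = %g)", x$a),
    alasso = if (is.null(x$weights)) " (weights pending)" else " (weighted)",
    "")
  cat("penalty family: ", x$family, extra, "\n", sep = "")
  invisible(x)
}

as_penalty_spec <- function(spec) {
  if (inherits(spec, "elsa_penalty_spec")) spec else penalty_spec(spec)
}
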