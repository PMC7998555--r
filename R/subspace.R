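#' Random covariate-subspace schemes
#'
#' A subspace keeps all `n` rows of the data but only a random subset of
#' the `p` covariate columns. Three selection schemes are supported:
#' \describe{
#'   \item{approach 1}{draw `p` covariates with replacement and keep the
#'     distinct ones; the random subspace size `p*` has expected value
#'     `p * (1 - (1 - 1/p)^p)`, about `0.63 p`.}
#'   \item{approach 2}{draw `n` covariates without replacement (clipped
#'     at `p` when `n > p`).}
#'   \item{approach 3}{draw `floor(n/2)` covariates without replacement.}
#' }
#'
#' @param approach 1, 2 or 3.
#' @param p total number of covariates (>= 1).
#' @param n sample size (>= 2); determines the subspace size for
#'   approaches 2 and 3.
#' @return an object of class `elsa_subspace_scheme`.
#' @export
subspace_scheme <- function(approach, p, n) {
  approach <- as.integer(approach)
  stopifnot(approach %in% 1:3, p >= 1, n >= 2)
  structure(list(approach = approach, p = as.integer(p), n = as.integer(n)),
            class = "elsa_subspace_scheme")
}

#' Draw one covariate subspace
#'
#' @param scheme a [subspace_scheme()].
#' @param seed optional seed for the draw.
#' @return a list with `indices` (sorted distinct covariate indices,
#'   1-based) and `approach`.
#' @export
draw_subspace <- function(scheme, seed = NULL) {
  stopifnot(inherits(scheme, "elsa_subspace_scheme"))
  p <- scheme$p
  idx <- with_seed(seed, switch(scheme$approach,
    unique(sample.int(p, p, replace = TRUE)),
    sample.int(p, min(scheme$n, p)),
    sample.int(p, min(scheme$n %/% 2L, p))
  ))
  list(indices = sort(idx), approach = scheme$approach)
}

#' Expected fraction of distinct covariates under approach 1
#'
#' The expected proportion of the `p` covariates that appear at least
#' once among `p` draws with replacement: `1 - (1 - 1/p)^p`, which
#' decreases from 1 at `p = 1` towards `1 - 1/e` (about 0.63).
#'
#' @param p number of covariates (>= 1).
#' @return a number in (0, 1].
#' @examples
#' expected_distinct_fraction(2)     # 0.75
#' expected_distinct_fraction(1000)  # ~0.632
#' @export
expected_distinct_fraction <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1) {
    stop("p must be a number >= 1", call. = FALSE)
  }
  1 - (1 - 1 / p)^p
}
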