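#' Parse a method name
#'
#' Methods are named `[E]{Tr|CV}<Family>[(args)]`: an optional ensemble
#' prefix `E`, the prediction rule (`Tr` = trimmed path average, `CV` =
#' 10-fold cross-validated penalty), the penalty family (`Lasso`,
#' `ELNET`, `Alasso`, `LARS`, `SCAD`) and, in parentheses, the subspace
#' approach `j` in 1..3 for ensemble methods and/or the elastic-net
#' `alpha`. Examples: `"CVLasso"`, `"TrSCAD"`, `"ETrLasso(1)"`,
#' `"ECVELNET(3,0.25)"`, `"TrELNET(0.5)"`. Family casing is not
#' significant; re-serialization is canonical.
#'
#' @param name a method name from the grammar above.
#' @return a list with `name` (canonical spelling), `family`, `rule`
#'   (`"trimmed"` or `"cv"`), `approach` (`NA` = fit on all covariates)
#'   and `alpha`.
#' @examples
#' parse_method_name("ETrELNET(1,0.25)")
#' @export
parse_method_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec(
    "^(E?)(Tr|CV)(ALasso|Lasso|ELNET|LARS|SCAD)(\\(([^)]*)\\))?$",
    name, ignore.case = TRUE))[[1]]
  if (length(m) == 0L) {
    stop("cannot parse method name '", name, "'; expected [E]{Tr|CV}",
         "{Lasso|ELNET|Alasso|LARS|SCAD}[(j)][(alpha)][(j,alpha)]",
         call. = FALSE)
  }
  ensemble <- toupper(m[2]) == "E"
  rule <- if (toupper(m[3]) == "TR") "trimmed" else "cv"
  family <- c(alasso = "alasso", lasso = "lasso", elnet = "elnet",
              lars = "lars", scad = "scad")[[tolower(m[4])]]
  args <- if (m[5] == "") numeric(0) else {
    out <- suppressWarnings(as.numeric(strsplit(m[6], ",")[[1]]))
    if (any(is.na(out))) stop("non-numeric argument in '", name, "'", call. = FALSE)
    out
  }
  approach <- NA_integer_
  alpha <- if (family == "elnet") NA_real_ else 1
  if (ensemble) {
    if (family == "elnet") {
      if (length(args) != 2L) stop("'", name, "' needs (j, alpha)", call. = FALSE)
      approach <- as.integer(args[1]); alpha <- args[2]
    } else {
      if (length(args) != 1L) stop("'", name, "' needs (j)", call. = FALSE)
      approach <- as.integer(args[1])
    }
    if (!approach %in% 1:3) stop("subspace approach must be 1, 2 or 3", call. = FALSE)
  } else {
    if (family == "elnet") {
      if (length(args) != 1L) stop("'", name, "' needs (alpha)", call. = FALSE)
      alpha <- args[1]
    } else if (length(args) != 0L) {
      stop("'", name, "' takes no arguments", call. = FALSE)
    }
  }
  if (family == "elnet" && (alpha <= 0 || alpha > 1)) {
    stop("elastic-net alpha must lie in (0, 1]", call. = FALSE)
  }
  desc <- list(family = family, rule = rule, approach = approach, alpha = alpha)
  desc$name <- format_method_name(desc)
  desc
}

#' @rdname parse_method_name
#' @param desc a parsed descriptor.
#' @export
format_method_name <- function(desc) {
  fam <- c(lasso = "Lasso", elnet = "ELNET", alasso = "Alasso",
           lars = "LARS", scad = "SCAD")[[desc$family]]
  args <- c(if (!is.na(desc$approach)) desc$approach,
            if (desc$family == "elnet") format(desc$alpha, digits = 4))
  paste0(if (!is.na(desc$approach)) "E", if (desc$rule == "trimmed") "Tr" else "CV",
         fam, if (length(args)) paste0("(", paste(args, collapse = ","), ")"))
}

#' Method-fitting control parameters
#'
#' Collects the tuning constants shared by every method: ensemble size
#' `B`, path length `L`, per-tail trim fraction, CV fold count, SCAD
#' shape `a` and the seed from which all method-internal randomness
#' (subspace draws, fold assignments) flows.
#'
#' @param B ensemble size (default 250).
#' @param L penalty-path length (default 100).
#' @param trim_fraction per-tail trim (default 0.10).
#' @param K CV folds (default 10).
#' @param a SCAD shape (default 3.7).
#' @param seed optional integer seed.
#' @return a list of class `elsa_control`.
#' @export
method_control <- function(B = 250L, L = 100L, trim_fraction = 0.10, K = 10L,
                           a = 3.7, seed = NULL) {
  structure(list(B = as.integer(B), L = as.integer(L),
                 trim_fraction = trim_fraction, K = as.integer(K), a = a,
                 seed = seed),
            class = "elsa_control")
}

method_spec <- function(desc, control) {
  penalty_spec(desc$family,
               alpha = if (desc$family == "elnet") desc$alpha else 1,
               a = control$a)
}

# Per-replicate cache of full-data path fits and CV selections, so that
# e.g. CVLasso and TrLasso (same family, same data) share one path fit.
cache_key <- function(desc) paste(desc$family, desc$alpha, sep = "_")

cached_path <- function(cache, key, fit_fun) {
  if (is.null(cache)) return(fit_fun())
  store <- paste0("path_", key)
  if (is.null(cache[[store]])) cache[[store]] <- fit_fun()
  cache[[store]]
}

#' Fit a named method
#'
#' Fits one method of the naming grammar on `(X, y)`: a plain penalized
#' fit on all covariates, or a random-subspace ensemble when the name
#' carries an approach index. The result predicts with its rule via
#' `predict()`.
#'
#' @param X,y training data.
#' @param method a method name or a [parse_method_name()] descriptor.
#' @param control a [method_control()].
#' @param cache optional environment shared by several methods fitted on
#'   the same data, to reuse full-data path fits.
#' @return an object of class `elsa_method_fit`.
#' @export
fit_method <- function(X, y, method, control = method_control(), cache = NULL) {
  desc <- if (is.character(method)) parse_method_name(method) else method
  X <- assert_finite_matrix(X, y)
  spec <- method_spec(desc, control)
  if (!is.na(desc$approach)) {
    scheme <- subspace_scheme(desc$approach, ncol(X), nrow(X))
    rule <- prediction_rule(desc$rule, control$trim_fraction, control$K)
    fit <- fit_ensemble(X, y, scheme, spec, rule, B = control$B,
                        L = control$L, seed = control$seed)
  } else {
    key <- cache_key(desc)
    full <- cached_path(cache, key, function() {
      fit_path(X, y, spec, L = control$L, seed = control$seed)
    })
    fit <- if (desc$rule == "trimmed") {
      list(kind = "trimmed", path = full, trim = control$trim_fraction)
    } else {
      sel <- cv_select(X, y, spec, K = control$K, seed = control$seed,
                       L = control$L, full_fit = full)
      list(kind = "cv", beta = sel$beta, intercept = sel$intercept,
           lambda = sel$lambda, index = sel$index)
    }
  }
  structure(list(descriptor = desc, fit = fit, control = control),
            class = "elsa_method_fit")
}

#' @export
predict.elsa_method_fit <- function(object, newx, ...) {
  newx <- if (is.matrix(newx)) newx else matrix(newx, nrow = 1L)
  f <- object$fit
  if (inherits(f, "elsa_ensemble")) return(predict(f, newx))
  if (f$kind == "trimmed") {
    predict_trimmed(f$path, newx, f$trim)
  } else {
    as.numeric(newx %*% f$beta + f$intercept)
  }
}

#' @export
print.elsa_method_fit <- function(x, ...) {
  cat("fitted method:", x$descriptor$name, "\n")
  invisible(x)
}
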