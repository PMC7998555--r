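#' Prediction rule for a fitted path
#'
#' Two ways to turn a fitted member into a single predictor: `"cv"`
#' predicts at the penalty selected by K-fold cross-validation;
#' `"trimmed"` predicts, per test point, with the trimmed average of the
#' predictions along the whole penalty path (default 10% dropped in each
#' tail), replacing penalty selection with robust averaging.
#'
#' @param rule `"trimmed"` or `"cv"`.
#' @param trim_fraction per-tail trim proportion in [0, 0.5) (trimmed
#'   rule).
#' @param K folds (cv rule).
#' @return an object of class `elsa_prediction_rule`.
#' @export
prediction_rule <- function(rule = c("trimmed", "cv"), trim_fraction = 0.10,
                            K = 10L) {
  rule <- match.arg(rule)
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  structure(list(rule = rule, trim_fraction = trim_fraction, K = as.integer(K)),
            class = "elsa_prediction_rule")
}

# Row-wise trimmed means of an n0 x L prediction matrix: sort each row,
# drop floor(trim * L) entries from each tail, average the rest.
trimmed_row_means <- function(P, trim_fraction) {
  L <- ncol(P)
  drop_k <- floor(trim_fraction * L)
  if (L - 2 * drop_k < 1) {
    stop("trim_fraction leaves no predictions to average", call. = FALSE)
  }
  keep <- (drop_k + 1L):(L - drop_k)
  apply(P, 1L, function(v) mean(sort(v)[keep]))
}

#' Trimmed-average prediction from a fitted path
#'
#' Computes the `L` per-path-point predictions for each test point,
#' sorts them, drops `floor(trim_fraction * L)` from each tail and
#' returns the mean of the rest.
#'
#' @param path an `elsa_coef_path`.
#' @param x0 a single covariate vector or a matrix of test points
#'   (columns matching the fit).
#' @param trim_fraction per-tail trim proportion.
#' @return a numeric prediction per test point.
#' @examples
#' # a path whose 100 predictions at x0 = 0 are its intercepts 1..100:
#' pf <- elsar:::new_coef_path(matrix(0, 1, 100), 1:100,
#'                             penalty_spec("lasso"), NULL)
#' predict_trimmed(pf, 0)  # mean of 11..90 = 50.5
#' @export
predict_trimmed <- function(path, x0, trim_fraction = 0.10) {
  stopifnot(inherits(path, "elsa_coef_path"))
  P <- predict(path, x0)
  trimmed_row_means(P, trim_fraction)
}

#' Variance of an ensemble of correlated predictors
#'
#' For `B` identically distributed member predictors with variance
#' `sigma2` and pairwise correlation `rho`, the variance of their mean
#' is `rho * sigma2 + (1 - rho) * sigma2 / B`: growing the ensemble
#' removes the second term but leaves the correlation floor
#' `rho * sigma2`, which is why weakly correlated members (small
#' subspaces) pay off.
#'
#' @param rho pairwise correlation in [-1, 1].
#' @param sigma2 member variance (> 0).
#' @param B ensemble size (>= 1).
#' @return the variance of the ensemble mean.
#' @export
ensemble_variance <- function(rho, sigma2, B) {
  stopifnot(rho >= -1, rho <= 1, sigma2 > 0, B >= 1)
  rho * sigma2 + (1 - rho) * sigma2 / B
}

#' Fit a random-subspace ensemble
#'
#' Draws `B` independent covariate subspaces, fits the requested penalty
#' family on each (the member sees all rows but only its own columns,
#' with its own `lambda_max` and path), and stores what its prediction
#' rule needs: the full coefficient path for the trimmed rule, or the
#' CV-selected coefficients for the cv rule. A member whose fit fails is
#' excluded from aggregation; the fit aborts if more than 10% of members
#' fail.
#'
#' @inheritParams fit_path
#' @param scheme a [subspace_scheme()]; its `p` and `n` must match `X`.
#' @param rule a [prediction_rule()].
#' @param B number of members.
#' @param seed seed driving subspace draws and member CV folds.
#' @return an object of class `elsa_ensemble`.
#' @export
fit_ensemble <- function(X, y, scheme, spec = penalty_spec("lasso"),
                         rule = prediction_rule("trimmed"), B = 250L,
                         L = 100L, seed = NULL) {
  spec <- as_penalty_spec(spec)
  X <- assert_finite_matrix(X, y)
  stopifnot(inherits(scheme, "elsa_subspace_scheme"), B >= 1)
  if (scheme$p != ncol(X)) stop("scheme p does not match ncol(X)", call. = FALSE)
  seeds <- child_seeds(seed, 2L * B)
  members <- vector("list", B)
  failures <- 0L
  for (b in seq_len(B)) {
    draw <- draw_subspace(scheme, seed = seeds[[b]])
    Xb <- X[, draw$indices, drop = FALSE]
    fit_b <- tryCatch({
      if (rule$rule == "trimmed") {
        fit_path(Xb, y, spec, L = L, seed = seeds[[B + b]])
      } else {
        sel <- cv_select(Xb, y, spec, K = rule$K, L = L, seed = seeds[[B + b]])
        list(beta = sel$beta, intercept = sel$intercept, lambda = sel$lambda)
      }
    }, error = function(e) e)
    if (inherits(fit_b, "error")) {
      failures <- failures + 1L
      members[[b]] <- NULL
    } else {
      members[[b]] <- list(indices = draw$indices, fit = fit_b)
    }
  }
  if (failures > 0.10 * B) {
    stop("ensemble fit failed: ", failures, " of ", B, " members errored",
         call. = FALSE)
  }
  structure(list(members = Filter(Negate(is.null), members), spec = spec,
                 rule = rule, scheme = scheme, B = B, p = ncol(X),
                 failures = failures),
            class = "elsa_ensemble")
}

# Prediction of one member at the full-column test matrix X0.
member_predict <- function(member, X0, rule) {
  X0b <- X0[, member$indices, drop = FALSE]
  if (rule$rule == "trimmed") {
    predict_trimmed(member$fit, X0b, rule$trim_fraction)
  } else {
    as.numeric(X0b %*% member$fit$beta + member$fit$intercept)
  }
}

#' Predict from a subspace ensemble
#'
#' The ensemble prediction at each test point is the unweighted mean of
#' the member predictions (each member applying its own rule on its own
#' covariate subset). `X0` must carry all `p` original columns.
#'
#' @param object an `elsa_ensemble`.
#' @param newx n0 x p matrix of test points.
#' @param members_matrix if `TRUE`, also return the n0 x B matrix of
#'   member predictions as attribute `"members"`.
#' @param ... unused.
#' @return length-n0 numeric vector of predictions.
#' @export
predict.elsa_ensemble <- function(object, newx, members_matrix = FALSE, ...) {
  newx <- if (is.matrix(newx)) newx else matrix(newx, nrow = 1L)
  if (ncol(newx) != object$p) {
    stop("newx must have the full ", object$p, " columns", call. = FALSE)
  }
  preds <- vapply(object$members, member_predict, numeric(nrow(newx)),
                  X0 = newx, rule = object$rule)
  preds <- matrix(preds, nrow = nrow(newx))
  out <- rowMeans(preds)
  if (members_matrix) attr(out, "members") <- preds
  out
}

#' @export
print.elsa_ensemble <- function(x, ...) {
  cat(sprintf("subspace ensemble: %s/%s, approach %d, B = %d (%d failed)\n",
              x$spec$family, x$rule$rule, x$scheme$approach, x$B, x$failures))
  invisible(x)
}

#' Export / import an ensemble as JSON
#'
#' Serializes member covariate index sets and coefficients (path matrix
#' + intercepts for the trimmed rule, selected coefficients for the cv
#' rule) for reproducibility audits. `read_ensemble_json()` restores an
#' object that predicts identically.
#'
#' @param model an `elsa_ensemble`.
#' @param file output / input path.
#' @return `write_ensemble_json()` returns `file` invisibly;
#'   `read_ensemble_json()` returns an `elsa_ensemble`.
#' @export
write_ensemble_json <- function(model, file) {
  stopifnot(inherits(model, "elsa_ensemble"))
  members <- lapply(model$members, function(mb) {
    if (model$rule$rule == "trimmed") {
      list(indices = mb$indices, betas = mb$fit$betas,
           intercepts = mb$fit$intercepts)
    } else {
      list(indices = mb$indices, beta = mb$fit$beta,
           intercept = mb$fit$intercept, lambda = mb$fit$lambda)
    }
  })
  obj <- list(family = model$spec$family, alpha = model$spec$alpha,
              a = model$spec$a, rule = unclass(model$rule),
              scheme = unclass(model$scheme), B = model$B, p = model$p,
              failures = model$failures, members = members)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_ensemble_json
#' @export
read_ensemble_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  rule <- prediction_rule(obj$rule$rule, obj$rule$trim_fraction, obj$rule$K)
  spec <- penalty_spec(obj$family, alpha = obj$alpha, a = obj$a)
  scheme <- subspace_scheme(obj$scheme$approach, obj$scheme$p, obj$scheme$n)
  members <- lapply(seq_len(nrow_or_len(obj$members)), function(i) {
    mb <- member_row(obj$members, i)
    if (rule$rule == "trimmed") {
      betas <- matrix(unlist(mb$betas), nrow = length(mb$indices))
      fit <- new_coef_path(betas, unlist(mb$intercepts), spec, NULL)
    } else {
      fit <- list(beta = unlist(mb$beta), intercept = mb$intercept,
                  lambda = mb$lambda)
    }
    list(indices = unlist(mb$indices), fit = fit)
  })
  structure(list(members = members, spec = spec, rule = rule, scheme = scheme,
                 B = obj$B, p = obj$p, failures = obj$failures),
            class = "elsa_ensemble")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
member_row <- function(x, i) if (is.data.frame(x)) lapply(x, `[[`, i) else x[[i]]
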