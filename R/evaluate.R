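#' Mean squared prediction error
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return the mean squared difference.
#' @export
mspe <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) < 1L) stop("need at least one test point", call. = FALSE)
  mean((y_true - y_pred)^2)
}

#' Efficiency of a method relative to a reference
#'
#' The per-replicate ratio `mspe_ref / mspe_method` averaged over
#' replicates (a value above 1 means the method beats the reference),
#' with the Monte-Carlo standard deviation of that mean
#' (`sd(ratios) / sqrt(M)`). With a single replicate the SD is reported
#' as 0 and flagged via attribute `"degenerate"`.
#'
#' @param mspe_ref,mspe_method positive per-replicate MSPE vectors of
#'   equal length.
#' @return a list with `eff`, `sd`, `ratios` and `win_fraction` (the
#'   fraction of replicates with ratio > 1).
#' @export
efficiency <- function(mspe_ref, mspe_method) {
  if (length(mspe_ref) != length(mspe_method)) {
    stop("MSPE vectors must have equal length", call. = FALSE)
  }
  if (any(mspe_ref <= 0) || any(mspe_method <= 0)) {
    stop("MSPE values must be positive", call. = FALSE)
  }
  ratios <- mspe_ref / mspe_method
  M <- length(ratios)
  out <- list(eff = mean(ratios),
              sd = if (M > 1L) sd(ratios) / sqrt(M) else 0,
              ratios = ratios,
              win_fraction = mean(ratios > 1))
  if (M == 1L) attr(out, "degenerate") <- TRUE
  out
}

normalize_methods <- function(methods, control) {
  lapply(methods, function(mth) {
    if (is.character(mth)) mth <- list(name = mth)
    desc <- parse_method_name(mth$name)
    ctl <- control
    for (f in intersect(names(mth), c("B", "L", "trim_fraction", "K", "a"))) {
      ctl[[f]] <- mth[[f]]
    }
    list(desc = desc, control = ctl)
  })
}

build_eff_table <- function(mspe_mat, reference, M_used, dropped) {
  methods <- colnames(mspe_mat)
  if (!reference %in% methods) {
    stop("reference method '", reference, "' not among the fitted methods",
         call. = FALSE)
  }
  ref <- mspe_mat[, reference]
  rows <- lapply(methods, function(mn) {
    e <- efficiency(ref, mspe_mat[, mn])
    data.frame(method = mn, eff = e$eff, sd = e$sd, M = M_used,
               win_fraction = e$win_fraction,
               ratio_sd = if (M_used > 1) sd(e$ratios) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  structure(tab, class = c("elsa_eff_table", "data.frame"),
            mspe = mspe_mat, reference = reference, dropped = dropped)
}

#' @export
print.elsa_eff_table <- function(x, ...) {
  cat("efficiency vs ", attr(x, "reference"), " (M = ", x$M[1], "):\n", sep = "")
  cells <- ifelse(x$method == attr(x, "reference"), "-",
                  sprintf("%.3f(%.3f)", x$eff, x$sd))
  for (i in seq_len(nrow(x))) cat(sprintf("  %-22s %s\n", x$method[i], cells[i]))
  if (attr(x, "dropped") > 0) {
    cat("  (", attr(x, "dropped"), " replicate(s) dropped after method failure)\n",
        sep = "")
  }
  invisible(x)
}

#' Write an efficiency table
#'
#' Writes the table as CSV (method, eff, sd, M, win_fraction) and,
#' optionally, as a formatted text table using the `x.xxx(0.00x)` cell
#' style, plus the full per-replicate MSPE matrix.
#'
#' @param tab an `elsa_eff_table`.
#' @param file CSV output path.
#' @param txt_file optional formatted text output path.
#' @param mspe_file optional CSV path for the per-replicate MSPE matrix.
#' @export
write_eff_table <- function(tab, file, txt_file = NULL, mspe_file = NULL) {
  stopifnot(inherits(tab, "elsa_eff_table"))
  write.csv(as.data.frame(tab), file, row.names = FALSE)
  if (!is.null(txt_file)) {
    lines <- c(sprintf("efficiency vs %s (M = %d)", attr(tab, "reference"),
                       tab$M[1]),
               sprintf("%-22s %s", tab$method,
                       ifelse(tab$method == attr(tab, "reference"), "-",
                              sprintf("%.3f(%.3f)", tab$eff, tab$sd))))
    writeLines(lines, txt_file)
  }
  if (!is.null(mspe_file)) write.csv(attr(tab, "mspe"), mspe_file, row.names = FALSE)
  invisible(file)
}

fit_and_score <- function(Xtr, ytr, Xte, yte, specs, rep_seed) {
  cache <- new.env(parent = emptyenv())
  out <- numeric(length(specs))
  names(out) <- vapply(specs, function(s) s$desc$name, character(1))
  for (i in seq_along(specs)) {
    ctl <- specs[[i]]$control
    ctl$seed <- rep_seed
    fit <- fit_method(Xtr, ytr, specs[[i]]$desc, ctl, cache = cache)
    out[i] <- mspe(yte, predict(fit, Xte))
  }
  out
}

#' Random-design efficiency study
#'
#' The replicate protocol for simulated random designs: each replicate
#' independently draws a training set of `model$n` rows and a test set
#' of `round(test_fraction * n)` rows from one draw of the generating
#' mechanism (same coefficients and covariance within a replicate),
#' fits every method on the same training data, and scores MSPE on the
#' same test data. Efficiencies are the means of per-replicate MSPE
#' ratios against the reference. A method failure drops the whole
#' replicate for all methods, preserving the paired comparison.
#'
#' @param model an [sim_model()].
#' @param methods character vector of method names, or a list whose
#'   elements are names or lists like `list(name = "ETrLasso(1)",
#'   B = 100)` overriding control fields per method.
#' @param M number of replicates.
#' @param test_fraction test-set fraction of `n` (default 0.3).
#' @param control shared [method_control()].
#' @param reference reference method name (default `"CVLasso"`), which
#'   must be present in `methods`.
#' @param seed seed driving the whole study.
#' @param progress print a dot per replicate.
#' @return an `elsa_eff_table` (data frame with columns `method`, `eff`,
#'   `sd`, `M`, `win_fraction`, `ratio_sd`; per-replicate MSPEs in
#'   attribute `"mspe"`).
#' @export
run_random_design <- function(model, methods, M = 100L,
                              test_fraction = 0.3,
                              control = method_control(),
                              reference = "CVLasso", seed = NULL,
                              progress = FALSE) {
  stopifnot(inherits(model, "elsa_sim_model"), M >= 1)
  specs <- normalize_methods(methods, control)
  n <- model$n
  n0 <- max(1L, round(test_fraction * n))
  seeds <- child_seeds(seed, 2L * M)
  rows <- vector("list", M)
  dropped <- 0L
  for (b in seq_len(M)) {
    dat <- generate(model, n_rows = n + n0, seed = seeds[[b]], keep_sigma = FALSE)
    tr <- seq_len(n)
    res <- tryCatch(
      fit_and_score(dat$X[tr, , drop = FALSE], dat$y[tr],
                    dat$X[-tr, , drop = FALSE], dat$y[-tr],
                    specs, seeds[[M + b]]),
      error = function(e) e)
    if (inherits(res, "error")) {
      dropped <- dropped + 1L
      warning("replicate ", b, " dropped: ", conditionMessage(res))
    } else {
      rows[[b]] <- res
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  mspe_mat <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(mspe_mat)) stop("every replicate failed", call. = FALSE)
  build_eff_table(mspe_mat, reference, nrow(mspe_mat), dropped)
}

#' Fixed-design efficiency study
#'
#' The resplit protocol for a fixed design: the rows of `(X, y)` are
#' repeatedly split at random into a training part (fraction
#' `1 - test_fraction`) and a test part, every method is fitted on the
#' training rows and scored on the test rows, and efficiencies are
#' averaged over resplits. When `response_sim` is given (a list with
#' `r`, and optionally `noise`, `beta_range`), the response is
#' regenerated on the fixed design before every resplit via
#' [generate_fixed_design_response()], so both the response draw and
#' the split vary across replicates.
#'
#' @inheritParams run_random_design
#' @param X,y the fixed dataset.
#' @param resplits number of random splits (study convention: 2000).
#' @param response_sim optional response-simulation settings.
#' @return an `elsa_eff_table`.
#' @export
run_fixed_design <- function(X, y = NULL, methods, resplits = 2000L,
                             test_fraction = 0.3,
                             control = method_control(),
                             reference = "CVLasso", seed = NULL,
                             response_sim = NULL, progress = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  n0 <- round(test_fraction * n)
  if (n0 < 1L || n - n0 < 2L) stop("n too small for the requested split", call. = FALSE)
  if (is.null(y) && is.null(response_sim)) {
    stop("either y or response_sim is required", call. = FALSE)
  }
  specs <- normalize_methods(methods, control)
  seeds <- child_seeds(seed, 3L * resplits)
  rows <- vector("list", resplits)
  dropped <- 0L
  for (b in seq_len(resplits)) {
    yb <- if (is.null(response_sim)) y else {
      generate_fixed_design_response(
        X, r = response_sim$r,
        noise = response_sim$noise %||% 0.4,
        beta_range = response_sim$beta_range %||% c(-2, 2),
        seed = seeds[[b]])$y
    }
    test <- with_seed(seeds[[resplits + b]], sample.int(n, n0))
    res <- tryCatch(
      fit_and_score(X[-test, , drop = FALSE], yb[-test],
                    X[test, , drop = FALSE], yb[test],
                    specs, seeds[[2L * resplits + b]]),
      error = function(e) e)
    if (inherits(res, "error")) {
      dropped <- dropped + 1L
      warning("resplit ", b, " dropped: ", conditionMessage(res))
    } else {
      rows[[b]] <- res
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  mspe_mat <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(mspe_mat)) stop("every resplit failed", call. = FALSE)
  build_eff_table(mspe_mat, reference, nrow(mspe_mat), dropped)
}

#' Efficiency as a function of model complexity
#'
#' Runs the random-design protocol at each value of `r` (number of
#' relevant covariates) and collects the efficiency-versus-`r/p` curves
#' that summarise how the methods compare as the model gets denser.
#'
#' @param preset a [sim_preset()] name or a function `r -> elsa_sim_model`.
#' @param r_values integer vector of `r` values.
#' @inheritParams run_random_design
#' @param p,n dimensions used when `preset` is a name.
#' @return a list with `tables` (one `elsa_eff_table` per `r`) and
#'   `curves` (a long data frame: `r`, `r_over_p`, `method`, `eff`,
#'   `sd`).
#' @export
complexity_sweep <- function(preset, r_values, methods, M = 100L,
                             p = 1000L, n = 180L,
                             control = method_control(),
                             reference = "CVLasso", seed = NULL,
                             progress = FALSE) {
  make_model <- if (is.function(preset)) preset else {
    function(r) sim_preset(preset, p = p, r = r, n = n)
  }
  seeds <- child_seeds(seed, length(r_values))
  tables <- vector("list", length(r_values))
  names(tables) <- as.character(r_values)
  for (i in seq_along(r_values)) {
    tables[[i]] <- run_random_design(make_model(r_values[i]), methods, M = M,
                                     control = control, reference = reference,
                                     seed = seeds[[i]], progress = progress)
  }
  curves <- do.call(rbind, lapply(seq_along(r_values), function(i) {
    tab <- tables[[i]]
    data.frame(r = r_values[i], r_over_p = r_values[i] / make_model(r_values[i])$p,
               method = tab$method, eff = tab$eff, sd = tab$sd)
  }))
  list(tables = tables, curves = curves)
}
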