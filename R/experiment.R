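#' Load an experiment configuration
#'
#' Reads a YAML (or JSON) experiment description and fills in defaults.
#' Recognised fields: `model` (one of the [sim_preset()] names, or
#' `"csv"` with `x_csv`/`y_csv` paths), `design` (`"random"` or
#' `"fixed"`), `p`, `r` (or `r_grid` for a sweep), `n`, `M`, `resplits`,
#' `B`, `L`, `trim_fraction`, `K`, `a`, `test_fraction`, `alpha`,
#' `methods` (character vector, required, containing the reference),
#' `reference`, `seed`, `out_dir`, and `response_sim` (list with `r`,
#' `noise` for fixed-design response regeneration).
#'
#' @param file path to a YAML/JSON config, or a list with the same
#'   fields.
#' @return a validated list of class `elsa_experiment_config`.
#' @export
experiment_config <- function(file) {
  cfg <- if (is.list(file)) file else yaml::read_yaml(file)
  defaults <- list(design = "random", p = 1000L, n = 180L, M = 100L,
                   resplits = 100L, B = 250L, L = 100L, trim_fraction = 0.10,
                   K = 10L, a = 3.7, test_fraction = 0.3,
                   reference = "CVLasso", seed = 1L, out_dir = ".")
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$methods) || length(cfg$methods) == 0L) {
    stop("config error: 'methods' must be a non-empty list", call. = FALSE)
  }
  lapply(cfg$methods, function(mm) {
    parse_method_name(if (is.list(mm)) mm$name else mm)
  })
  if (is.null(cfg$model)) stop("config error: 'model' is required", call. = FALSE)
  if (cfg$model == "csv") {
    if (is.null(cfg$x_csv)) stop("config error: model 'csv' needs 'x_csv'", call. = FALSE)
  } else if (!cfg$model %in% c("strong_corr", "weak_corr", "strong_beta",
                               "weak_beta", "gene_like")) {
    stop("config error: unknown model '", cfg$model, "'", call. = FALSE)
  }
  structure(cfg, class = "elsa_experiment_config")
}

read_design_csv <- function(x_csv, y_csv = NULL, header = TRUE) {
  xs <- as.matrix(read.csv(x_csv, header = header))
  if (!is.null(y_csv)) {
    y <- as.numeric(read.csv(y_csv, header = header)[[1]])
  } else {
    y <- as.numeric(xs[, ncol(xs)])
    xs <- xs[, -ncol(xs), drop = FALSE]
  }
  list(X = xs, y = y)
}

#' Run a configured experiment
#'
#' Executes the protocol described by a config: builds or loads the
#' data, runs the random- or fixed-design study (or a complexity sweep
#' when `r_grid` is present), and writes the results to `out_dir`:
#' `efficiency.csv`, a formatted `efficiency.txt`, the per-replicate
#' `mspe.csv` and a `run_log.json` recording the seed, package version,
#' problem sizes and failure counts. Deterministic for a fixed seed.
#'
#' @param config an [experiment_config()] (or path / list coercible to
#'   one).
#' @return the `elsa_eff_table` (or sweep list), invisibly; results are
#'   on disk.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "elsa_experiment_config")) config <- experiment_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  control <- method_control(B = config$B, L = config$L,
                            trim_fraction = config$trim_fraction,
                            K = config$K, a = config$a)
  result <- if (!is.null(config$r_grid)) {
    complexity_sweep(config$model, r_values = config$r_grid,
                     methods = config$methods, M = config$M, p = config$p,
                     n = config$n, control = control,
                     reference = config$reference, seed = config$seed)
  } else if (config$model == "csv" || config$model == "gene_like" ||
             config$design == "fixed") {
    dat <- if (config$model == "csv") {
      read_design_csv(config$x_csv, config$y_csv, config$header %||% TRUE)
    } else {
      list(X = make_synthetic_gene_design(n = config$n, p = config$p,
                                          seed = config$seed),
           y = NULL)
    }
    run_fixed_design(dat$X, dat$y, methods = config$methods,
                     resplits = config$resplits,
                     test_fraction = config$test_fraction, control = control,
                     reference = config$reference, seed = config$seed,
                     response_sim = config$response_sim)
  } else {
    model <- sim_preset(config$model, p = config$p, r = config$r, n = config$n)
    run_random_design(model, methods = config$methods, M = config$M,
                      test_fraction = config$test_fraction, control = control,
                      reference = config$reference, seed = config$seed)
  }
  if (inherits(result, "elsa_eff_table")) {
    write_eff_table(result,
                    file.path(config$out_dir, "efficiency.csv"),
                    file.path(config$out_dir, "efficiency.txt"),
                    file.path(config$out_dir, "mspe.csv"))
    dropped <- attr(result, "dropped")
  } else {
    write.csv(result$curves, file.path(config$out_dir, "sweep_curves.csv"),
              row.names = FALSE)
    for (rv in names(result$tables)) {
      write_eff_table(result$tables[[rv]],
                      file.path(config$out_dir, paste0("efficiency_r", rv, ".csv")))
    }
    dropped <- sum(vapply(result$tables, attr, 0L, "dropped"))
  }
  log <- list(seed = config$seed, package_version = as.character(
                utils::packageVersion("elsar")),
              r_version = R.version.string,
              model = config$model, design = config$design,
              p = config$p, n = config$n, r = config$r %||% config$r_grid,
              M = config$M, B = config$B, methods = unlist(lapply(
                config$methods, function(mm) if (is.list(mm)) mm$name else mm)),
              dropped_replicates = dropped,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}
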