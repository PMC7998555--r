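test_that("experiment configs validate their fields", {
  expect_error(experiment_config(list(model = "strong_corr")), "methods")
  expect_error(experiment_config(list(model = "strong_corr", methods = list())),
               "non-empty")
  expect_error(experiment_config(list(methods = "CVLasso")), "model")
  expect_error(experiment_config(list(model = "nope", methods = "CVLasso")),
               "unknown model")
  expect_error(experiment_config(list(model = "csv", methods = "CVLasso")),
               "x_csv")
  cfg <- experiment_config(list(model = "strong_corr", r = 10,
                                methods = c("CVLasso", "TrLasso")))
  expect_s3_class(cfg, "elsa_experiment_config")
  expect_equal(cfg$B, 250L)
  expect_equal(cfg$trim_fraction, 0.10)
})

test_that("run_experiment writes deterministic results from a YAML config", {
  out1 <- file.path(tempdir(), "exp1"); out2 <- file.path(tempdir(), "exp2")
  base <- list(model = "strong_corr", design = "random", p = 12L, r = 3L,
               n = 24L, M = 3L, B = 4L, L = 20L, K = 5L, seed = 17L,
               methods = c("CVLasso", "TrLasso", "ETrLasso(3)"))
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(c(base, list(out_dir = out1)), cfg_file)
  res1 <- run_experiment(cfg_file)
  expect_s3_class(res1, "elsa_eff_table")
  expect_true(all(file.exists(file.path(out1, c("efficiency.csv",
                                                "efficiency.txt",
                                                "mspe.csv",
                                                "run_log.json")))))
  run_experiment(c(base, list(out_dir = out2)))
  expect_identical(readLines(file.path(out1, "efficiency.csv")),
                   readLines(file.path(out2, "efficiency.csv")))
  log <- jsonlite::read_json(file.path(out1, "run_log.json"))
  expect_equal(log$seed, 17L)
  expect_equal(log$dropped_replicates, 0L)
})

test_that("the bundled reduced experiment config parses", {
  f <- system.file("extdata", "table4_reduced.yaml", package = "elsar")
  expect_true(nzchar(f))
  cfg <- experiment_config(f)
  expect_equal(cfg$r, 300L)
  expect_length(cfg$methods, 28L)
  for (nm in cfg$methods) expect_type(parse_method_name(nm), "list")
})

test_that("the command-line driver simulates datasets to CSV", {
  cli <- system.file("cli", "elsa.R", package = "elsar")
  expect_true(nzchar(cli))
  out <- file.path(tempdir(), "cli_sim")
  res <- system2("Rscript", c(cli, "simulate", "--model", "strong_corr",
                              "--p", "15", "--r", "4", "--n", "20",
                              "--seed", "3", "--out", out),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=",
                              paste(.libPaths(), collapse = .Platform$path.sep)))
  expect_true(file.exists(file.path(out, "X.csv")))
  X <- as.matrix(read.csv(file.path(out, "X.csv")))
  expect_equal(dim(X), c(20L, 15L))
  beta <- read.csv(file.path(out, "beta.csv"))$beta_true
  expect_equal(sum(beta != 0), 4L)
})
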