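test_that("mspe and efficiency match hand arithmetic", {
  expect_equal(mspe(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mspe(c(0, 0), c(1, -1)), 1)
  expect_equal(mspe(3, 1), 4)
  expect_error(mspe(1:3, 1:2), "equal length")

  e <- efficiency(c(2, 2), c(1, 4))
  expect_equal(e$eff, 1.25)   # (2/1 + 2/4) / 2
  expect_equal(e$win_fraction, 0.5)
  expect_equal(efficiency(c(1, 2, 3), c(1, 2, 3))$eff, 1)
  expect_equal(efficiency(c(1, 2, 3), c(1, 2, 3))$sd, 0)
  expect_equal(efficiency(c(2, 4), c(1, 2))$eff, 2)
  expect_error(efficiency(c(1, -1), c(1, 1)), "positive")
  e1 <- efficiency(2, 1)
  expect_equal(e1$sd, 0)
  expect_true(isTRUE(attr(e1, "degenerate")))
})

test_that("efficiency is invariant to rescaling the response", {
  withr::with_seed(91, {
    ref <- runif(30, 0.5, 2)
    met <- runif(30, 0.5, 2)
  })
  c2 <- 17.3^2
  expect_equal(efficiency(ref, met)$eff, efficiency(c2 * ref, c2 * met)$eff)
})

test_that("the random-design study pairs methods on identical replicates", {
  model <- sim_model(p = 15, r = 4, n = 30, noise = 0.15)
  tab <- run_random_design(model, c("CVLasso", "TrLasso"), M = 5,
                           control = method_control(L = 40L), seed = 77)
  expect_s3_class(tab, "elsa_eff_table")
  expect_equal(tab$eff[tab$method == "CVLasso"], 1)   # reference vs itself
  expect_equal(tab$sd[tab$method == "CVLasso"], 0)
  mat <- attr(tab, "mspe")
  expect_equal(dim(mat), c(5L, 2L))
  expect_true(all(mat > 0))
  # same seed reproduces the table exactly
  tab2 <- run_random_design(model, c("CVLasso", "TrLasso"), M = 5,
                            control = method_control(L = 40L), seed = 77)
  expect_equal(tab$eff, tab2$eff)
  expect_error(run_random_design(model, c("TrLasso"), M = 2), "reference")
})

test_that("reported SD shrinks like 1/sqrt(M) under replicate subsampling", {
  model <- sim_model(p = 10, r = 3, n = 24, noise = 0.15)
  tab <- run_random_design(model, c("CVLasso", "TrLasso"), M = 16,
                           control = method_control(L = 30L, K = 5L), seed = 99)
  mat <- attr(tab, "mspe")
  ratios <- mat[, "CVLasso"] / mat[, "TrLasso"]
  sd_full <- sd(ratios) / sqrt(16)
  sd_quarter <- sd(ratios[1:4]) / sqrt(4)
  # quarter-sample SD of the mean is about twice the full-sample one
  expect_gt(sd_quarter / sd_full, 0.8)
  expect_lt(sd_quarter / sd_full, 5)
})

test_that("fixed-design resplits are reproducible and handle simulated responses", {
  X <- make_synthetic_gene_design(n = 40, p = 25, seed = 5)
  tab <- run_fixed_design(X, methods = c("CVLasso", "TrLasso"), resplits = 4,
                          control = method_control(L = 30L, K = 5L),
                          seed = 31, response_sim = list(r = 5))
  tab2 <- run_fixed_design(X, methods = c("CVLasso", "TrLasso"), resplits = 4,
                           control = method_control(L = 30L, K = 5L),
                           seed = 31, response_sim = list(r = 5))
  expect_equal(tab$eff, tab2$eff)
  # single deterministic resplit with a fixed y
  y <- generate_fixed_design_response(X, r = 5, seed = 8)$y
  t1 <- run_fixed_design(X, y, methods = c("CVLasso", "TrLasso"), resplits = 1,
                         control = method_control(L = 30L, K = 5L), seed = 13)
  t2 <- run_fixed_design(X, y, methods = c("CVLasso", "TrLasso"), resplits = 1,
                         control = method_control(L = 30L, K = 5L), seed = 13)
  expect_equal(t1$eff, t2$eff)
})

test_that("a null model (r = 0) gives efficiencies near one", {
  # with no signal no method can beat predicting the mean by more than
  # noise, so every efficiency is ~1
  model <- sim_model(p = 12, r = 0, n = 30, noise = 1)
  tab <- run_random_design(model, c("CVLasso", "TrLasso"), M = 12,
                           control = method_control(L = 30L, K = 5L), seed = 41)
  row <- tab[tab$method == "TrLasso", ]
  expect_lt(abs(row$eff - 1), max(0.1, 3 * row$sd))
})

test_that("efficiency tables print and export in the cell format", {
  model <- sim_model(p = 10, r = 2, n = 24, noise = 0.15)
  tab <- run_random_design(model, c("CVLasso", "TrLasso"), M = 3,
                           control = method_control(L = 20L, K = 5L), seed = 3)
  out <- capture.output(print(tab))
  expect_true(any(grepl("TrLasso\\s+\\d\\.\\d{3}\\(\\d\\.\\d{3}\\)", out)))
  fcsv <- tempfile(fileext = ".csv"); ftxt <- tempfile(fileext = ".txt")
  write_eff_table(tab, fcsv, ftxt)
  expect_equal(read.csv(fcsv)$method, c("CVLasso", "TrLasso"))
  expect_true(any(grepl("\\(", readLines(ftxt))))
})
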