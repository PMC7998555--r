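test_that("lasso on an orthonormal design equals soft-thresholding at every path point", {
  n <- 60; p <- 5
  X <- orthonormal_design(n, p, seed = 11)
  beta <- c(3, -2, 1, 0.5, 0)
  y <- withr::with_seed(2, as.numeric(X %*% beta + rnorm(n, 0, 0.3)))
  fit <- fit_path(X, y, "lasso", L = 50L)
  z <- as.numeric(crossprod(X, y - mean(y))) / n   # per-coordinate OLS on std scale
  sc <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  for (l in seq_along(fit$intercepts)) {
    expect_equal(fit$betas[, l], soft(z, fit$path$values[l]) / sc,
                 tolerance = 1e-6)
  }
})

test_that("single-covariate fits use the exact univariate solution", {
  withr::with_seed(4, {
    x <- matrix(rnorm(30, 2, 3))
    y <- as.numeric(1.5 * x + rnorm(30, 0, 0.4))
  })
  fit <- fit_path(x, y, "lasso", L = 20L)
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  z <- sum(((x - m) / s) * (y - mean(y))) / 30
  expect_equal(fit$betas[1, ], as.numeric(soft(z, fit$path$values) / s),
               tolerance = 1e-10)
  # predictions reproduce OLS at the unpenalized end of a long path
  fit2 <- fit_path(x, y, "lasso", path = make_lambda_path(1e-8, 2L))
  ols <- lm(y ~ x)
  expect_equal(fit2$betas[1, 2], unname(coef(ols)[2]), tolerance = 1e-4)
})

test_that("duplicated columns share the load under the elastic net (grouping effect)", {
  # The exact minimizer for two identical columns is symmetric. The
  # difference direction is nearly flat at small lambda (curvature ~
  # lambda * (1 - alpha)), so the solver pins it down only to its own
  # tolerance: assert symmetry relative to the coefficient magnitude,
  # and that the load is genuinely split (pure lasso would instead give
  # the pair an arbitrary one-sided split).
  alpha <- 0.5
  withr::with_seed(9, {
    x <- rnorm(50)
    X <- cbind(x, x)
    y <- as.numeric(2 * x + rnorm(50, 0, 0.2))
  })
  fit <- fit_path(X, y, penalty_spec("elnet", alpha = alpha), L = 30L)
  b1 <- fit$betas[1, ]; b2 <- fit$betas[2, ]
  expect_lt(max(abs(b1 - b2) / pmax(1, abs(b1 + b2))), 0.05)
  mid <- 15L
  expect_gt(min(abs(c(b1[mid], b2[mid]))), 0.3 * abs(b1[mid] + b2[mid]))
})

test_that("elnet with alpha = 1 is the lasso code path", {
  dat <- toy_regression(seed = 21)
  f1 <- fit_path(dat$X, dat$y, "lasso", L = 25L)
  f2 <- fit_path(dat$X, dat$y, penalty_spec("elnet", alpha = 1), L = 25L)
  expect_equal(f1$betas, f2$betas, tolerance = 1e-10)
  expect_equal(f1$intercepts, f2$intercepts, tolerance = 1e-10)
})

test_that("support counts are consistent and grow from empty at lambda_max", {
  dat <- toy_regression(n = 30, p = 40, r = 4, seed = 13)  # p > n
  fit <- fit_path(dat$X, dat$y, "lasso")
  expect_identical(fit$support_counts,
                   colSums(abs(fit$betas) > 1e-12))
  expect_identical(unname(fit$support_counts[1]), 0)
  expect_gte(fit$support_counts[length(fit$intercepts)], fit$support_counts[1])
})

test_that("path fits reject non-finite input and handle p = 0", {
  expect_error(fit_path(matrix(c(1, Inf), 2, 1), c(1, 2)), "finite")
  f <- fit_path(matrix(numeric(0), 5, 0), rnorm(5) + 3)
  expect_equal(nrow(f$betas), 0L)
  expect_equal(unique(f$intercepts), mean(f$intercepts))
})

test_that("coefficient paths export to CSV", {
  dat <- toy_regression(seed = 1, n = 20, p = 4)
  fit <- fit_path(dat$X, dat$y, "lasso", L = 5L)
  f <- tempfile(fileext = ".csv")
  write_coef_path_csv(fit, f)
  tab <- read.csv(f, row.names = 1)
  expect_equal(dim(tab), c(5L, 5L))
  expect_equal(unname(as.numeric(tab[1, ])), fit$intercepts)
})
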