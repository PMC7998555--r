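test_that("random covariance draws are symmetric, repaired and in range", {
  S1 <- draw_covariance(1, seed = 1)
  expect_equal(dim(S1), c(1L, 1L))
  expect_true(S1[1, 1] >= 0.8 && S1[1, 1] <= 1.2)

  for (s in 1:5) {
    S <- draw_covariance(300, seed = s)
    expect_equal(S, t(S), tolerance = 1e-12)
    ev <- attr(S, "eig")$values
    expect_gte(min(ev), 1e-6 - 1e-12)
    # strongly correlated law at this size is indefinite before repair
    expect_lt(attr(S, "min_eigenvalue_raw"), 0)
    # repair perturbs the diagonal by a bounded amount
    expect_lt(max(abs(diag(S) - pmin(pmax(diag(S), 0.8), 1.2))), 0.25)
  }
  # the weak-correlation law must keep its diagonal close to the drawn
  # range: the repair perturbation stays small relative to the 0.2 span
  S <- draw_covariance(200, cov_range = c(0, 0.2), seed = 7)
  expect_lt(max(abs(diag(S) - pmin(pmax(diag(S), 0.8), 1.2))), 0.1)
  expect_true(all(diag(S) > 0.7 & diag(S) < 1.3))
  cr <- attr(S, "corr_range")
  expect_true(cr[1] >= -0.05 && cr[2] <= 0.3)
})

test_that("generated coefficients form one contiguous block of r nonzeros", {
  model <- sim_model(p = 40, r = 7, n = 20)
  for (s in 1:10) {
    dat <- generate(model, seed = s)
    nz <- which(dat$beta != 0)
    expect_length(nz, 7L)
    expect_identical(nz, nz[1]:(nz[1] + 6L))
    expect_true(all(abs(dat$beta[nz]) <= 2))
  }
  expect_equal(sum(generate(sim_model(p = 10, r = 0, n = 15), seed = 1)$beta != 0), 0L)
  expect_equal(sum(generate(sim_model(p = 10, r = 10, n = 15), seed = 1)$beta != 0), 10L)
})

test_that("datasets are bit-identical for identical seeds", {
  model <- sim_model(p = 25, r = 5, n = 30)
  d1 <- generate(model, seed = 123)
  d2 <- generate(model, seed = 123)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$beta, d2$beta)
  d3 <- generate(model, seed = 124)
  expect_false(identical(d1$y, d3$y))
})

test_that("the sample covariance of generated rows converges to the repaired covariance", {
  model <- sim_model(p = 20, r = 0, n = 10)
  dat <- generate(model, n_rows = 8000, seed = 55)
  emp <- cov(dat$X) * (7999 / 8000)
  # Monte-Carlo SE of a covariance entry is ~ sqrt((s_ii s_jj + s_ij^2)/n)
  mx <- max(abs(emp - dat$Sigma))
  se_bound <- 3 * sqrt(2 * max(diag(dat$Sigma))^2 / 8000)
  expect_lt(mx, se_bound + 0.02)
})

test_that("a null model's response variance matches the noise variance", {
  model <- sim_model(p = 15, r = 0, n = 400, noise = 0.15)
  dat <- generate(model, seed = 9)
  expect_lt(abs(var(dat$y) - 0.15) / 0.15, 0.3)
  expect_equal(dat$noise_sd, sqrt(0.15))
  # the sd reading takes the spread literally
  msd <- sim_model(p = 15, r = 0, n = 400, noise = 0.15,
                   gaussian_second_arg = "sd")
  expect_equal(generate(msd, seed = 9)$noise_sd, 0.15)
})

test_that("strong-correlation designs show the documented wide positive correlation band", {
  model <- sim_preset("strong_corr", p = 150, r = 30, n = 50)
  dat <- generate(model, seed = 13)
  cr <- attr(dat$Sigma, "corr_range")
  expect_gt(cr[1], 0.2)
  expect_lt(cr[2], 1.0)
})

test_that("fixed-design responses and the synthetic gene design are reproducible", {
  X <- make_synthetic_gene_design()
  expect_equal(dim(X), c(120L, 200L))
  expect_lt(max(abs(colMeans(X))), 1e-8)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-8)
  expect_identical(X, make_synthetic_gene_design())
  expect_false(identical(X, make_synthetic_gene_design(seed = 2)))

  r1 <- generate_fixed_design_response(X, r = 100, seed = 3)
  r2 <- generate_fixed_design_response(X, r = 100, seed = 3)
  expect_identical(r1$y, r2$y)
  expect_length(which(r1$beta != 0), 100L)
  expect_equal(generate_fixed_design_response(X, r = 0, seed = 4)$beta,
               rep(0, 200))
  # noiseless-predictor spread on the standardized design, for
  # calibrating the noise variance choice
  sd_pred <- sd(X %*% r1$beta)
  expect_gt(sd_pred, 0)
})
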