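test_that("trimmed averaging drops the right tails", {
  # a path whose 100 predictions at x0 = 0 are the intercepts 1..100
  pf <- elsar:::new_coef_path(matrix(0, 1, 100), 1:100,
                              penalty_spec("lasso"), NULL)
  expect_equal(predict_trimmed(pf, 0, 0.10), mean(11:90))  # 50.5
  expect_equal(predict_trimmed(pf, 0, 0), mean(1:100))
  pc <- elsar:::new_coef_path(matrix(0, 1, 7), rep(3.2, 7),
                              penalty_spec("lasso"), NULL)
  expect_equal(predict_trimmed(pc, 0, 0.10), 3.2)
  expect_error(elsar:::trimmed_row_means(matrix(1, 1, 2), 0.5), "no predictions")
  # trim 0 with a single path point is the single-point predictor
  p1 <- elsar:::new_coef_path(matrix(2, 1, 1), 1, penalty_spec("lasso"), NULL)
  expect_equal(predict_trimmed(p1, 3, 0), 7)
})

test_that("the ensemble variance law has its closed-form values", {
  expect_equal(ensemble_variance(1, 2, 50), 2)        # perfectly correlated
  expect_equal(ensemble_variance(0, 1, 4), 0.25)      # iid mean of 4
  expect_equal(ensemble_variance(0.2, 2, 1e9), 0.4, tolerance = 1e-6)
  expect_error(ensemble_variance(0.2, 2, 0), "B")
})

test_that("ensemble predictions average members and respect their bounds", {
  dat <- toy_regression(n = 30, p = 10, r = 2, seed = 81)
  scheme <- subspace_scheme(3L, 10L, 30L)
  model <- fit_ensemble(dat$X, dat$y, scheme, "lasso",
                        prediction_rule("trimmed"), B = 12L, L = 20L, seed = 3)
  X0 <- dat$X[1:5, ]
  pred <- predict(model, X0, members_matrix = TRUE)
  members <- attr(pred, "members")
  expect_equal(as.numeric(pred), rowMeans(members))
  expect_true(all(pred >= apply(members, 1, min) - 1e-12))
  expect_true(all(pred <= apply(members, 1, max) + 1e-12))
  # invariant to member order
  perm <- model
  perm$members <- rev(perm$members)
  expect_equal(predict(perm, X0), as.numeric(pred))
  expect_error(predict(model, X0[, 1:3]), "full")
})

test_that("a full-coverage subspace scheme makes trimmed members identical", {
  # approach 2 with n >= p: every member uses all covariates, so the
  # trimmed ensemble is deterministic and equals the single-path predictor
  dat <- toy_regression(n = 30, p = 8, r = 2, seed = 83)
  scheme <- subspace_scheme(2L, 8L, 30L)
  model <- fit_ensemble(dat$X, dat$y, scheme, "lasso",
                        prediction_rule("trimmed"), B = 5L, L = 25L, seed = 4)
  single <- fit_path(dat$X, dat$y, "lasso", L = 25L)
  x0 <- dat$X[1:3, ]
  expect_equal(predict(model, x0),
               as.numeric(predict_trimmed(single, x0, 0.10)), tolerance = 1e-10)
})

test_that("the empirical ensemble variance follows the correlation law", {
  # fixed small dataset; refit the ensemble with varying subspace seeds
  # and compare the variance of the ensemble prediction at one test
  # point with rho*sigma2 + (1 - rho)*sigma2/B using plug-in member
  # moments
  dat <- toy_regression(n = 30, p = 40, r = 4, noise_sd = 1, seed = 85)
  scheme <- subspace_scheme(3L, 40L, 30L)   # members see 15 of 40 covariates
  x0 <- withr::with_seed(86, matrix(rnorm(40), 1, 40))
  B <- 8L
  refits <- 200L
  ens <- numeric(refits)
  member_preds <- matrix(NA_real_, refits, B)
  for (i in seq_len(refits)) {
    m <- fit_ensemble(dat$X, dat$y, scheme, "lasso",
                      prediction_rule("trimmed"), B = B, L = 20L, seed = 9000 + i)
    pr <- predict(m, x0, members_matrix = TRUE)
    ens[i] <- pr
    member_preds[i, ] <- attr(pr, "members")
  }
  sigma2 <- var(as.numeric(member_preds))
  cors <- cor(member_preds)
  rho <- mean(cors[upper.tri(cors)])
  predicted <- ensemble_variance(rho, sigma2, B)
  expect_lt(abs(var(ens) - predicted) / predicted, 0.35)
})

test_that("ensembles round-trip through JSON", {
  dat <- toy_regression(n = 25, p = 6, r = 2, seed = 87)
  scheme <- subspace_scheme(3L, 6L, 25L)
  for (rule in list(prediction_rule("trimmed"), prediction_rule("cv", K = 5L))) {
    model <- fit_ensemble(dat$X, dat$y, scheme, "lasso", rule, B = 4L,
                          L = 15L, seed = 11)
    f <- tempfile(fileext = ".json")
    write_ensemble_json(model, f)
    back <- read_ensemble_json(f)
    expect_equal(predict(back, dat$X), predict(model, dat$X), tolerance = 1e-12)
  }
})
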