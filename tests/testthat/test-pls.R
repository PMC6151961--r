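test_that("PLS at full rank reproduces ordinary least squares", {
  set.seed(31)
  n <- 25; p <- 6
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
  Y <- cbind(logkw = X %*% rnorm(p) + rnorm(n, sd = 0.3),
             logKi = X %*% rnorm(p) + rnorm(n, sd = 0.3))
  m <- fit_pls(X, Y, A = p)
  pred <- predict(m, X)$predictions
  ols <- cbind(fitted(lm(Y[, 1] ~ X)), fitted(lm(Y[, 2] ~ X)))
  expect_lt(max(abs(pred - ols)), 1e-8)
  # exact linear Y at A = p: zero training error
  Yex <- cbind(logkw = drop(X %*% rnorm(p)), logKi = drop(X %*% rnorm(p)))
  mex <- fit_pls(X, Yex, A = p)
  expect_lt(max(abs(predict(mex, X)$predictions - Yex)), 1e-8)
})

test_that("scores are orthogonal and training RSS is monotone in A", {
  fx <- fitted_fixture(n = 30, p = 8, latent = 3, noise = 0.3, A = 6)
  G <- crossprod(fx$model$training_scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  rss <- vapply(1:6, function(a) {
    m <- fit_pls(fx$X, fx$Y, A = a)
    sum((predict(m, fx$X)$predictions - fx$Y)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("low-rank X is captured by as many components", {
  fx <- fitted_fixture(n = 30, p = 10, latent = 3, noise = 0, A = 3)
  expect_gte(fx$model$r2x, 0.999)
})

test_that("prediction identities hold", {
  fx <- fitted_fixture()
  m <- fx$model
  # the training-mean row predicts the training Y mean
  pr <- predict(m, matrix(colMeans(fx$X), 1))$predictions
  expect_equal(unname(drop(pr)), unname(colMeans(fx$Y)), tolerance = 1e-10)
  # deterministic: identical inputs give bit-identical outputs
  expect_identical(predict(m, fx$X), predict(m, fx$X))
  expect_error(predict(m, fx$X[, 1:3]), "columns")
})

test_that("predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(4)
  n <- 30; p <- 12
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
  Y <- cbind(logkw = X %*% rnorm(p) + rnorm(n, sd = 0.4),
             logKi = X %*% rnorm(p) + rnorm(n, sd = 0.4))
  Xnew <- matrix(rnorm(5 * p), 5, p, dimnames = list(NULL, colnames(X)))
  for (A in c(2, 4)) {
    ours <- predict(fit_pls(X, Y, A), Xnew)$predictions
    ref <- mixOmics::pls(X, Y, ncomp = A, mode = "regression",
                         scale = TRUE)
    theirs <- predict(ref, Xnew)$predict[, , A]
    expect_lt(max(abs(ours - theirs)), 1e-6)
  }
})

test_that("cross-validation picks the planted latent dimension", {
  ds <- generate_synthetic(synthetic_spec(
    n_compounds = 40, n_descriptors = 12, latent_dim = 3,
    n_informative = 12, n_binary = 0, noise_sd_x = 0,
    noise_sd_y = 0, seed = 13))
  X <- ds$desc$values; Y <- property_matrix(ds$props)
  cv <- cross_validate(X, Y, A_max = 6, k = 7, seed = 2)
  expect_identical(cv$A_chosen, 3L)
  # same seed, same folds, same choice
  cv2 <- cross_validate(X, Y, A_max = 6, k = 7, seed = 2)
  expect_identical(cv$cv_table, cv2$cv_table)
  # k = n reduces to leave-one-out and still runs
  loo <- cross_validate(X[1:12, ], Y[1:12, ], A_max = 3, k = 12, seed = 1)
  expect_identical(nrow(loo$cv_table), 3L)
  # a fold whose training remainder has fewer than 2 samples is rejected
  expect_error(cross_validate(X[1:2, ], Y[1:2, ], A_max = 2, k = 2), "fold")
})

test_that("metrics implement the RMSE and MRE definitions", {
  fx <- fitted_fixture()
  met0 <- pls_metrics(fx$model, fx$X, fx$Y)
  # hand-checkable case: obsd (1,2), pred (2,4)
  # RMSE = sqrt((1 + 4)/2); MRE = mean(1/1, 2/2) * 100 = 100%
  obsd <- cbind(a = c(1, 2))
  pred <- cbind(a = c(2, 4))
  expect_equal(sqrt(mean((pred - obsd)^2)), sqrt(2.5))
  expect_equal(unname(plsinvert:::mre_pct(pred, obsd)), 100)
  # pred == obsd gives all-zero metrics
  expect_equal(unname(plsinvert:::mre_pct(obsd, obsd)), 0)
  expect_true(all(met0$rmsee >= 0) && met0$r2x <= 1 && met0$r2y <= 1)
  # observed zero is excluded with a warning
  expect_warning(plsinvert:::mre_pct(cbind(c(1, 2)), cbind(c(0, 2))),
                 "excluded")
})

test_that("model JSON round-trip preserves predictions exactly", {
  fx <- fitted_fixture()
  f <- withr::local_tempfile(fileext = ".json")
  write_pls_model(fx$model, f)
  back <- read_pls_model(f)
  expect_equal(predict(back, fx$X)$predictions,
               predict(fx$model, fx$X)$predictions, tolerance = 1e-12)
  expect_identical(back$A, fx$model$A)
})
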