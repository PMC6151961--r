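# fixture: model + problem on clean 2-latent data (2 responses pin the
# scores, and the residual bound pins the descriptor plane)
inversion_fixture <- function(seed = 51, n = 40, p = 8, noise = 0.05,
                              n_binary = 0, ga = NULL) {
  ds <- generate_synthetic(synthetic_spec(
    n_compounds = n, n_descriptors = p, latent_dim = 2,
    n_informative = p, n_binary = n_binary,
    noise_sd_x = noise, noise_sd_y = noise, seed = seed))
  X <- ds$desc$values
  Y <- property_matrix(ds$props); rownames(Y) <- ds$props$compound_ids
  model <- fit_pls(X, Y, A = 2)
  list(ds = ds, X = X, Y = Y, model = model,
       kinds = unname(ds$desc$kinds))
}

test_that("problem constants derive from the critical limits", {
  fx <- inversion_fixture()
  prob <- build_inversion_problem(fx$model,
                                  reference_properties(0, 0), fx$X,
                                  kinds = fx$kinds)
  expect_equal(prob$c1, t2_critical(2, 40, 0.05))
  s0_sq <- fx$model$ssx_residual / ((40 - 2 - 1) * (8 - 2))
  expect_equal(prob$c2,
               s0_sq * (8 - 2) * dmodx_critical(fx$model, 0.05)^2)
  # quantile monotonicity: alpha -> 1 drives c1 toward 0
  probs <- vapply(c(0.05, 0.5, 0.99), function(a)
    build_inversion_problem(fx$model, reference_properties(0, 0), fx$X,
                            kinds = fx$kinds, alpha = a)$c1, numeric(1))
  expect_true(all(diff(probs) < 0))
  expect_lt(probs[3], 0.5)
  expect_equal(unname(prob$bounds$lower), unname(apply(fx$X, 2, min)))
})

test_that("c2 bounds the residual exactly at the DModX limit", {
  # conversion consistency: a row whose DModX sits at the critical value
  # has squared residual equal to c2
  fx <- inversion_fixture()
  prob <- build_inversion_problem(fx$model, reference_properties(0, 0),
                                  fx$X, kinds = fx$kinds)
  dxc <- dmodx_critical(fx$model, 0.05)
  # scale a residual direction until DModX == dxc, then measure ||e||^2
  x0 <- fx$X[1, ]
  m <- fx$model
  e <- plsinvert:::residual_matrix(m, matrix(x0, 1))
  stopifnot(sum(e^2) > 0)
  s0 <- sqrt(m$ssx_residual / ((m$n_train - m$A - 1) * (m$p - m$A)))
  # residual vectors live in the orthogonal complement of the loading
  # space, so scaling the residual part scales DModX linearly
  lambda <- dxc / dmodx(m, matrix(x0, 1))
  xs <- plsinvert:::apply_scaling(matrix(x0, 1), m$x_scaling)
  tn <- xs %*% m$Rstar
  recon <- tcrossprod(tn, m$P)
  xs_crit <- recon + lambda * (xs - recon)
  expect_equal(drop(dmodx(m, xs_crit, scaled = TRUE)), dxc,
               tolerance = 1e-8)
  expect_equal(sum((xs_crit - recon)^2), prob$c2, tolerance = 1e-6)
})

test_that("objective is the squared property deviation", {
  fx <- inversion_fixture()
  x0 <- fx$X[3, ]
  pr <- predict(fx$model, x0)$predictions
  prob0 <- build_inversion_problem(fx$model,
                                   reference_properties(pr[1], pr[2]),
                                   fx$X, kinds = fx$kinds)
  expect_equal(inversion_objective(x0, prob0), 0, tolerance = 1e-18)
  prob1 <- build_inversion_problem(fx$model,
                                   reference_properties(pr[1] + 1, pr[2]),
                                   fx$X, kinds = fx$kinds)
  expect_equal(inversion_objective(x0, prob1), 1, tolerance = 1e-10)
  expect_error(inversion_objective(fx$X[1, ] * 100, prob0), "bounds")
})

test_that("finite differences match the analytic linear-model gradient", {
  fx <- inversion_fixture()
  m <- fx$model
  prob <- build_inversion_problem(m, reference_properties(0.5, -0.5),
                                  fx$X, kinds = fx$kinds)
  x0 <- colMeans(fx$X)
  # dyhat/dx = diag(y_scale) C Rstar' diag(1/x_scale), objective gradient
  # = 2 J' (yhat - ref)
  J <- diag(m$y_scaling$scale) %*% m$C %*% t(m$Rstar) %*%
    diag(1 / m$x_scaling$scale)
  yhat <- drop(predict(m, x0)$predictions)
  grad_analytic <- drop(2 * t(J) %*% (yhat - c(0.5, -0.5)))
  eps <- 1e-6
  grad_fd <- vapply(seq_along(x0), function(i) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    (inversion_objective(xp, prob, check = FALSE) -
       inversion_objective(xm, prob, check = FALSE)) / (2 * eps)
  }, numeric(1))
  expect_equal(grad_fd, grad_analytic, tolerance = 1e-4)
})

test_that("a reference at an in-domain prediction is recovered feasibly", {
  fx <- inversion_fixture()
  rep_ <- diagnose(fx$model, fx$X, fx$Y)
  idx <- which(rep_$in_domain)[1]
  pr <- predict(fx$model, fx$X[idx, ])$predictions
  for (seed in c(1, 2, 3)) {
    prob <- build_inversion_problem(
      fx$model, reference_properties(pr[1], pr[2]), fx$X,
      kinds = fx$kinds,
      ga = inversion_ga_config(population_size = 40, generations = 30,
                               seed = seed))
    sol <- invert_model(prob)
    expect_true(sol$feasible)
    expect_lte(sol$objective, 1e-4)
    # internal consistency and constraint slacks
    expect_equal(unname(sol$predicted),
                 unname(drop(predict(fx$model, sol$x_star)$predictions)),
                 tolerance = 1e-12)
    expect_lte(sol$t2_value, prob$c1)
    expect_lte(sol$recon_residual, prob$c2)
    expect_true(all(sol$x_star >= prob$bounds$lower - 1e-9) &&
                  all(sol$x_star <= prob$bounds$upper + 1e-9))
  }
})

test_that("mixed-integer genes stay on their lattices", {
  fx <- inversion_fixture(seed = 52, n_binary = 2)
  ref <- make_reference(fx$ds, 4)
  prob <- build_inversion_problem(
    fx$model, ref$reference, fx$X, kinds = fx$kinds,
    ga = inversion_ga_config(population_size = 40, generations = 25,
                             seed = 9))
  sol <- invert_model(prob)
  bin <- fx$kinds == "binary"
  expect_true(all(sol$x_star[bin] %in% c(0, 1)))
  expect_true(sol$feasible)
})

test_that("relaxing the constraints drives the objective to zero", {
  fx <- inversion_fixture()
  # an achievable reference: the prediction of a mid-domain blend
  pr <- predict(fx$model, colMeans(fx$X))$predictions
  prob <- build_inversion_problem(fx$model,
                                  reference_properties(pr[1] + 0.1,
                                                       pr[2] - 0.1),
                                  fx$X, kinds = fx$kinds,
                                  ga = inversion_ga_config(
                                    population_size = 40,
                                    generations = 30, seed = 3))
  prob$c1 <- 1e9; prob$c2 <- 1e9
  sol <- invert_model(prob)
  expect_lt(sol$objective, 1e-6)
})
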