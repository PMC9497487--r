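test_that("residuals vanish on noiseless data and reduce to y, x", {
  th <- scenario_truth(1, rho = 0.5)
  z <- seq(-2, 2, length.out = 50)
  x <- predict_stage1(th, z)
  y <- predict_stage2(th, x)
  r <- pliv_residuals(th, pliv_data(y, x, z))
  expect_equal(r$u, rep(0, 50))
  expect_equal(r$v, rep(0, 50))

  th0 <- pliv_theta(alpha = c(0, 0), beta = c(0, 0))
  d <- make_linear_iv(n = 20)
  r0 <- pliv_residuals(th0, d)
  expect_equal(r0$u, d$y)
  expect_equal(r0$v, d$x)

  # single observation against the stage predictors directly
  th1 <- scenario_truth(1, rho = 0.5)
  r1 <- pliv_residuals(th1, pliv_data(y = 2.8, x = 2, z = 1))
  expect_equal(r1$u, 2.8 - predict_stage2(th1, 2))
  expect_equal(r1$v, 2 - predict_stage1(th1, 1)) # = 2 - 0.25
  expect_equal(r1$v, 1.75)
})

test_that("log-likelihood includes the bivariate normal constant", {
  th <- pliv_theta(alpha = c(0, 0), beta = c(0, 0), rho = 0,
                   sigma_u = 1, sigma_v = 1)
  # u = y, v = x at zero coefficients
  expect_equal(pliv_loglik(th, pliv_data(0, 0, 0)), -log(2 * pi))
  expect_equal(pliv_loglik(th, pliv_data(1, 0, 0)), -log(2 * pi) - 0.5)
})

test_that("log-likelihood equals a direct bivariate normal density", {
  set.seed(42)
  d <- make_linear_iv(n = 60, seed = 5)
  for (rep in 1:5) {
    th <- random_theta(d, K = 1, J = 1)
    r <- pliv_residuals(th, d)
    # independent oracle: generic multivariate normal density via the
    # covariance matrix, not the expanded quadratic form
    Sig <- matrix(c(th$sigma_u^2,
                    th$rho * th$sigma_u * th$sigma_v,
                    th$rho * th$sigma_u * th$sigma_v,
                    th$sigma_v^2), 2, 2)
    Sinv <- solve(Sig)
    w <- cbind(r$u, r$v)
    ll <- -log(2 * pi) - 0.5 * log(det(Sig)) -
      0.5 * rowSums((w %*% Sinv) * w)
    expect_equal(pliv_loglik(th, d), mean(ll), tolerance = 1e-12)
  }
})

test_that("likelihood separates into two Gaussian pieces when rho = 0", {
  d <- make_linear_iv(n = 40, seed = 8)
  th <- pliv_theta(alpha = c(0.4, 1.1), beta = c(-0.2, 0.9),
                   rho = 0, sigma_u = 0.7, sigma_v = 1.3)
  r <- pliv_residuals(th, d)
  expect_equal(pliv_loglik(th, d),
               mean(dnorm(r$u, 0, th$sigma_u, log = TRUE)) +
                 mean(dnorm(r$v, 0, th$sigma_v, log = TRUE)))
})

test_that("likelihood diverges to -Inf as |rho| approaches 1", {
  d <- make_linear_iv(n = 40, seed = 9)
  base <- pliv_loglik(pliv_theta(alpha = c(0, 1), beta = c(0, 1),
                                 rho = 0, sigma_u = 1, sigma_v = 1), d)
  for (r in c(1 - 1e-8, -(1 - 1e-8))) {
    near <- pliv_loglik(pliv_theta(alpha = c(0, 1), beta = c(0, 1),
                                   rho = r, sigma_u = 1, sigma_v = 1), d)
    expect_lt(near, base - 1e3)
  }
  expect_error(pliv_loglik(pliv_theta(alpha = c(0, 1), beta = c(0, 1),
                                      rho = 1), d), "rho")
})

test_that("analytic score matches finite differences of the likelihood", {
  sim <- generate_scenario(1, n = 200, rho = 0.5, seed = 31)
  set.seed(77)
  for (rep in 1:8) {
    th <- random_theta(sim$data, K = 1, J = 1)
    g_analytic <- colMeans(pliv_score(th, sim$data))
    g_numeric <- numeric_gradient(th, sim$data)
    expect_equal(g_analytic, g_numeric, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("threshold score columns vanish when the hinge coefficient is 0", {
  d <- make_linear_iv(n = 50, seed = 3)
  th <- pliv_theta(alpha = c(0.2, 0, 1), beta = c(0, 0.5), c = 0.1,
                   rho = 0.3, sigma_u = 1, sigma_v = 1)
  S <- pliv_score(th, d)
  expect_equal(unname(S[, "c1"]), rep(0, 50))
})

test_that("score columns average to ~0 at a converged maximizer", {
  sim <- generate_scenario(1, n = 500, rho = 0.5, seed = 101)
  fit <- suppressWarnings(fit_liml(sim$data, 1, 1))
  expect_true(fit$converged)
  S <- pliv_score(fit$theta, sim$data)
  smooth <- !grepl("^[ct][0-9]+$", colnames(S))
  expect_lt(max(abs(colMeans(S)[smooth])), 1e-3)
})
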