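test_that("2SLS initialization is exact on noiseless linear data", {
  z <- seq(-2, 2, length.out = 40)
  x <- 3 * z
  y <- 2 * x
  init <- tsls_init(pliv_data(y, x, z), K = 0, J = 0)
  expect_equal(init$alpha, c(0, 3), tolerance = 1e-10)
  expect_equal(init$beta, c(0, 2), tolerance = 1e-10)
})

test_that("initial threshold placement is evenly spaced in quantile space", {
  set.seed(4)
  z <- rnorm(400)
  d <- pliv_data(rnorm(400), rnorm(400) + z, z)
  init1 <- tsls_init(d, K = 1, J = 0)
  expect_equal(init1$c, unname(quantile(z, 0.5))) # midpoint of 5%-95%
  init2 <- tsls_init(d, K = 2, J = 0)
  expect_equal(init2$c, unname(quantile(z, c(0.35, 0.65))))
})

test_that("2SLS recovers coefficients at low noise with true thresholds", {
  sim <- generate_scenario(1, n = 2000, rho = 0.2, sigma = 0.01, seed = 11)
  init <- tsls_init(sim$data, K = 1, J = 1, c_init = 0.5, t_init = 0)
  expect_lt(max(abs(init$alpha - c(-1, 0.5, 1))), 0.05)
  expect_lt(max(abs(init$beta - c(-0.2, 1, 0.5))), 0.05)
})

test_that("grid-search initialization finds thresholds near the truth", {
  sim <- generate_scenario(1, n = 800, rho = 0.5, sigma = 0.1, seed = 21)
  init <- tsls_init(sim$data, K = 1, J = 1, method = "grid")
  expect_lt(abs(init$c - 0.5), 0.3)
  expect_lt(abs(init$t - 0.0), 0.3)
  expect_error(tsls_init(sim$data, K = 2, J = 2, method = "grid"),
               "grid")
})

test_that("identifiability requires at least as many instrument kinks", {
  d <- make_linear_iv(100)
  expect_error(tsls_init(d, K = 0, J = 1), "identifiability")
  expect_error(fit_liml(d, K = 0, J = 1), "identifiability")
})

test_that("LIML with no thresholds matches the closed-form 2SLS estimate", {
  d <- make_linear_iv(n = 2000, seed = 13)
  fit <- fit_liml(d, K = 0, J = 0)
  b_iv <- tsls_closed_form(d)
  expect_lt(max(abs(fit$theta$beta - b_iv)), 1e-4)
})

test_that("LIML recovers scenario-1 truth from a large sample", {
  sim <- generate_scenario(1, n = 5000, rho = 0.5, seed = 55)
  fit <- suppressWarnings(fit_liml(sim$data, 1, 1, common_sigma = TRUE))
  expect_true(fit$converged)
  est <- theta_to_vector(fit$theta, common_sigma = TRUE)
  truth <- theta_to_vector(sim$truth, common_sigma = TRUE)
  # tolerance: ~3 empirical SEs at n = 5000 (reference SEs at n = 500,
  # scaled by sqrt(500/5000)), generous for the slow threshold c
  tol <- c(alpha0 = 0.045, alpha1 = 0.10, alpha2 = 0.045,
           beta0 = 0.055, beta1 = 0.075, beta2 = 0.035,
           c1 = 0.25, t1 = 0.10, rho = 0.04, sigma = 0.02)
  expect_true(all(abs(est - truth)[names(tol)] < tol))
})

test_that("every fit ascends from its initializer", {
  for (s in 1:5) {
    sim <- generate_scenario(1, n = 300, rho = 0.2, seed = 600 + s)
    fit <- suppressWarnings(fit_liml(sim$data, 1, 1))
    expect_gte(fit$loglik, fit$loglik_init - 1e-8)
  }
})

test_that("estimates are equivariant under shifting the instrument", {
  sim <- generate_scenario(1, n = 1500, rho = 0.5, seed = 77)
  delta <- 2.5
  d2 <- pliv_data(sim$data$y, sim$data$x, sim$data$z + delta)
  f1 <- suppressWarnings(fit_liml(sim$data, 1, 1))
  f2 <- suppressWarnings(fit_liml(d2, 1, 1))
  aK1 <- f1$theta$alpha[3]
  expect_equal(f2$theta$c, f1$theta$c + delta, tolerance = 1e-2)
  expect_equal(f2$theta$alpha[1], f1$theta$alpha[1] - aK1 * delta,
               tolerance = 1e-2)
  expect_equal(f2$theta$beta, f1$theta$beta, tolerance = 1e-2)
})

test_that("information criteria match their definitions", {
  d <- make_linear_iv(n = 400, seed = 17)
  fit <- fit_liml(d, 0, 0)
  p <- theta_length(0, 0)
  expect_equal(pliv_bic(fit), -2 * fit$loglik_total + p * log(400))
  expect_equal(pliv_aic(fit), -2 * fit$loglik_total + 2 * p)
})

test_that("BIC selects no thresholds on linear data, (1,1) on kinked data", {
  pick_linear <- vapply(1:12, function(s) {
    d <- make_linear_iv(n = 400, seed = 3000 + s)
    sel <- suppressWarnings(
      select_thresholds(d, Kmax = 1, Jmax = 1, criterion = "BIC",
                        options = fit_options()))
    sel$K == 0 && sel$J == 0
  }, logical(1))
  expect_gt(mean(pick_linear), 0.5)

  pick_kinked <- vapply(1:12, function(s) {
    sim <- generate_scenario(1, n = 500, rho = 0.5, seed = 4000 + s)
    sel <- suppressWarnings(
      select_thresholds(sim$data, Kmax = 1, Jmax = 1, criterion = "BIC",
                        options = fit_options()))
    sel$K == 1 && sel$J == 1
  }, logical(1))
  expect_gt(mean(pick_kinked), 0.5)
})
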