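test_that("hinge function evaluates with a strict kink and is continuous", {
  expect_identical(relu_threshold(2.5, 2), 0.5)
  expect_identical(relu_threshold(1, 2), 0)
  expect_identical(relu_threshold(2, 2), 0) # strict inequality at the kink
  # continuity across the kink from both sides
  eps <- 1e-10
  expect_lt(abs(relu_threshold(2 + eps, 2)), 1e-9)
  expect_lt(abs(relu_threshold(2 - eps, 2)), 1e-9)
  expect_true(all(relu_threshold(rnorm(100), 0.3) >= 0))
})

test_that("stage design matrix has intercept, hinge columns, linear term", {
  expect_equal(unname(build_stage_design(c(0, 1, 3), 2)),
               rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 3)))
  expect_equal(unname(build_stage_design(5, numeric(0))),
               rbind(c(1, 5)))
  expect_equal(unname(build_stage_design(c(-1, 0, 4), c(0, 2))),
               rbind(c(1, 0, 0, -1), c(1, 0, 0, 0), c(1, 4, 2, 4)))
  expect_error(build_stage_design(1:3, c(2, 1)), "strictly increasing")
})

test_that("piecewise slope matches the worked segment slopes", {
  # y = phi(x, 2) + 3 phi(x, 3) + 2 x
  beta <- c(0, 1, 3, 2)
  t <- c(2, 3)
  expect_identical(piecewise_slope(beta, t, 2.5), 3)
  expect_identical(piecewise_slope(beta, t, 3.5), 6)
  expect_identical(piecewise_slope(beta, t, 1.0), 2) # base slope
  expect_error(piecewise_slope(beta, t, 3), "kink")
})

test_that("stage predictors evaluate the structural means", {
  th <- scenario_truth(1, rho = 0.5)
  expect_equal(predict_stage1(th, 1), -1 + 0.5 * 0.5 + 1)
  expect_equal(predict_stage1(th, 0), -1)
  th2 <- pliv_theta(alpha = c(0, 1), beta = c(-0.2, 1, 0.5), t = 0)
  expect_equal(predict_stage2(th2, 2), -0.2 + 2 + 1)
})

test_that("numerical derivative of the stage-2 mean equals piecewise_slope", {
  th <- scenario_truth(2)
  h <- 1e-7
  for (x0 in c(-2.3, -0.4, 1.1, 2.6)) {
    num <- (predict_stage2(th, x0 + h) - predict_stage2(th, x0 - h)) / (2 * h)
    expect_equal(num, piecewise_slope(th$beta, th$t, x0), tolerance = 1e-5)
  }
})

test_that("with no thresholds both stages are affine (linear IV model)", {
  th <- pliv_theta(alpha = c(1, 2), beta = c(-1, 3))
  z <- c(-2, 0, 1, 5)
  expect_equal(predict_stage1(th, z), 1 + 2 * z)
  expect_equal(predict_stage2(th, z), -1 + 3 * z)
})

test_that("stage-1 mean is equivariant under shifting the instrument", {
  th <- scenario_truth(1)
  delta <- 1.7
  z <- seq(-3, 3, length.out = 41)
  aK1 <- th$alpha[th$K + 2L]
  shifted <- pliv_theta(alpha = c(th$alpha[1] - aK1 * delta,
                                  th$alpha[-1]),
                        beta = th$beta, c = th$c + delta, t = th$t,
                        rho = th$rho, sigma_u = th$sigma_u,
                        sigma_v = th$sigma_v)
  expect_equal(predict_stage1(shifted, z + delta), predict_stage1(th, z))
})

test_that("theta and dataset containers validate their invariants", {
  expect_error(pliv_theta(alpha = c(1, 2), beta = c(1, 2), c = 0.5),
               "length")
  expect_error(pliv_theta(alpha = c(1, 2, 3, 4), beta = c(1, 2),
                          c = c(1, 0.5)), "increasing")
  expect_error(pliv_theta(alpha = c(1, 2), beta = c(1, 2), rho = 1),
               "rho")
  expect_error(pliv_theta(alpha = c(1, 2), beta = c(1, 2), sigma_u = 0),
               "sigma_u")
  expect_error(pliv_data(1:3, 1:3, 1:2), "length")
  expect_error(pliv_data(c(1, NA), 1:2, 1:2), "missing")
  expect_equal(theta_length(1, 1), 11)
  expect_equal(theta_length(0, 0), 7)
  expect_equal(theta_length(2, 2, common_sigma = TRUE), 14)
  vec <- theta_to_vector(scenario_truth(2, rho = 0.2))
  back <- vector_to_theta(vec, 2, 2)
  expect_equal(theta_to_vector(back), vec)
})
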