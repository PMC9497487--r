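# Fixtures are generated in code; the scenario generators are part of the
# package surface and double as test fixtures.

# simple linear IV data (no kinks): x = a0 + a1 z + v, y = b0 + b1 x + u
make_linear_iv <- function(n = 500, a = c(0.5, 1.2), b = c(-0.3, 0.8),
                           rho = 0.4, sigma = 0.5, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  e1 <- rnorm(n)
  e2 <- rnorm(n)
  v <- sigma * e1
  u <- sigma * (rho * e1 + sqrt(1 - rho^2) * e2)
  x <- a[1] + a[2] * z + v
  y <- b[1] + b[2] * x + u
  pliv_data(y, x, z)
}

# closed-form two-stage least squares for the linear (K = J = 0) model
tsls_closed_form <- function(data) {
  xhat <- fitted(lm(data$x ~ data$z))
  unname(coef(lm(data$y ~ xhat)))
}

# a random valid theta for a (K, J) model whose thresholds stay strictly
# inside the data range and at least `gap` away from every data point
# (keeps finite-difference oracles away from hinge kinks)
random_theta <- function(data, K, J, gap = 1e-4) {
  pick_thresholds <- function(v, m) {
    if (m == 0L) return(numeric(0))
    q <- quantile(v, c(0.1, 0.9), names = FALSE)
    repeat {
      cand <- sort(runif(m, q[1], q[2]))
      ok <- all(vapply(cand, function(p) min(abs(v - p)) > gap, logical(1)))
      if (ok && (m < 2 || min(diff(cand)) > 10 * gap)) return(cand)
    }
  }
  pliv_theta(alpha = rnorm(K + 2L, 0, 0.8),
             beta = rnorm(J + 2L, 0, 0.8),
             c = pick_thresholds(data$z, K),
             t = pick_thresholds(data$x, J),
             rho = runif(1, -0.8, 0.8),
             sigma_u = runif(1, 0.2, 1.5),
             sigma_v = runif(1, 0.2, 1.5))
}

# central finite differences of the mean log-likelihood in the canonical
# raw parameter vector (the independent oracle for the analytic score)
numeric_gradient <- function(theta, data, h = 1e-6) {
  vec <- theta_to_vector(theta)
  K <- theta$K
  J <- theta$J
  vapply(seq_along(vec), function(m) {
    up <- vec; up[m] <- up[m] + h
    dn <- vec; dn[m] <- dn[m] - h
    (pliv_loglik(vector_to_theta(up, K, J), data) -
       pliv_loglik(vector_to_theta(dn, K, J), data)) / (2 * h)
  }, numeric(1))
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
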