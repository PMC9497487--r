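# ---- internal, non-validating computations on a plain parameter list ----
# pl: list(alpha, beta, cc, tt, rho, su, sv)

.pl_from_theta <- function(theta) {
  list(alpha = theta$alpha, beta = theta$beta, cc = theta$c, tt = theta$t,
       rho = theta$rho, su = theta$sigma_u, sv = theta$sigma_v)
}

.residuals_raw <- function(pl, data) {
  D1 <- .stage_design(data$z, pl$cc)
  D2 <- .stage_design(data$x, pl$tt)
  list(u = data$y - drop(D2 %*% pl$beta),
       v = data$x - drop(D1 %*% pl$alpha),
       D1 = D1, D2 = D2)
}

.loglik_terms <- function(u, v, rho, su, sv) {
  a <- 1 / (1 - rho^2)
  Q <- u^2 / su^2 - 2 * rho * u * v / (su * sv) + v^2 / sv^2
  -log(2 * pi) - log(su * sv) - 0.5 * log1p(-rho^2) - 0.5 * a * Q
}

.loglik_raw <- function(pl, data) {
  if (!is.finite(pl$rho) || abs(pl$rho) >= 1 || pl$su <= 0 || pl$sv <= 0) {
    return(-Inf)
  }
  r <- .residuals_raw(pl, data)
  mean(.loglik_terms(r$u, r$v, pl$rho, pl$su, pl$sv))
}

# per-observation score matrix, canonical column order; optionally with the
# indicator sets frozen (used for the smooth part of the Hessian)
.score_raw <- function(pl, data, common_sigma = FALSE,
                       frozen = NULL) {
  K <- length(pl$cc)
  J <- length(pl$tt)
  n <- data$n
  rho <- pl$rho
  su <- pl$su
  sv <- pl$sv
  if (is.null(frozen)) {
    Iz <- if (K) vapply(pl$cc, function(ck) as.numeric(data$z > ck),
                        numeric(n)) else NULL
    Ix <- if (J) vapply(pl$tt, function(tj) as.numeric(data$x > tj),
                        numeric(n)) else NULL
  } else {
    Iz <- frozen$Iz
    Ix <- frozen$Ix
  }
  D1 <- matrix(1, n, K + 2L)
  if (K) for (k in seq_len(K)) D1[, k + 1L] <- (data$z - pl$cc[k]) * Iz[, k]
  D1[, K + 2L] <- data$z
  D2 <- matrix(1, n, J + 2L)
  if (J) for (j in seq_len(J)) D2[, j + 1L] <- (data$x - pl$tt[j]) * Ix[, j]
  D2[, J + 2L] <- data$x
  u <- data$y - drop(D2 %*% pl$beta)
  v <- data$x - drop(D1 %*% pl$alpha)

  a <- 1 / (1 - rho^2)
  dl_du <- -a * (u / su^2 - rho * v / (su * sv))
  dl_dv <- -a * (v / sv^2 - rho * u / (su * sv))

  S_alpha <- -dl_dv * D1
  S_beta <- -dl_du * D2
  S_c <- if (K) {
    m <- matrix(0, n, K)
    for (k in seq_len(K)) m[, k] <- pl$alpha[k + 1L] * Iz[, k] * dl_dv
    m
  } else NULL
  S_t <- if (J) {
    m <- matrix(0, n, J)
    for (j in seq_len(J)) m[, j] <- pl$beta[j + 1L] * Ix[, j] * dl_du
    m
  } else NULL

  Q <- u^2 / su^2 - 2 * rho * u * v / (su * sv) + v^2 / sv^2
  S_rho <- rho * a - rho * a^2 * Q + a * u * v / (su * sv)
  S_su <- -1 / su + a * u^2 / su^3 - a * rho * u * v / (su^2 * sv)
  S_sv <- -1 / sv + a * v^2 / sv^3 - a * rho * u * v / (sv^2 * su)

  S <- cbind(S_alpha, S_beta, S_c, S_t, S_rho,
             if (common_sigma) S_su + S_sv else cbind(S_su, S_sv))
  colnames(S) <- theta_names(K, J, common_sigma)
  S
}

# ---- exported, validating wrappers ----

#' Structural residuals of the two stages
#'
#' Computes the stage-1 residual \eqn{v_i = x_i - \alpha_0 - \sum_k \alpha_k
#' \varphi(z_i, c_k) - \alpha_{K+1} z_i} and the stage-2 residual
#' \eqn{u_i = y_i - \beta_0 - \sum_j \beta_j \varphi(x_i, t_j) -
#' \beta_{J+1} x_i}. The stage-2 residual uses the observed `x`, not a
#' fitted value: the likelihood is limited-information, conditioning both
#' equations on the realized exposure.
#'
#' @param theta a [pliv_theta] object.
#' @param data a [pliv_data] object.
#' @return list with numeric vectors `u` and `v` of length `data$n`.
#' @export
pliv_residuals <- function(theta, data) {
  theta <- as_pliv_theta(theta)
  r <- .residuals_raw(.pl_from_theta(theta), data)
  list(u = r$u, v = r$v)
}

#' Limited-information log-likelihood
#'
#' Mean per-observation log density of the residual pair \eqn{(u_i, v_i)}
#' under a bivariate normal with standard deviations `sigma_u`, `sigma_v`
#' and correlation `rho`:
#' \deqn{\ell_n(\theta) = \frac1n \sum_i \Big[-\log 2\pi - \log \sigma_u
#'   \sigma_v - \tfrac12 \log(1 - \rho^2) - \tfrac{1}{2(1-\rho^2)}
#'   Q(u_i, v_i)\Big],}
#' with \eqn{Q(u, v) = u^2/\sigma_u^2 - 2\rho u v / (\sigma_u \sigma_v) +
#' v^2/\sigma_v^2}. The additive constant \eqn{-\log 2\pi} is included so
#' that absolute values are comparable across software and usable in
#' AIC/BIC. The total model log-likelihood is `n * pliv_loglik(...)`.
#'
#' @inheritParams pliv_residuals
#' @return scalar mean log-likelihood \eqn{\ell_n(\theta)}.
#' @export
pliv_loglik <- function(theta, data) {
  theta <- as_pliv_theta(theta)
  .loglik_raw(.pl_from_theta(theta), data)
}

#' Analytic per-observation score
#'
#' Gradient \eqn{\partial \ell_i / \partial \theta} of each observation's
#' log density, in the canonical parameter order `(alpha, beta, c, t, rho,
#' sigma_u, sigma_v)`. Threshold derivatives follow the chain rule through
#' the hinge: \eqn{\partial \varphi(z, c_k)/\partial c_k = -I(z > c_k)}, so
#' \eqn{\partial v_i / \partial c_k = +\alpha_k I(z_i > c_k)} (and
#' analogously for `t_j` with `beta_j`). At a data point exactly on a
#' threshold the indicator contributes 0, consistent with the strict
#' inequality of the hinge (a probability-zero event for continuous data).
#'
#' @inheritParams pliv_residuals
#' @param common_sigma logical; if `TRUE`, report a single `sigma` column
#'   equal to the sum of the `sigma_u` and `sigma_v` partials (requires
#'   `sigma_u == sigma_v` in `theta`).
#' @return an `n x p` matrix with named columns; column means vanish at a
#'   maximizer up to optimizer tolerance.
#' @export
pliv_score <- function(theta, data, common_sigma = FALSE) {
  theta <- as_pliv_theta(theta)
  if (common_sigma && theta$sigma_u != theta$sigma_v) {
    stop("common_sigma = TRUE requires sigma_u == sigma_v")
  }
  .score_raw(.pl_from_theta(theta), data, common_sigma)
}
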