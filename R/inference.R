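# pseudo-inverse fallback for near-singular information matrices
.safe_solve <- function(A, label = "matrix") {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (!is.null(out)) {
    kap <- tryCatch(kappa(A, exact = FALSE), error = function(e) Inf)
    if (is.finite(kap) && kap < 1e12) return(out)
  }
  warning(label, " is singular or ill-conditioned; ",
          "using Moore-Penrose pseudo-inverse")
  s <- svd(A)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Average outer product of per-observation scores
#'
#' \eqn{M = \frac1n \sum_i \dot\ell_i \dot\ell_i^\top}, the empirical
#' second moment of the score, estimating \eqn{E[\dot\ell \dot\ell^\top]}.
#' At the MLE this is the sample information used for model-based standard
#' errors and as the meat of the sandwich.
#'
#' @param scores an `n x p` score matrix (see [pliv_score]).
#' @return symmetric positive semidefinite `p x p` matrix.
#' @export
outer_product_M <- function(scores) {
  M <- crossprod(scores) / nrow(scores)
  (M + t(M)) / 2
}

#' Gaussian kernel density estimate at a point
#'
#' Rule-of-thumb (Silverman) bandwidth Gaussian KDE, used to replace the
#' indicator-derived second derivatives of the likelihood by density terms
#' when building the Hessian: the average derivative of an indicator
#' \eqn{I(z > c)} converges to the density of `z` at `c`.
#'
#' @param sample numeric vector, at least 10 points, nondegenerate.
#' @param point scalar evaluation point.
#' @param bw optional bandwidth override.
#' @return positive density estimate.
#' @export
kde_density <- function(sample, point, bw = NULL) {
  if (length(sample) < 10L) stop("need at least 10 sample points")
  if (sd(sample) == 0) stop("degenerate (zero-variance) sample")
  if (is.null(bw)) bw <- bw.nrd0(sample)
  mean(dnorm((point - sample) / bw)) / bw
}

#' Hessian-type matrix V of the mean log-likelihood
#'
#' Estimates the expected second derivative of the per-observation
#' log-likelihood at `theta`, the bread of the sandwich covariance. The
#' smooth part is obtained by central finite differences of the analytic
#' score with the hinge indicator sets frozen at `theta` (the almost-
#' everywhere derivative, including the coefficient-threshold couplings).
#' Differentiating the free-standing indicators in the threshold score
#' entries produces Dirac terms whose averages converge to density-weighted
#' limits; these are added on the threshold diagonal blocks via a Gaussian
#' kernel smoothing of the indicator derivative (bandwidth from
#' [kde_density]'s rule of thumb), so that the density of the instrument at
#' each `c_k` and of the exposure at each `t_j` enters exactly where the
#' asymptotic theory places it. With no thresholds (K = J = 0) the
#' correction vanishes and V is the ordinary numerical Hessian.
#'
#' @param theta a [pliv_theta] at (or near) the optimum.
#' @param data a [pliv_data] object.
#' @param common_sigma logical, as in the fit.
#' @param h_rel relative finite-difference step.
#' @return symmetric `p x p` matrix (negative definite near a maximum).
#' @export
hessian_V <- function(theta, data, common_sigma = FALSE, h_rel = 1e-5) {
  theta <- as_pliv_theta(theta)
  pl <- .pl_from_theta(theta)
  K <- theta$K
  J <- theta$J
  p <- theta_length(K, J, common_sigma)
  n <- data$n

  frozen <- list(
    Iz = if (K) vapply(pl$cc, function(ck) as.numeric(data$z > ck),
                       numeric(n)) else NULL,
    Ix = if (J) vapply(pl$tt, function(tj) as.numeric(data$x > tj),
                       numeric(n)) else NULL)

  vec0 <- theta_to_vector(theta, common_sigma)
  grad_at <- function(vec) {
    plv <- .par_to_pl_raw(vec, K, J, common_sigma)
    colMeans(.score_raw(plv, data, common_sigma, frozen = frozen))
  }

  V <- matrix(0, p, p)
  for (m in seq_len(p)) {
    h <- h_rel * max(1, abs(vec0[m]))
    up <- vec0; up[m] <- up[m] + h
    dn <- vec0; dn[m] <- dn[m] - h
    V[m, ] <- (grad_at(up) - grad_at(dn)) / (2 * h)
  }
  V <- (V + t(V)) / 2

  # density-limit (Dirac) terms on the threshold diagonals:
  # d/dc_k of the indicator inside the c_k score entry
  r <- .residuals_raw(pl, data)
  a <- 1 / (1 - pl$rho^2)
  dl_du <- -a * (r$u / pl$su^2 - pl$rho * r$v / (pl$su * pl$sv))
  dl_dv <- -a * (r$v / pl$sv^2 - pl$rho * r$u / (pl$su * pl$sv))
  if (K) {
    bw <- bw.nrd0(data$z)
    for (k in seq_len(K)) {
      kern <- dnorm((data$z - pl$cc[k]) / bw) / bw
      idx <- (K + 2L) + (J + 2L) + k
      V[idx, idx] <- V[idx, idx] - pl$alpha[k + 1L] * mean(dl_dv * kern)
    }
  }
  if (J) {
    bw <- bw.nrd0(data$x)
    for (j in seq_len(J)) {
      kern <- dnorm((data$x - pl$tt[j]) / bw) / bw
      idx <- (K + 2L) + (J + 2L) + K + j
      V[idx, idx] <- V[idx, idx] - pl$beta[j + 1L] * mean(dl_du * kern)
    }
  }
  dimnames(V) <- list(names(vec0), names(vec0))
  V
}

# raw-scale vector -> plain parameter list (no validation, no transform)
.par_to_pl_raw <- function(vec, K, J, common_sigma) {
  i <- 0L
  take <- function(m) {
    out <- unname(vec[i + seq_len(m)])
    i <<- i + m
    out
  }
  alpha <- take(K + 2L)
  beta <- take(J + 2L)
  cc <- take(K)
  tt <- take(J)
  rho <- take(1L)
  if (common_sigma) {
    su <- sv <- take(1L)
  } else {
    su <- take(1L)
    sv <- take(1L)
  }
  list(alpha = alpha, beta = beta, cc = cc, tt = tt, rho = rho,
       su = su, sv = sv)
}

#' Variance-covariance estimate for a fitted PLIV model
#'
#' Model-based mode (appropriate when the model is correctly specified)
#' uses the inverse of the score outer product: `cov = M^{-1} / n`.
#' Sandwich mode (robust to misspecification) uses
#' `cov = V^{-1} M V^{-1} / n` with the Hessian-type `V` of [hessian_V].
#' Under correct specification the two agree asymptotically
#' (`V = -M` in the limit).
#'
#' @param fit a `pliv_fit` from [fit_liml].
#' @param data the data used for the fit (defaults to the copy stored in
#'   the fit).
#' @param mode `"model_based"` (default) or `"sandwich"`.
#' @return an object of class `pliv_vcov` with elements `M`, `V` (sandwich
#'   mode only), `cov`, `se`, `mode` and the parameter names.
#' @export
pliv_vcov <- function(fit, data = fit$data,
                      mode = c("model_based", "sandwich")) {
  mode <- match.arg(mode)
  n <- data$n
  S <- pliv_score(fit$theta, data, common_sigma = fit$common_sigma)
  M <- outer_product_M(S)
  V <- NULL
  if (mode == "model_based") {
    cov <- .safe_solve(M, "score outer product M") / n
  } else {
    V <- hessian_V(fit$theta, data, common_sigma = fit$common_sigma)
    Vi <- .safe_solve(V, "Hessian V")
    cov <- Vi %*% M %*% t(Vi) / n
  }
  cov <- (cov + t(cov)) / 2
  d <- diag(cov)
  if (any(d < -1e-10)) {
    stop("covariance estimate has negative diagonal entries")
  }
  se <- sqrt(pmax(d, 0))
  nm <- colnames(S)
  dimnames(cov) <- list(nm, nm)
  names(se) <- nm
  structure(list(M = M, V = V, cov = cov, se = se, mode = mode,
                 n = n, parameters = nm),
            class = "pliv_vcov")
}

#' @export
vcov.pliv_fit <- function(object, mode = "model_based", ...) {
  pliv_vcov(object, mode = mode)$cov
}

#' @export
print.pliv_vcov <- function(x, digits = 4, ...) {
  cat(sprintf("PLIV %s covariance (n = %d)\n  SE: ",
              gsub("_", "-", x$mode), x$n))
  print(signif(x$se, digits))
  invisible(x)
}

#' Wald summary table for a fitted PLIV model
#'
#' One row per parameter with estimate, standard error, z-value, normal
#' confidence interval and two-sided p-value. P-values for the threshold
#' location parameters are reported as `NA`: testing a threshold location
#' against zero is not meaningful.
#'
#' @param fit a `pliv_fit`.
#' @param vc a `pliv_vcov` for the same fit (default: model-based).
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `parameter`, `estimate`, `se`, `z`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
summarize <- function(fit, vc = pliv_vcov(fit), level = 0.95) {
  est <- theta_to_vector(fit$theta, fit$common_sigma)
  stopifnot(identical(names(est), vc$parameters))
  se <- vc$se
  z <- est / se
  q <- qnorm((1 + level) / 2)
  p <- 2 * pnorm(-abs(z))
  p[grepl("^[ct][0-9]+$", names(est))] <- NA_real_
  data.frame(parameter = names(est), estimate = unname(est),
             se = unname(se), z = unname(z),
             ci_low = unname(est - q * se), ci_high = unname(est + q * se),
             p = unname(p), row.names = NULL)
}
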