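#' Continuous threshold (ReLU / hinge) function
#'
#' Computes \eqn{\varphi(x, t) = (x - t)\,I(x > t)}, the continuous threshold
#' function used to build piecewise linear mean functions. The indicator is
#' strict, so \code{relu_threshold(t, t) == 0} and the function is continuous
#' in both arguments.
#'
#' @param x numeric vector.
#' @param t numeric threshold (scalar or vector recycled against `x`).
#' @return numeric vector of \eqn{(x - t)_+}.
#' @examples
#' relu_threshold(2.5, 2) # 0.5
#' relu_threshold(c(1, 2, 3), 2) # 0 0 1
#' @export
relu_threshold <- function(x, t) {
  (x - t) * (x > t)
}

# internal design builder without the ordering check (used inside the
# optimizer, where threshold iterates may transiently cross)
.stage_design <- function(v, thresholds) {
  n <- length(v)
  m <- length(thresholds)
  out <- matrix(1, n, m + 2L)
  if (m > 0L) {
    for (k in seq_len(m)) out[, k + 1L] <- relu_threshold(v, thresholds[k])
  }
  out[, m + 2L] <- v
  out
}

#' Stage design matrix for a piecewise linear regression
#'
#' Materializes the regressors of one stage of the piecewise linear IV model:
#' an intercept column, one hinge column \eqn{\varphi(v, \tau_k)} per
#' threshold (in threshold order), and the linear term last. The column order
#' matches the coefficient order \eqn{(\alpha_0, \alpha_1, \ldots,
#' \alpha_{K+1})}.
#'
#' @param v numeric vector (the stage's running variable, `z` or `x`).
#' @param thresholds strictly increasing numeric vector (possibly empty).
#' @return an `length(v) x (length(thresholds) + 2)` numeric matrix.
#' @examples
#' build_stage_design(c(0, 1, 3), 2)
#' build_stage_design(5, numeric(0)) # classical linear design
#' @export
build_stage_design <- function(v, thresholds = numeric(0)) {
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  m <- length(thresholds)
  out <- .stage_design(v, thresholds)
  colnames(out) <- c("(Intercept)",
                     if (m > 0L) paste0("phi", seq_len(m)),
                     "linear")
  out
}

#' Local slope of a piecewise linear stage function
#'
#' For the stage-2 mean function \eqn{\beta_0 + \sum_j \beta_j \varphi(x,
#' t_j) + \beta_{J+1} x}, returns the derivative at `x0`: the base slope
#' \eqn{\beta_{J+1}} plus the sum of the hinge coefficients \eqn{\beta_j}
#' whose thresholds lie below `x0`. This is the subset causal effect of a
#' unit increase in `x` on the segment containing `x0`.
#'
#' @param beta coefficient vector `(beta0, beta1, ..., betaJ, betaJ+1)` of
#'   length `length(t) + 2`.
#' @param t strictly increasing thresholds (possibly empty).
#' @param x0 evaluation point(s); must not coincide with a threshold, where
#'   the slope is undefined.
#' @return numeric vector of local slopes, one per element of `x0`.
#' @examples
#' # y = phi(x, 2) + 3 phi(x, 3) + 2 x
#' piecewise_slope(c(0, 1, 3, 2), c(2, 3), 2.5) # 3
#' piecewise_slope(c(0, 1, 3, 2), c(2, 3), 3.5) # 6
#' @export
piecewise_slope <- function(beta, t = numeric(0), x0) {
  J <- length(t)
  if (length(beta) != J + 2L) {
    stop("beta must have length(t) + 2 elements")
  }
  if (J > 1L && any(diff(t) <= 0)) stop("thresholds must be strictly increasing")
  vapply(x0, function(p) {
    if (J > 0L && any(p == t)) {
      stop("slope is undefined exactly at a threshold (kink point)")
    }
    beta[J + 2L] + sum(beta[1L + which(t < p)])
  }, numeric(1))
}

#' Conditional mean predictors of the two stages
#'
#' `predict_stage1` evaluates the first-stage mean of X given Z,
#' \eqn{\alpha_0 + \sum_k \alpha_k \varphi(z, c_k) + \alpha_{K+1} z};
#' `predict_stage2` evaluates the second-stage mean of Y given X,
#' \eqn{\beta_0 + \sum_j \beta_j \varphi(x, t_j) + \beta_{J+1} x}.
#'
#' @param theta a [pliv_theta] parameter object.
#' @param z,x numeric vectors at which to evaluate the stage means.
#' @return numeric vector of conditional means.
#' @examples
#' th <- pliv_theta(alpha = c(-1, 0.5, 1), beta = c(-0.2, 1, 0.5),
#'                  c = 0.5, t = 0, rho = 0.5,
#'                  sigma_u = 0.3, sigma_v = 0.3)
#' predict_stage1(th, 1) # -1 + 0.5 * 0.5 + 1 = 0.25
#' predict_stage2(th, 2) # -0.2 + 2 + 1 = 2.8
#' @export
predict_stage1 <- function(theta, z) {
  theta <- as_pliv_theta(theta)
  drop(.stage_design(z, theta$c) %*% theta$alpha)
}

#' @rdname predict_stage1
#' @export
predict_stage2 <- function(theta, x) {
  theta <- as_pliv_theta(theta)
  drop(.stage_design(x, theta$t) %*% theta$beta)
}
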