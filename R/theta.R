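#' Parameter vector of the piecewise linear IV model
#'
#' Bundles the full parameter set \eqn{\theta = (\alpha, \beta, c, t, \rho,
#' \sigma_u, \sigma_v)}: first-stage coefficients `alpha` (length K+2,
#' intercept / hinge terms / linear term), second-stage coefficients `beta`
#' (length J+2), thresholds `c` in the instrument Z (length K, strictly
#' increasing) and `t` in the exposure X (length J, strictly increasing),
#' the error correlation `rho` in (-1, 1) and the error standard deviations
#' `sigma_u`, `sigma_v` (both positive). `K = J = 0` gives the classical
#' linear IV model.
#'
#' Thresholds are stored sorted ascending; the model is invariant to joint
#' permutations of (hinge coefficient, threshold) pairs, so the canonical
#' ordering removes label-switching ambiguity.
#'
#' @param alpha numeric vector of length `length(c) + 2`.
#' @param beta numeric vector of length `length(t) + 2`.
#' @param c,t strictly increasing numeric threshold vectors (may be empty).
#' @param rho error correlation, in (-1, 1).
#' @param sigma_u,sigma_v positive error standard deviations.
#' @return an object of class `pliv_theta`.
#' @export
pliv_theta <- function(alpha, beta, c = numeric(0), t = numeric(0),
                       rho = 0, sigma_u = 1, sigma_v = 1) {
  K <- length(c)
  J <- length(t)
  if (length(alpha) != K + 2L) stop("alpha must have length(c) + 2 elements")
  if (length(beta) != J + 2L) stop("beta must have length(t) + 2 elements")
  if (K > 1L && any(diff(c) <= 0)) stop("c must be strictly increasing")
  if (J > 1L && any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (!is.finite(rho) || abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  if (!is.finite(sigma_u) || sigma_u <= 0) stop("sigma_u must be positive")
  if (!is.finite(sigma_v) || sigma_v <= 0) stop("sigma_v must be positive")
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         c = as.numeric(c), t = as.numeric(t),
         rho = as.numeric(rho), sigma_u = as.numeric(sigma_u),
         sigma_v = as.numeric(sigma_v), K = K, J = J),
    class = "pliv_theta")
}

#' @rdname pliv_theta
#' @param x object to coerce / test.
#' @export
as_pliv_theta <- function(x) {
  if (inherits(x, "pliv_theta")) return(x)
  stop("expected a 'pliv_theta' object")
}

#' @export
print.pliv_theta <- function(x, digits = 4, ...) {
  cat(sprintf("Piecewise linear IV parameters (K = %d, J = %d)\n", x$K, x$J))
  cat("  alpha:", signif(x$alpha, digits), "\n")
  cat("  beta: ", signif(x$beta, digits), "\n")
  if (x$K) cat("  c:    ", signif(x$c, digits), "\n")
  if (x$J) cat("  t:    ", signif(x$t, digits), "\n")
  cat(sprintf("  rho = %s, sigma_u = %s, sigma_v = %s\n",
              signif(x$rho, digits), signif(x$sigma_u, digits),
              signif(x$sigma_v, digits)))
  invisible(x)
}

#' Number of free parameters of a (K, J) model
#'
#' `(K + 2) + (J + 2) + K + J + 3` for separate error standard deviations,
#' one fewer when `sigma_u = sigma_v` is imposed.
#'
#' @param K,J nonnegative threshold counts.
#' @param common_sigma logical; is a single common error SD estimated?
#' @return integer parameter count.
#' @export
theta_length <- function(K, J, common_sigma = FALSE) {
  (K + 2L) + (J + 2L) + K + J + 3L - as.integer(common_sigma)
}

#' @rdname theta_length
#' @export
theta_names <- function(K, J, common_sigma = FALSE) {
  c(paste0("alpha", 0:(K + 1L)),
    paste0("beta", 0:(J + 1L)),
    if (K > 0L) paste0("c", seq_len(K)),
    if (J > 0L) paste0("t", seq_len(J)),
    "rho",
    if (common_sigma) "sigma" else c("sigma_u", "sigma_v"))
}

#' Flatten / rebuild the canonical parameter vector
#'
#' The canonical ordering is `(alpha, beta, c, t, rho, sigma...)`, matching
#' the score and covariance matrix layouts.
#'
#' @param theta a [pliv_theta] object.
#' @param common_sigma logical; collapse `sigma_u`/`sigma_v` (must be equal)
#'   into a single `sigma` entry.
#' @return `theta_to_vector`: named numeric vector; `vector_to_theta`: a
#'   [pliv_theta].
#' @export
theta_to_vector <- function(theta, common_sigma = FALSE) {
  theta <- as_pliv_theta(theta)
  if (common_sigma && theta$sigma_u != theta$sigma_v) {
    stop("common_sigma = TRUE requires sigma_u == sigma_v")
  }
  out <- c(theta$alpha, theta$beta, theta$c, theta$t, theta$rho,
           if (common_sigma) theta$sigma_u else c(theta$sigma_u, theta$sigma_v))
  names(out) <- theta_names(theta$K, theta$J, common_sigma)
  out
}

#' @rdname theta_to_vector
#' @param vec numeric vector in canonical order.
#' @param K,J threshold counts encoded in `vec`.
#' @export
vector_to_theta <- function(vec, K, J, common_sigma = FALSE) {
  if (length(vec) != theta_length(K, J, common_sigma)) {
    stop("parameter vector has the wrong length for (K, J)")
  }
  i <- 0L
  take <- function(m) {
    out <- vec[i + seq_len(m)]
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
  pliv_theta(alpha, beta, cc, tt, rho, su, sv)
}

# sort thresholds ascending, permuting the paired hinge coefficients
.canonicalize_theta <- function(theta) {
  if (theta$K > 1L) {
    o <- order(theta$c)
    theta$c <- theta$c[o]
    theta$alpha[1L + seq_len(theta$K)] <- theta$alpha[1L + o]
  }
  if (theta$J > 1L) {
    o <- order(theta$t)
    theta$t <- theta$t[o]
    theta$beta[1L + seq_len(theta$J)] <- theta$beta[1L + o]
  }
  theta
}

#' Observed data for a piecewise linear IV analysis
#'
#' Aligned observation vectors for the outcome `y`, exposure `x` and
#' instrument `z`, with flags recording any log transforms already applied.
#' Missing values are not allowed here; ingestion (see [read_pliv_table])
#' drops incomplete rows and records the count.
#'
#' @param y,x,z numeric vectors of equal length without missing values.
#' @param log_y,log_x,log_z logicals recording applied log transforms.
#' @return an object of class `pliv_data`.
#' @export
pliv_data <- function(y, x, z, log_y = FALSE, log_x = FALSE, log_z = FALSE) {
  n <- length(y)
  if (length(x) != n || length(z) != n) {
    stop("y, x and z must have equal length")
  }
  if (anyNA(y) || anyNA(x) || anyNA(z) ||
      !all(is.finite(y)) || !all(is.finite(x)) || !all(is.finite(z))) {
    stop("y, x and z must be finite and free of missing values")
  }
  structure(
    list(y = as.numeric(y), x = as.numeric(x), z = as.numeric(z),
         n = n, log_y = log_y, log_x = log_x, log_z = log_z),
    class = "pliv_data")
}

#' @export
print.pliv_data <- function(x, ...) {
  tr <- c(if (x$log_y) "log(y)", if (x$log_x) "log(x)", if (x$log_z) "log(z)")
  cat(sprintf("PLIV dataset: %d observations%s\n", x$n,
              if (length(tr)) paste0(" [", paste(tr, collapse = ", "), "]")
              else ""))
  invisible(x)
}
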