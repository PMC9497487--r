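#' Fitting options for the LIML optimizer
#'
#' @param max_iter maximum optimizer iterations.
#' @param grad_tol gradient-norm threshold (on the mean log-likelihood
#'   scale, in the transformed parameter space) below which a fit is
#'   declared converged in addition to the optimizer's own stopping rule.
#'   The norm is taken over the coordinates in which the objective is
#'   smooth (coefficients, correlation, scales); at a maximum sitting on a
#'   data kink the threshold coordinates carry a subgradient rather than a
#'   zero gradient, so they are judged by the optimizer's own stopping
#'   criterion instead.
#' @param optimizer quasi-Newton method name passed to [stats::optim()].
#' @param seed integer seed for stochastic restarts (`NULL` = leave RNG
#'   state alone).
#' @param restarts number of additional randomly jittered starts.
#' @param threshold_bounds quantile pair bounding initial (and final)
#'   threshold placement.
#' @return list of class `pliv_options`.
#' @export
fit_options <- function(max_iter = 500L, grad_tol = 1e-3,
                        optimizer = "BFGS", seed = NULL, restarts = 0L,
                        threshold_bounds = c(0.05, 0.95)) {
  stopifnot(grad_tol > 0, max_iter >= 1, restarts >= 0,
            length(threshold_bounds) == 2,
            threshold_bounds[1] > 0, threshold_bounds[2] < 1,
            threshold_bounds[1] < threshold_bounds[2])
  structure(list(max_iter = as.integer(max_iter), grad_tol = grad_tol,
                 optimizer = optimizer, seed = seed,
                 restarts = as.integer(restarts),
                 threshold_bounds = threshold_bounds),
            class = "pliv_options")
}

# quantile levels for evenly spaced interior threshold placement:
# K points at b1 + i * (b2 - b1) / (K + 1), i = 1..K (K = 1 -> midpoint)
.threshold_probs <- function(K, bounds) {
  if (K == 0L) return(numeric(0))
  bounds[1] + seq_len(K) * diff(bounds) / (K + 1L)
}

.lm_coef <- function(X, y, what = "design") {
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    stop("initialization error: rank-deficient ", what,
         " (a threshold may lie outside the data range)")
  }
  fit
}

#' Two-stage least squares initialization
#'
#' Provides starting values for the LIML optimizer. Thresholds in the
#' instrument are placed evenly spaced (in quantile space) between the 5%
#' and 95% sample quantiles of `z`; stage 1 regresses `x` on the hinge
#' design of `z`, giving `alpha` and fitted values `xhat`; thresholds in the
#' exposure are placed analogously from the quantiles of `xhat`; stage 2
#' regresses `y` on the hinge design of `xhat`, giving `beta`. Points below
#' the 5% and above the 95% quantiles are avoided to limit boundary
#' effects. `rho`, `sigma_u`, `sigma_v` are initialized from the empirical
#' moments of the two stages' structural residuals.
#'
#' With `method = "grid"` (supported for K, J <= 1) the thresholds are
#' instead chosen by a coarse grid search over 19 quantile points per
#' threshold, minimizing the stage-2 residual sum of squares.
#'
#' @param data a [pliv_data] object.
#' @param K,J nonnegative threshold counts (K >= J).
#' @param method `"quantile"` (default) or `"grid"`.
#' @param bounds quantile pair delimiting threshold placement.
#' @param c_init,t_init optional fixed threshold vectors overriding the
#'   placement rule.
#' @return a [pliv_theta] start value, with attribute `first_stage_F`
#'   carrying the first-stage F-statistic (instrument-strength diagnostic).
#' @export
tsls_init <- function(data, K = 0L, J = 0L,
                      method = c("quantile", "grid"),
                      bounds = c(0.05, 0.95),
                      c_init = NULL, t_init = NULL) {
  method <- match.arg(method)
  if (J > K) stop("K >= J is required for identifiability")
  n <- data$n
  if (n < theta_length(K, J) + 2L) stop("too few observations for (K, J)")

  if (method == "grid" && (K > 1L || J > 1L)) {
    stop("grid initialization is supported for K, J <= 1 only")
  }
  grid_pts <- function(v) unname(quantile(v, seq(bounds[1], bounds[2],
                                                 length.out = 19)))

  one_pass <- function(cc, tt_fixed = NULL) {
    D1 <- .stage_design(data$z, cc)
    f1 <- .lm_coef(D1, data$x, "first-stage design")
    xhat <- drop(D1 %*% f1$coefficients)
    tt <- if (!is.null(tt_fixed)) tt_fixed else
      if (J > 0L) unname(quantile(xhat, .threshold_probs(J, bounds))) else
        numeric(0)
    D2 <- .stage_design(xhat, tt)
    f2 <- .lm_coef(D2, data$y, "second-stage design")
    list(cc = cc, tt = tt, alpha = unname(f1$coefficients),
         beta = unname(f2$coefficients), xhat = xhat,
         sse = sum(f2$residuals^2), f1 = f1)
  }

  if (method == "grid") {
    cand_c <- if (!is.null(c_init)) list(c_init) else
      if (K == 0L) list(numeric(0)) else as.list(grid_pts(data$z))
    best <- NULL
    for (cc in cand_c) {
      base <- one_pass(cc)
      cand_t <- if (!is.null(t_init)) list(t_init) else
        if (J == 0L) list(numeric(0)) else as.list(grid_pts(base$xhat))
      for (tt in cand_t) {
        res <- one_pass(cc, tt_fixed = tt)
        if (is.null(best) || res$sse < best$sse) best <- res
      }
    }
    pass <- best
  } else {
    cc <- if (!is.null(c_init)) sort(c_init) else
      if (K > 0L) unname(quantile(data$z, .threshold_probs(K, bounds))) else
        numeric(0)
    pass <- one_pass(cc, tt_fixed = if (!is.null(t_init)) sort(t_init))
  }

  # error moments: stage-1 residual v, structural stage-2 residual u
  # (observed x, not fitted)
  v <- data$x - drop(.stage_design(data$z, pass$cc) %*% pass$alpha)
  u <- data$y - drop(.stage_design(data$x, pass$tt) %*% pass$beta)
  su <- max(sd(u), 1e-8)
  sv <- max(sd(v), 1e-8)
  rho <- suppressWarnings(cor(u, v))
  if (!is.finite(rho)) rho <- 0
  rho <- max(min(rho, 0.99), -0.99)

  # first-stage F for the joint null on all non-intercept coefficients
  p1 <- K + 1L
  rss <- sum(v^2)
  tss <- sum((data$x - mean(data$x))^2)
  Fstat <- ((tss - rss) / p1) / (rss / (n - p1 - 1L))

  theta <- pliv_theta(pass$alpha, pass$beta, pass$cc, pass$tt, rho, su, sv)
  attr(theta, "first_stage_F") <- Fstat
  theta
}

# ---- transformed parameter space: rho = tanh(eta), sigma = exp(s) ----

.pl_to_par <- function(pl, common_sigma) {
  c(pl$alpha, pl$beta, pl$cc, pl$tt, atanh(pl$rho),
    if (common_sigma) log(sqrt(pl$su * pl$sv)) else c(log(pl$su), log(pl$sv)))
}

.par_to_pl <- function(par, K, J, common_sigma) {
  i <- 0L
  take <- function(m) {
    out <- par[i + seq_len(m)]
    i <<- i + m
    out
  }
  alpha <- take(K + 2L)
  beta <- take(J + 2L)
  cc <- take(K)
  tt <- take(J)
  rho <- tanh(take(1L))
  if (common_sigma) {
    su <- sv <- exp(take(1L))
  } else {
    su <- exp(take(1L))
    sv <- exp(take(1L))
  }
  list(alpha = unname(alpha), beta = unname(beta), cc = unname(cc),
       tt = unname(tt), rho = unname(rho), su = unname(su), sv = unname(sv))
}

# chain-rule jacobian diag for transformed gradient
.par_jacobian <- function(pl, K, J, common_sigma) {
  c(rep(1, (K + 2L) + (J + 2L) + K + J),
    1 - pl$rho^2,
    if (common_sigma) pl$su else c(pl$su, pl$sv))
}

#' Simultaneous LIML estimation of the piecewise linear IV model
#'
#' Maximizes the limited-information log-likelihood over all coefficients,
#' thresholds and error parameters jointly, by quasi-Newton ascent with the
#' analytic score, starting from the two-stage least squares initializer.
#' The correlation and standard deviations are optimized on a transformed
#' scale (`atanh`, `log`) so the open-interval and positivity constraints
#' need no boundary handling; thresholds are optimized on the raw scale,
#' where the objective is continuous and piecewise smooth. Thresholds are
#' re-sorted into canonical ascending order after optimization, and a
#' threshold that escapes the data's 5%-95% quantile range is projected
#' back with a warning.
#'
#' @param data a [pliv_data] object.
#' @param K,J nonnegative threshold counts; `K >= J` is required for
#'   identifiability (the hinge instruments must be at least as numerous as
#'   the hinge regressors they identify).
#' @param options a [fit_options] list.
#' @param common_sigma logical; impose `sigma_u = sigma_v` during
#'   estimation (a single common error SD).
#' @param init optional [pliv_theta] start (default: [tsls_init]).
#' @param init_method initializer passed to [tsls_init].
#' @return an object of class `pliv_fit`: the estimate `theta`, mean and
#'   total log-likelihood, convergence information, the initializer and the
#'   first-stage F-statistic. Never errors on non-convergence; the
#'   `converged` flag records it.
#' @export
fit_liml <- function(data, K = 0L, J = 0L, options = fit_options(),
                     common_sigma = FALSE, init = NULL,
                     init_method = "quantile") {
  if (J > K) stop("K >= J is required for identifiability")
  K <- as.integer(K)
  J <- as.integer(J)
  if (data$n < theta_length(K, J, common_sigma)) {
    stop("fewer observations than parameters")
  }

  if (is.null(init)) {
    init <- tsls_init(data, K, J, method = init_method,
                      bounds = options$threshold_bounds)
  }
  first_stage_F <- attr(init, "first_stage_F")
  if (is.null(first_stage_F)) first_stage_F <- NA_real_
  if (common_sigma && init$sigma_u != init$sigma_v) {
    s <- sqrt(init$sigma_u * init$sigma_v)
    init <- pliv_theta(init$alpha, init$beta, init$c, init$t, init$rho, s, s)
  }

  fn <- function(par) {
    pl <- .par_to_pl(par, K, J, common_sigma)
    ll <- .loglik_raw(pl, data)
    if (!is.finite(ll)) return(-1e10)
    ll
  }
  gr <- function(par) {
    pl <- .par_to_pl(par, K, J, common_sigma)
    g <- colMeans(.score_raw(pl, data, common_sigma))
    g <- g * .par_jacobian(pl, K, J, common_sigma)
    g[!is.finite(g)] <- 0
    g
  }

  run_optim <- function(par0) {
    optim(par0, fn, gr, method = options$optimizer,
          control = list(fnscale = -1, maxit = options$max_iter,
                         reltol = 1e-12))
  }

  par0 <- .pl_to_par(.pl_from_theta(init), common_sigma)
  opt <- run_optim(par0)
  # polish: a fresh quasi-Newton pass from the terminal point (the reset
  # Hessian approximation often finishes the smooth coordinates after the
  # first pass stalls on a threshold kink)
  opt2 <- tryCatch(run_optim(opt$par), error = function(e) NULL)
  if (!is.null(opt2) && opt2$value >= opt$value) opt <- opt2
  if (options$restarts > 0L) {
    if (!is.null(options$seed)) set.seed(options$seed)
    sc_z <- diff(range(data$z))
    sc_x <- diff(range(data$x))
    for (r in seq_len(options$restarts)) {
      parr <- par0
      idx_c <- (K + J + 4L) + seq_len(K)
      idx_t <- (K + J + 4L) + K + seq_len(J)
      parr[idx_c] <- parr[idx_c] + rnorm(K, 0, 0.1 * sc_z)
      parr[idx_t] <- parr[idx_t] + rnorm(J, 0, 0.1 * sc_x)
      optr <- tryCatch(run_optim(parr), error = function(e) NULL)
      if (!is.null(optr) && optr$value > opt$value) opt <- optr
    }
  }

  pl <- .par_to_pl(opt$par, K, J, common_sigma)

  # project escaped thresholds back into the quantile bounds
  clamp <- function(thr, v) {
    qb <- quantile(v, options$threshold_bounds, names = FALSE)
    if (length(thr) && (any(thr < qb[1]) || any(thr > qb[2]))) {
      warning("threshold estimate outside the ",
              paste(options$threshold_bounds * 100, collapse = "-"),
              "% quantile range of the data; projected back")
      thr <- pmin(pmax(thr, qb[1]), qb[2])
    }
    thr
  }
  pl$cc <- clamp(pl$cc, data$z)
  pl$tt <- clamp(pl$tt, data$x)

  # near-coincident thresholds are not identified
  near <- function(thr, v) length(thr) > 1L &&
    any(diff(sort(thr)) < 1e-6 * diff(range(v)))
  if (near(pl$cc, data$z) || near(pl$tt, data$x)) {
    warning("two threshold estimates are nearly coincident; ",
            "the model is not identified at this point")
  }

  theta <- .canonicalize_theta(
    pliv_theta(pl$alpha, pl$beta, sort(pl$cc), sort(pl$tt),
               pl$rho, pl$su, pl$sv))
  # re-pair hinge coefficients with sorted thresholds
  if (K > 1L) theta$alpha[1L + seq_len(K)] <- pl$alpha[1L + order(pl$cc)]
  if (J > 1L) theta$beta[1L + seq_len(J)] <- pl$beta[1L + order(pl$tt)]

  ll <- .loglik_raw(.pl_from_theta(theta), data)
  g_final <- colMeans(.score_raw(.pl_from_theta(theta), data, common_sigma)) *
    .par_jacobian(.pl_from_theta(theta), K, J, common_sigma)
  grad_norm <- sqrt(sum(g_final^2))
  # stationarity is only well defined in the coordinates where the
  # objective is smooth: at a maximum sitting on a data kink the threshold
  # coordinates carry a sign-changing subgradient, not a zero gradient
  smooth <- !grepl("^[ct][0-9]+$", names(g_final))
  grad_norm_smooth <- sqrt(sum(g_final[smooth]^2))

  structure(
    list(theta = theta, K = K, J = J, common_sigma = common_sigma,
         loglik = ll, loglik_total = data$n * ll, n = data$n,
         converged = (opt$convergence == 0L) &&
           grad_norm_smooth < options$grad_tol,
         n_iter = unname(opt$counts["function"]), grad_norm = grad_norm,
         grad_norm_smooth = grad_norm_smooth,
         init = init, loglik_init = pliv_loglik(init, data),
         first_stage_F = first_stage_F,
         data = data, options = options),
    class = "pliv_fit")
}

#' @export
print.pliv_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Piecewise linear IV model (LIML), K = %d, J = %d, n = %d\n",
    x$K, x$J, x$n))
  print(x$theta, digits = digits)
  cat(sprintf("log-likelihood = %.4f (mean %.6f), %sconverged, %d evaluations\n",
              x$loglik_total, x$loglik, if (x$converged) "" else "NOT ",
              x$n_iter))
  cat(sprintf("first-stage F = %.2f\n", x$first_stage_F))
  invisible(x)
}

#' Model AIC / BIC
#'
#' `AIC = -2 n ell_n + 2 p` and `BIC = -2 n ell_n + p log n`, with `p` the
#' free-parameter count of the (K, J) model.
#'
#' @param fit a `pliv_fit`.
#' @return scalar criterion value.
#' @export
pliv_aic <- function(fit) {
  -2 * fit$loglik_total + 2 * theta_length(fit$K, fit$J, fit$common_sigma)
}

#' @rdname pliv_aic
#' @export
pliv_bic <- function(fit) {
  -2 * fit$loglik_total +
    theta_length(fit$K, fit$J, fit$common_sigma) * log(fit$n)
}

#' Select the numbers of thresholds by information criterion
#'
#' Fits every admissible pair `(K, J)` with `0 <= J <= min(K, Jmax)` and
#' `K <= Kmax`, and returns the pair minimizing AIC or BIC. A member fit
#' that fails is marked missing and excluded from the selection.
#'
#' @param data a [pliv_data] object.
#' @param Kmax,Jmax maximal threshold counts (`Kmax >= Jmax >= 0`).
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param options a [fit_options] list.
#' @param common_sigma passed to [fit_liml].
#' @return list with elements `K`, `J` (the selected pair), `criterion`,
#'   and `table` (one row per candidate with log-likelihood, parameter
#'   count, AIC and BIC).
#' @export
select_thresholds <- function(data, Kmax = 2L, Jmax = Kmax,
                              criterion = c("BIC", "AIC"),
                              options = fit_options(),
                              common_sigma = FALSE) {
  criterion <- match.arg(criterion)
  if (Jmax > Kmax || Jmax < 0L) stop("need Kmax >= Jmax >= 0")
  rows <- list()
  for (K in 0:Kmax) {
    for (J in 0:min(K, Jmax)) {
      fit <- tryCatch(
        suppressWarnings(fit_liml(data, K, J, options = options,
                                  common_sigma = common_sigma)),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(fit)) {
        data.frame(K = K, J = J, loglik = NA_real_, npar = NA_integer_,
                   AIC = NA_real_, BIC = NA_real_, converged = FALSE)
      } else {
        data.frame(K = K, J = J, loglik = fit$loglik_total,
                   npar = theta_length(K, J, common_sigma),
                   AIC = pliv_aic(fit), BIC = pliv_bic(fit),
                   converged = fit$converged)
      }
    }
  }
  tab <- do.call(rbind, rows)
  crit <- tab[[criterion]]
  if (all(is.na(crit))) stop("all candidate fits failed")
  best <- which.min(crit)
  list(K = tab$K[best], J = tab$J[best], criterion = criterion, table = tab)
}
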