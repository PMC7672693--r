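# Two-stage baseline: independent per-time-point Bayesian variance-component
# fits, then GP smoothing of the logarithmized posterior means and 95%
# interval limits.  It exists to quantify how much uncertainty the joint
# model removes by borrowing strength across time; it is deliberately not
# competitive.

#' Stage one: per-time-point variance components
#'
#' For a single centred phenotype vector y(t), fits y(t) ~ N(0, s2G G + s2E I)
#' with independent N(0, 1) priors on log s2G and log s2E, by adaptive
#' random-walk Metropolis updating one log-variance at a time.  The
#' likelihood reuses the factorized form on one column, i.e. the T = 1
#' special case of the joint model.
#'
#' @param y_t centred (and globally scaled) phenotype vector at one time point.
#' @param G relationship matrix or cached [eigendecompose_grm()] result.
#' @param iterations MCMC iterations (burn-in: first half).
#' @param seed optional; if `NULL` the current RNG stream is used so a caller
#'   may seed once for many time points.
#' @return list with posterior means and 2.5/97.5% quantiles of log s2G and
#'   log s2E: fields `post_mean_logG`, `lower95_logG`, `upper95_logG` and the
#'   `*_logE` counterparts.
#' @export
stage1_fit <- function(y_t, G, iterations = 8000L, seed = NULL) {
  if (!inherits(G, "eigen_grm")) G <- eigendecompose_grm(G)
  if (!is.null(seed)) set.seed(seed)
  if (iterations < 20L) stop("too few iterations")
  z <- crossprod(G$U, as.numeric(y_t))
  xi <- G$xi
  ll <- function(lsG, lsE) joint_loglik(z, xi, exp(lsG), exp(lsE))

  lsG <- 0; lsE <- 0
  cur_ll <- ll(lsG, lsE)
  stG <- adaptive_rw_state(0.5)
  stE <- adaptive_rw_state(0.5)
  keep <- seq.int(iterations %/% 2L + 1L, iterations)
  dG <- dE <- numeric(iterations)
  for (i in seq_len(iterations)) {
    r <- adaptive_rw_step(lsG, function(v) ll(v, lsE) +
                            stats::dnorm(v, log = TRUE),
                          stG, cur_logpost = cur_ll +
                            stats::dnorm(lsG, log = TRUE))
    stG <- r$state
    if (r$accepted) { lsG <- r$theta; cur_ll <- r$logpost - stats::dnorm(lsG, log = TRUE) }
    r <- adaptive_rw_step(lsE, function(v) ll(lsG, v) +
                            stats::dnorm(v, log = TRUE),
                          stE, cur_logpost = cur_ll +
                            stats::dnorm(lsE, log = TRUE))
    stE <- r$state
    if (r$accepted) { lsE <- r$theta; cur_ll <- r$logpost - stats::dnorm(lsE, log = TRUE) }
    dG[i] <- lsG; dE[i] <- lsE
  }
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  qG <- qs(dG[keep]); qE <- qs(dE[keep])
  list(post_mean_logG = mean(dG[keep]), lower95_logG = qG[1], upper95_logG = qG[2],
       post_mean_logE = mean(dE[keep]), lower95_logE = qE[1], upper95_logE = qE[2])
}

# Gaussian marginal log-likelihood y ~ N(0, C_lambda + gamma2 I) via Cholesky.
.gp_marginal_ll <- function(y, times, lambda, gamma2) {
  C <- cov_matrix(times, matern_kernel(lambda))
  K <- C + diag(gamma2 + 1e-10, length(y))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(y * alpha))
}

#' Conjugate GP reconstruction at fixed hyperparameters
#'
#' f | y, lambda, gamma2 ~ N(C (C + gamma2 I)^{-1} y,
#' C - C (C + gamma2 I)^{-1} C).  As gamma2 -> 0 the mean interpolates y; as
#' gamma2 -> Inf it shrinks to the prior mean 0.
#'
#' @param y observed curve (already standardized by the caller).
#' @param times time grid.
#' @param lambda,gamma2 kernel length scale and error variance.
#' @return list with `f_mean` and `f_cov`.
#' @export
gp_smooth_reconstruct <- function(y, times, lambda, gamma2) {
  C <- cov_matrix(times, matern_kernel(lambda))
  A <- C + diag(gamma2 + 1e-10, length(y))
  W <- solve(A, C)              # A^{-1} C
  f_mean <- drop(crossprod(W, y))
  f_cov <- C - crossprod(W, C)
  list(f_mean = f_mean, f_cov = (f_cov + t(f_cov)) / 2)
}

#' Stage two: GP smoothing of a noisy curve
#'
#' Standardizes the curve to mean zero and unit variance, samples (log
#' gamma2, log lambda) under y ~ N(0, C_lambda + gamma2 I) with priors
#' log gamma2 ~ N(0, 100^2) and log lambda ~ N(mu_lambda, zeta_lambda^2)
#' (alternating adaptive random-walk Metropolis), then reconstructs the
#' smooth process at the grid with the conjugate formula at the posterior
#' means of (lambda, gamma2) and de-standardizes.
#'
#' @param y_curve noisy curve of length T (e.g. logarithmized stage-one
#'   posterior means).
#' @param times time grid.
#' @param iterations MCMC iterations (burn-in: first half).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list with `gamma2`, `lambda` (posterior means), `f_mean`, `f_cov`
#'   on the original scale of `y_curve`.
#' @export
stage2_smooth <- function(y_curve, times, iterations = 4000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y_curve <- as.numeric(y_curve)
  if (length(y_curve) != length(times)) stop("curve/grid length mismatch")
  m0 <- mean(y_curve)
  s0 <- stats::sd(y_curve)
  if (!is.finite(s0) || s0 <= 0)
    stop("constant curve: zero variance standardization")
  ys <- (y_curve - m0) / s0
  hyper <- lengthscale_hyperprior(times)

  lg2 <- 0; llam <- hyper$mu_lambda
  lp_g <- function(v) .gp_marginal_ll(ys, times, exp(llam), exp(v)) +
    stats::dnorm(v, 0, 100, log = TRUE)
  lp_l <- function(v) .gp_marginal_ll(ys, times, exp(v), exp(lg2)) +
    stats::dnorm(v, hyper$mu_lambda, hyper$zeta_lambda, log = TRUE)
  stg <- adaptive_rw_state(0.5)
  stl <- adaptive_rw_state(0.5)
  cur_g <- lp_g(lg2)
  dG2 <- dLam <- numeric(iterations)
  for (i in seq_len(iterations)) {
    r <- adaptive_rw_step(lg2, lp_g, stg, cur_logpost = cur_g)
    stg <- r$state; lg2 <- r$theta
    r <- adaptive_rw_step(llam, lp_l, stl)
    stl <- r$state; llam <- r$theta
    cur_g <- lp_g(lg2)
    dG2[i] <- exp(lg2); dLam[i] <- exp(llam)
  }
  keep <- seq.int(iterations %/% 2L + 1L, iterations)
  gamma2_hat <- mean(dG2[keep])
  lambda_hat <- mean(dLam[keep])
  rec <- gp_smooth_reconstruct(ys, times, lambda_hat, gamma2_hat)
  list(gamma2 = gamma2_hat, lambda = lambda_hat,
       f_mean = rec$f_mean * s0 + m0,
       f_cov = rec$f_cov * s0^2)
}

#' Two-stage estimation of dynamic variance components
#'
#' Stage one fits the variance components independently at every time point
#' on the globally centred-and-scaled data (same convention as the joint
#' model); stage two GP-smooths, on the log scale, the posterior-mean curve
#' and both 95% interval limit curves of each component, independently per
#' curve, and exponentiates back.  Heritability curves are derived from the
#' smoothed component curves with the conservative ratio convention
#' h2_lower = G_lo / (G_lo + E_up), h2_upper = G_up / (G_up + E_lo), clipped
#' to (0, 1).
#'
#' @param panel a [phenotype_panel()].
#' @param G relationship matrix in the panel's individual order.
#' @param iterations stage-one iterations per time point.
#' @param smooth_iterations stage-two iterations per curve.
#' @param seed integer seed for the whole procedure.
#' @param scale `"analysis"` or `"original"` scale for the variance summaries.
#' @return list of data.frames `sigma2_G`, `sigma2_E`, `h2` (columns time,
#'   mean, lower95, upper95) plus `scale_factor` and, for T > 1, the stage-two
#'   hyperparameter estimates in `smoothing`.
#' @export
run_two_stage <- function(panel, G, iterations = 8000L,
                          smooth_iterations = 4000L, seed,
                          scale = c("analysis", "original")) {
  scale <- match.arg(scale)
  G <- .validate_run_args(panel, G, iterations, 0L, 1L)
  if (missing(seed)) stop("seed is required")
  cs <- center_scale(panel)
  eig <- eigendecompose_grm(G)
  times <- panel$times
  T_ <- length(times)

  set.seed(seed)
  s1 <- vector("list", T_)
  for (t in seq_len(T_))
    s1[[t]] <- stage1_fit(cs$panel$values[, t], eig, iterations = iterations)
  pull <- function(f) vapply(s1, `[[`, numeric(1), f)

  curves <- list(mG = pull("post_mean_logG"),
                 loG = pull("lower95_logG"), upG = pull("upper95_logG"),
                 mE = pull("post_mean_logE"),
                 loE = pull("lower95_logE"), upE = pull("upper95_logE"))

  if (T_ == 1L) {
    sm <- lapply(curves, function(cv) list(f_mean = cv))
    smoothing <- NULL
  } else {
    sm <- lapply(curves, function(cv)
      stage2_smooth(cv, times, iterations = smooth_iterations))
    smoothing <- lapply(sm, function(s) c(lambda = s$lambda, gamma2 = s$gamma2))
  }
  ex <- lapply(sm, function(s) exp(s$f_mean))

  fac <- if (scale == "original") cs$scale_factor else 1
  mk <- function(m, lo, up, what) {
    cross <- m < lo | m > up
    if (any(cross))
      warning(sum(cross), " time point(s) where the smoothed ", what,
              " mean curve crosses its smoothed interval limits")
    data.frame(time = times, mean = m, lower95 = pmin(lo, m),
               upper95 = pmax(up, m), row.names = NULL)
  }
  sigma2_G <- mk(ex$mG * fac, ex$loG * fac, ex$upG * fac, "sigma2_G")
  sigma2_E <- mk(ex$mE * fac, ex$loE * fac, ex$upE * fac, "sigma2_E")
  eps <- 1e-12
  clip <- function(x) pmin(pmax(x, eps), 1 - eps)
  h2 <- data.frame(time = times,
                   mean = clip(ex$mG / (ex$mG + ex$mE)),
                   lower95 = clip(ex$loG / (ex$loG + ex$upE)),
                   upper95 = clip(ex$upG / (ex$upG + ex$loE)),
                   row.names = NULL)
  h2$lower95 <- pmin(h2$lower95, h2$mean)
  h2$upper95 <- pmax(h2$upper95, h2$mean)
  list(sigma2_G = sigma2_G, sigma2_E = sigma2_E, h2 = h2,
       scale_factor = cs$scale_factor, smoothing = smoothing)
}
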