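# Generic MCMC kernels.
#
# Elliptical slice sampling updates a vector with a standard-normal prior
# (the whitened GP coefficients) without rejections; adaptive Gaussian
# random-walk Metropolis updates scalars (log length scales, log variances),
# tuning its step size toward the 0.44 acceptance rate that is optimal for
# one-dimensional targets.  Both kernels draw from R's global RNG stream, so
# seeding once at the chain entry point makes whole runs bit-reproducible.

#' One elliptical slice sampling update
#'
#' Rejection-free transition for a posterior proportional to
#' N(eta; 0, I) * exp(loglik(eta)).  An auxiliary draw nu ~ N(0, I) defines
#' an ellipse through the current state; the angle bracket \[theta - 2pi,
#' theta\] is shrunk toward 0 until a point above the slice level is found,
#' which is guaranteed because the current state (angle 0) lies above it.
#'
#' @param eta current state vector.
#' @param loglik function(eta) returning the log-likelihood (prior excluded).
#' @param cur_loglik optional cached `loglik(eta)` to avoid re-evaluation.
#' @param max_shrink safety cap on bracket contractions.
#' @return list with `eta` (new state), `loglik` (its log-likelihood) and
#'   `n_evals` (likelihood evaluations used).
#' @export
elliptical_slice_step <- function(eta, loglik, cur_loglik = NULL,
                                  max_shrink = 1000L) {
  ll0 <- if (is.null(cur_loglik)) loglik(eta) else cur_loglik
  if (is.nan(ll0) || is.na(ll0)) stop("log-likelihood is NaN at the current state")
  nu <- stats::rnorm(length(eta))
  logy <- ll0 + log(stats::runif(1))
  theta <- stats::runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi
  hi <- theta
  for (k in seq_len(max_shrink)) {
    prop <- eta * cos(theta) + nu * sin(theta)
    llp <- loglik(prop)
    if (is.nan(llp) || is.na(llp)) stop("log-likelihood returned NaN")
    if (llp > logy)
      return(list(eta = prop, loglik = llp, n_evals = k))
    if (theta < 0) lo <- theta else hi <- theta
    theta <- stats::runif(1, lo, hi)
  }
  stop("elliptical slice bracket failed to shrink after ", max_shrink,
       " contractions")
}

#' Fresh state for the adaptive random-walk sampler
#'
#' @param init_step initial proposal standard deviation.
#' @return list with `log_step`, `iteration`, `accept_count`.
#' @export
adaptive_rw_state <- function(init_step = 1) {
  if (!is.finite(init_step) || init_step <= 0) stop("init_step must be > 0")
  list(log_step = log(init_step), iteration = 0L, accept_count = 0L)
}

#' One adaptive random-walk Metropolis update of a scalar
#'
#' Symmetric Gaussian proposal N(theta, exp(log_step)^2) accepted by the
#' Metropolis rule, followed by a Robbins-Monro step-size update
#' log_step <- log_step + delta(i) * (accepted - 0.44) with gain
#' delta(i) = min(0.01, i^(-1/2)).  The diminishing gain preserves ergodicity
#' while steering the long-run acceptance rate to 0.44.
#'
#' @param theta current scalar value.
#' @param logpost function(theta) returning the log posterior density.
#' @param state an [adaptive_rw_state()].
#' @param cur_logpost optional cached `logpost(theta)`.
#' @param target target acceptance rate (0.44).
#' @return list with `theta`, `logpost` (at the returned theta), `state`,
#'   `accepted`.
#' @export
adaptive_rw_step <- function(theta, logpost, state, cur_logpost = NULL,
                             target = 0.44) {
  lp0 <- if (is.null(cur_logpost)) logpost(theta) else cur_logpost
  if (is.nan(lp0) || is.na(lp0)) stop("log-posterior is NaN at the current state")
  prop <- theta + exp(state$log_step) * stats::rnorm(1)
  lpp <- logpost(prop)
  accepted <- FALSE
  if (is.nan(lpp) || is.na(lpp)) {
    warning("log-posterior NaN at proposal; rejecting")
  } else if (log(stats::runif(1)) < lpp - lp0) {
    accepted <- TRUE
  }
  state$iteration <- state$iteration + 1L
  delta <- min(0.01, 1 / sqrt(state$iteration))
  state$log_step <- state$log_step + delta * (as.numeric(accepted) - target)
  if (accepted) state$accept_count <- state$accept_count + 1L
  list(theta = if (accepted) prop else theta,
       logpost = if (accepted) lpp else lp0,
       state = state,
       accepted = accepted)
}
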