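# Joint whitened MCMC over (eta_G, eta_E, log lambda_G, log lambda_E).
#
# The log-variance curves are parameterized as log sigma2 = C(lambda)^{1/2}
# eta with eta ~ N(0, I) ("whitening"), which decouples the curves from their
# length scales under the prior and lets elliptical slice sampling update the
# curves without rejections.  Length scales get adaptive random-walk
# Metropolis on the log scale under the automatic hyperprior of
# [lengthscale_hyperprior()].

.curve_from_eta <- function(L, eta) exp(drop(L %*% eta))

#' Log posterior density of the whitened joint model
#'
#' Sum of the factorized likelihood at the curves implied by the state, the
#' standard-normal log priors of eta_G and eta_E, and the normal hyperpriors
#' of the log length scales.  Exposed mainly for testing; [run_joint_mcmc()]
#' evaluates the same quantity incrementally with cached covariance roots.
#'
#' @param state list with `eta_G`, `eta_E`, `log_lambda_G`, `log_lambda_E`.
#' @param z transformed phenotypes U' y_c (N x T).
#' @param xi eigenvalues of G.
#' @param times time grid (length T).
#' @param hyper hyperprior list from [lengthscale_hyperprior()].
#' @return scalar log posterior density (unnormalized).
#' @export
log_posterior <- function(state, z, xi, times, hyper) {
  LG <- cov_sqrt(cov_matrix(times, matern_kernel(exp(state$log_lambda_G))))
  LE <- cov_sqrt(cov_matrix(times, matern_kernel(exp(state$log_lambda_E))))
  ll <- joint_loglik(z, xi, .curve_from_eta(LG, state$eta_G),
                     .curve_from_eta(LE, state$eta_E))
  pr_eta <- sum(stats::dnorm(state$eta_G, log = TRUE)) +
    sum(stats::dnorm(state$eta_E, log = TRUE))
  pr_lam <- stats::dnorm(state$log_lambda_G, hyper$mu_lambda,
                         hyper$zeta_lambda, log = TRUE) +
    stats::dnorm(state$log_lambda_E, hyper$mu_lambda, hyper$zeta_lambda,
                 log = TRUE)
  comps <- c(likelihood = ll, eta_prior = pr_eta, lambda_prior = pr_lam)
  if (any(!is.finite(comps)))
    stop("non-finite log-posterior component: ",
         paste(names(comps)[!is.finite(comps)], collapse = ", "))
  ll + pr_eta + pr_lam
}

.validate_run_args <- function(panel, G, iterations, burnin, thin) {
  stopifnot(inherits(panel, "phenotype_panel"))
  G <- .check_relmat(G)
  if (nrow(G) != nrow(panel$values))
    stop("panel and relationship matrix disagree on the number of individuals")
  gids <- rownames(G)
  if (!is.null(gids) && !is.null(panel$ids) && !identical(gids, panel$ids))
    stop("individual IDs of the panel and the relationship matrix differ ",
         "(same individuals in identical order are required)")
  if (iterations <= burnin || burnin < 0) stop("need iterations > burnin >= 0")
  if (thin < 1) stop("thin must be >= 1")
  G
}

#' Joint MCMC for dynamic variance components and heritability
#'
#' Runs the whitened sampler: per sweep, an elliptical slice update of
#' eta_E, then of eta_G, then adaptive random-walk Metropolis updates of
#' log lambda_E and log lambda_G.  Data are centred and scaled internally
#' (see [center_scale()]); draws are stored on that analysis scale and, for
#' the variance components, also back on the original scale via the recorded
#' scale factor.  Heritability h2(t) = sigma2_G(t) / (sigma2_G(t) +
#' sigma2_E(t)) is scale-free.
#'
#' @param panel a [phenotype_panel()].
#' @param G relationship matrix with individuals in the panel's order.
#' @param iterations total MCMC sweeps.
#' @param burnin sweeps discarded from the front (default half).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; required, the run is bit-reproducible given it.
#' @param config optional list: `verbose` (logical), `progress_every`
#'   (default 1000), `log_file` (path), `init_step` (RW start step),
#'   `cov_sqrt_fn` (covariance-root routine, injectable for instrumentation).
#' @return object of class `posterior_draws`: matrices `sigma2_G`,
#'   `sigma2_E`, `h2` (S x T, analysis scale), `sigma2_G_orig`,
#'   `sigma2_E_orig` (original scale), vectors `lambda_G`, `lambda_E`, and
#'   `meta` (seed, iterations, burnin, thin, scale_factor, acceptance rates,
#'   time grid).
#' @export
run_joint_mcmc <- function(panel, G, iterations = 20000L,
                           burnin = iterations %/% 2L, thin = 10L,
                           seed, config = list()) {
  G <- .validate_run_args(panel, G, iterations, burnin, thin)
  if (missing(seed)) stop("seed is required")
  covfn <- config$cov_sqrt_fn
  if (is.null(covfn)) covfn <- cov_sqrt
  logger <- .make_logger(config)

  cs <- center_scale(panel)
  eig <- eigendecompose_grm(G)
  z <- transform_phenotypes(eig, cs$panel)
  xi <- eig$xi
  times <- panel$times
  hyper <- lengthscale_hyperprior(times)

  set.seed(seed)
  T_ <- length(times)
  eta_G <- eta_E <- rep(0, T_)
  log_lam_G <- log_lam_E <- hyper$mu_lambda
  LG <- covfn(cov_matrix(times, matern_kernel(exp(log_lam_G))))
  LE <- covfn(cov_matrix(times, matern_kernel(exp(log_lam_E))))
  sG <- .curve_from_eta(LG, eta_G)
  sE <- .curve_from_eta(LE, eta_E)
  cur_ll <- joint_loglik(z, xi, sG, sE)

  init_step <- if (is.null(config$init_step)) 0.5 else config$init_step
  st_E <- adaptive_rw_state(init_step)
  st_G <- adaptive_rw_state(init_step)

  S <- (iterations - burnin) %/% thin
  if (S < 1L) stop("no draws would be stored; decrease burnin or thin")
  out_sG <- matrix(NA_real_, S, T_)
  out_sE <- matrix(NA_real_, S, T_)
  out_lamG <- out_lamE <- numeric(S)
  s <- 0L

  # Proposal-side cache for the lambda updates: the RW logpost closure stores
  # the covariance root and likelihood of the proposal so an accepted move
  # reuses them instead of refactorizing.
  lam_cache <- new.env(parent = emptyenv())
  make_lam_logpost <- function(which) {
    force(which)
    function(lam) {
      L <- covfn(cov_matrix(times, matern_kernel(exp(lam))))
      ll <- if (which == "E")
        joint_loglik(z, xi, sG, .curve_from_eta(L, eta_E))
      else
        joint_loglik(z, xi, .curve_from_eta(L, eta_G), sE)
      assign("L", L, envir = lam_cache)
      assign("ll", ll, envir = lam_cache)
      ll + stats::dnorm(lam, hyper$mu_lambda, hyper$zeta_lambda, log = TRUE)
    }
  }

  for (i in seq_len(iterations)) {
    # eta_E, then eta_G, by elliptical slice sampling
    r <- elliptical_slice_step(
      eta_E, function(e) joint_loglik(z, xi, sG, .curve_from_eta(LE, e)),
      cur_loglik = cur_ll)
    eta_E <- r$eta; cur_ll <- r$loglik
    sE <- .curve_from_eta(LE, eta_E)

    r <- elliptical_slice_step(
      eta_G, function(e) joint_loglik(z, xi, .curve_from_eta(LG, e), sE),
      cur_loglik = cur_ll)
    eta_G <- r$eta; cur_ll <- r$loglik
    sG <- .curve_from_eta(LG, eta_G)

    # log lambda_E, then log lambda_G, by adaptive random walk
    lpE <- make_lam_logpost("E")
    r <- adaptive_rw_step(log_lam_E, lpE, st_E,
                          cur_logpost = cur_ll +
                            stats::dnorm(log_lam_E, hyper$mu_lambda,
                                         hyper$zeta_lambda, log = TRUE))
    st_E <- r$state
    if (r$accepted) {
      log_lam_E <- r$theta
      LE <- get("L", envir = lam_cache)
      cur_ll <- get("ll", envir = lam_cache)
      sE <- .curve_from_eta(LE, eta_E)
    }

    lpG <- make_lam_logpost("G")
    r <- adaptive_rw_step(log_lam_G, lpG, st_G,
                          cur_logpost = cur_ll +
                            stats::dnorm(log_lam_G, hyper$mu_lambda,
                                         hyper$zeta_lambda, log = TRUE))
    st_G <- r$state
    if (r$accepted) {
      log_lam_G <- r$theta
      LG <- get("L", envir = lam_cache)
      cur_ll <- get("ll", envir = lam_cache)
      sG <- .curve_from_eta(LG, eta_G)
    }

    if (i > burnin && (i - burnin) %% thin == 0L) {
      s <- s + 1L
      out_sG[s, ] <- sG
      out_sE[s, ] <- sE
      out_lamG[s] <- exp(log_lam_G)
      out_lamE[s] <- exp(log_lam_E)
    }
    if (i %% logger$every == 0L)
      logger$log(sprintf(
        "iteration %d/%d loglik %.3f acc(lambda_E) %.3f acc(lambda_G) %.3f",
        i, iterations, cur_ll, st_E$accept_count / i, st_G$accept_count / i))
  }

  logger$log(sprintf("finished: %d stored draws, final acceptance E=%.3f G=%.3f",
                     S, st_E$accept_count / iterations,
                     st_G$accept_count / iterations))
  structure(list(
    sigma2_G = out_sG,
    sigma2_E = out_sE,
    h2 = out_sG / (out_sG + out_sE),
    sigma2_G_orig = out_sG * cs$scale_factor,
    sigma2_E_orig = out_sE * cs$scale_factor,
    lambda_G = out_lamG,
    lambda_E = out_lamE,
    meta = list(seed = seed, iterations = iterations, burnin = burnin,
                thin = thin, scale_factor = cs$scale_factor, times = times,
                accept_rate_lambda_E = st_E$accept_count / iterations,
                accept_rate_lambda_G = st_G$accept_count / iterations,
                method = "joint")
  ), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(paste0("posterior_draws (%s): %d draws x %d time points ",
                     "(%d iterations, burnin %d, thin %d, seed %s)\n"),
              x$meta$method, nrow(x$sigma2_G), ncol(x$sigma2_G),
              x$meta$iterations, x$meta$burnin, x$meta$thin,
              format(x$meta$seed)))
  invisible(x)
}

.curve_summary <- function(draws, times) {
  if (is.null(dim(draws)) || nrow(draws) < 1L) stop("empty draws")
  data.frame(time = times,
             mean = colMeans(draws),
             lower95 = apply(draws, 2L, stats::quantile, probs = 0.025),
             upper95 = apply(draws, 2L, stats::quantile, probs = 0.975),
             row.names = NULL)
}

#' Posterior curve summaries
#'
#' Pointwise posterior means and central 95% credible intervals for the two
#' variance components and heritability.  h2 is summarized from the per-draw
#' h2 values, not from a ratio of summarized components.
#'
#' @param draws a `posterior_draws` object.
#' @param scale `"analysis"` (mean total variance 2) or `"original"` for the
#'   variance components; h2 is identical on both.
#' @return list of data.frames `sigma2_G`, `sigma2_E`, `h2`, each with
#'   columns time, mean, lower95, upper95.
#' @export
summarize_draws <- function(draws, scale = c("analysis", "original")) {
  stopifnot(inherits(draws, "posterior_draws"))
  scale <- match.arg(scale)
  if (nrow(draws$sigma2_G) < 1L) stop("empty draws")
  sG <- if (scale == "analysis") draws$sigma2_G else draws$sigma2_G_orig
  sE <- if (scale == "analysis") draws$sigma2_E else draws$sigma2_E_orig
  list(sigma2_G = .curve_summary(sG, draws$meta$times),
       sigma2_E = .curve_summary(sE, draws$meta$times),
       h2 = .curve_summary(draws$h2, draws$meta$times))
}

#' Posterior breeding values at one time point
#'
#' Conditional on point estimates of the variance components at time t, the
#' breeding values are Gaussian with
#' mu_u = s2G G (s2G G + s2E I)^{-1} y and
#' Sigma_u = s2G G - s2G G (s2G G + s2E I)^{-1} s2G G,
#' evaluated through the eigendecomposition of G (no explicit inverse).
#'
#' @param G relationship matrix or a cached [eigendecompose_grm()] result.
#' @param sigma2_G,sigma2_E positive variance estimates at the time point.
#' @param y_t centred phenotype vector at the time point.
#' @return list with `mu_u` (N-vector) and `Sigma_u` (N x N).
#' @export
breeding_values <- function(G, sigma2_G, sigma2_E, y_t) {
  if (!inherits(G, "eigen_grm")) G <- eigendecompose_grm(G)
  if (!is.finite(sigma2_G) || !is.finite(sigma2_E) ||
      sigma2_G <= 0 || sigma2_E <= 0)
    stop("variance estimates must be positive")
  if (length(y_t) != nrow(G$U)) stop("length(y_t) must match G")
  g <- sigma2_G * G$xi
  d <- g / (g + sigma2_E)
  zt <- crossprod(G$U, y_t)
  mu <- drop(G$U %*% (d * zt))
  Sigma <- G$U %*% ((g - g * d) * t(G$U))
  list(mu_u = mu, Sigma_u = (Sigma + t(Sigma)) / 2)
}
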