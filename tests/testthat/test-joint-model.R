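test_that("log_posterior matches a monolithic dense evaluation", {
  set.seed(201)
  N <- 4; T_ <- 3
  times <- c(0, 1.5, 4)
  G <- random_psd(N) + diag(0.1, N)
  eg <- eigendecompose_grm(G)
  y <- matrix(rnorm(N * T_), N, T_)
  z <- crossprod(eg$U, y)
  hyper <- lengthscale_hyperprior(times)
  state <- list(eta_G = rnorm(T_), eta_E = rnorm(T_),
                log_lambda_G = hyper$mu_lambda + 0.3,
                log_lambda_E = hyper$mu_lambda - 0.2)

  # independent dense computation, including an independent symmetric root
  dense_sqrt <- function(C) {
    e <- eigen(C + diag(1e-10, nrow(C)), symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  mk_curve <- function(lam, eta) {
    D <- abs(outer(times, times, "-"))
    exp(drop(dense_sqrt((1 + D / lam) * exp(-D / lam)) %*% eta))
  }
  s2G <- mk_curve(exp(state$log_lambda_G), state$eta_G)
  s2E <- mk_curve(exp(state$log_lambda_E), state$eta_E)
  expected <- dense_joint_loglik(y, G, s2G, s2E) +
    sum(dnorm(state$eta_G, log = TRUE)) + sum(dnorm(state$eta_E, log = TRUE)) +
    dnorm(state$log_lambda_G, hyper$mu_lambda, hyper$zeta_lambda, log = TRUE) +
    dnorm(state$log_lambda_E, hyper$mu_lambda, hyper$zeta_lambda, log = TRUE)
  expect_equal(log_posterior(state, z, eg$xi, times, hyper), expected,
               tolerance = 1e-8)
})

test_that("zero whitened coefficients give unit curves", {
  set.seed(203)
  N <- 5; T_ <- 3; times <- 1:3
  G <- random_psd(N) + diag(0.1, N)
  eg <- eigendecompose_grm(G)
  z <- crossprod(eg$U, matrix(rnorm(N * T_), N, T_))
  hyper <- lengthscale_hyperprior(times)
  state <- list(eta_G = rep(0, T_), eta_E = rep(0, T_),
                log_lambda_G = hyper$mu_lambda, log_lambda_E = hyper$mu_lambda)
  lp <- log_posterior(state, z, eg$xi, times, hyper)
  expected_ll <- joint_loglik(z, eg$xi, rep(1, T_), rep(1, T_))
  pr <- 2 * T_ * dnorm(0, log = TRUE) +
    2 * dnorm(hyper$mu_lambda, hyper$mu_lambda, hyper$zeta_lambda, log = TRUE)
  expect_equal(lp, expected_ll + pr)
})

joint_fixture <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) {
      sim <<- simulate_longitudinal(40, seq(0, 12, by = 2), seed = 205)
    }
    sim
  }
})

test_that("run_joint_mcmc is bitwise reproducible and validates inputs", {
  sim <- joint_fixture()
  run <- function() run_joint_mcmc(sim$panel, sim$truth$G_true,
                                   iterations = 300, burnin = 100, thin = 4,
                                   seed = 99)
  d1 <- run(); d2 <- run()
  expect_identical(d1, d2)
  expect_identical(nrow(d1$sigma2_G), (300L - 100L) %/% 4L)
  expect_true(all(d1$h2 > 0 & d1$h2 < 1))
  expect_true(all(d1$sigma2_G > 0))
  expect_equal(d1$sigma2_G_orig, d1$sigma2_G * d1$meta$scale_factor)

  expect_error(run_joint_mcmc(sim$panel, sim$truth$G_true[1:10, 1:10],
                              iterations = 10, seed = 1),
               "number of individuals")
  Gbad <- sim$truth$G_true
  rownames(Gbad) <- rev(rownames(Gbad))
  expect_error(run_joint_mcmc(sim$panel, Gbad, iterations = 10, seed = 1),
               "IDs")
  expect_error(run_joint_mcmc(sim$panel, sim$truth$G_true, iterations = 10,
                              burnin = 20, seed = 1), "burnin")
})

test_that("covariance roots are recomputed only for length-scale proposals", {
  sim <- joint_fixture()
  calls <- 0L
  counting_sqrt <- function(C, ...) { calls <<- calls + 1L; cov_sqrt(C, ...) }
  iters <- 40L
  run_joint_mcmc(sim$panel, sim$truth$G_true, iterations = iters,
                 burnin = 20, thin = 2, seed = 7,
                 config = list(cov_sqrt_fn = counting_sqrt))
  # two at initialization plus one per lambda proposal (two per sweep)
  expect_identical(calls, 2L + 2L * iters)
})

test_that("h2 draws are invariant to rescaling the raw phenotypes", {
  sim <- joint_fixture()
  p2 <- phenotype_panel(sim$panel$values * 4, sim$panel$times, sim$panel$ids)
  d1 <- run_joint_mcmc(sim$panel, sim$truth$G_true, iterations = 200,
                       burnin = 100, thin = 2, seed = 55)
  d2 <- run_joint_mcmc(p2, sim$truth$G_true, iterations = 200,
                       burnin = 100, thin = 2, seed = 55)
  expect_identical(d1$h2, d2$h2)
  expect_equal(d2$meta$scale_factor, 16 * d1$meta$scale_factor)
})

test_that("summarize_draws computes pointwise means and empirical 95% intervals", {
  times <- 1:4
  mk <- function(sG, sE) structure(list(
    sigma2_G = sG, sigma2_E = sE, h2 = sG / (sG + sE),
    sigma2_G_orig = sG, sigma2_E_orig = sE,
    lambda_G = rep(1, nrow(sG)), lambda_E = rep(1, nrow(sG)),
    meta = list(times = times, scale_factor = 1)), class = "posterior_draws")

  same <- mk(matrix(1.3, 5, 4), matrix(0.7, 5, 4))
  s <- summarize_draws(same)
  expect_equal(s$h2$lower95, s$h2$mean)
  expect_equal(s$h2$upper95, s$h2$mean)
  expect_equal(s$h2$mean, rep(0.65, 4))

  two <- mk(rbind(rep(0.2, 4), rep(0.4, 4)), matrix(1, 2, 4))
  expect_equal(summarize_draws(two)$sigma2_G$mean, rep(0.3, 4))

  # quantiles against an independent sort-and-interpolate computation
  set.seed(207)
  S <- 1001
  sG <- matrix(rexp(S * 4), S, 4)
  s <- summarize_draws(mk(sG, matrix(1, S, 4)))
  manual_q <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p
    lo <- floor(h) + 1
    x[lo] + (h - floor(h)) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(s$sigma2_G$lower95, apply(sG, 2, manual_q, p = 0.025))
  expect_equal(s$sigma2_G$upper95, apply(sG, 2, manual_q, p = 0.975))
})

test_that("breeding_values matches the dense formula and its limits", {
  set.seed(209)
  N <- 5
  G <- random_psd(N) + diag(0.2, N)
  y <- rnorm(N)
  s2G <- 0.8; s2E <- 0.5
  bv <- breeding_values(G, s2G, s2E, y)
  A <- s2G * G + s2E * diag(N)
  expect_equal(bv$mu_u, drop(s2G * G %*% solve(A, y)), tolerance = 1e-10)
  expect_equal(bv$Sigma_u,
               s2G * G - s2G * G %*% solve(A, s2G * G), tolerance = 1e-10)

  # G = I: scalar shrinkage
  bvI <- breeding_values(diag(N), s2G, s2E, y)
  expect_equal(bvI$mu_u, s2G / (s2G + s2E) * y)

  # vanishing genetic variance: no signal
  bv0 <- breeding_values(G, 1e-12, 1, y)
  expect_lt(max(abs(bv0$mu_u)), 1e-10)
  expect_lt(max(abs(bv0$Sigma_u)), 1e-10)
  expect_error(breeding_values(G, -1, 1, y), "positive")
})
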