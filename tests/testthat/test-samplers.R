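test_that("elliptical slice sampling preserves the standard-normal prior", {
  # constant likelihood: the chain's stationary law is the N(0, I) prior
  set.seed(101)
  d <- 3
  eta <- rep(5, d)                      # deliberately far start
  ll <- function(e) 0
  n <- 20000
  draws <- matrix(NA_real_, n, d)
  cur <- NULL
  for (i in seq_len(n)) {
    r <- elliptical_slice_step(eta, ll, cur_loglik = cur)
    eta <- r$eta; cur <- r$loglik
    draws[i, ] <- eta
  }
  expect_true(all(abs(colMeans(draws)) < 0.05))
  expect_true(all(abs(apply(draws, 2, var) - 1) < 0.1))
})

test_that("elliptical slice sampling matches the conjugate Gaussian posterior", {
  # prior N(0, I), likelihood N(y | eta, s2 I): posterior mean y/(1+s2),
  # variance s2/(1+s2) per coordinate
  set.seed(103)
  y <- c(1.5, -0.8)
  s2 <- 0.5
  ll <- function(e) -sum((y - e)^2) / (2 * s2)
  eta <- c(0, 0); cur <- ll(eta)
  n <- 50000
  draws <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    r <- elliptical_slice_step(eta, ll, cur_loglik = cur)
    eta <- r$eta; cur <- r$loglik
    draws[i, ] <- eta
  }
  expect_equal(colMeans(draws), y / (1 + s2), tolerance = 0.02)
  expect_equal(unname(apply(draws, 2, var)), rep(s2 / (1 + s2), 2),
               tolerance = 0.05)
})

test_that("elliptical slice sampling moves every step and rejects NaN likelihoods", {
  set.seed(107)
  eta <- rnorm(4); cur <- NULL
  ll <- function(e) -sum(e^2) / 4
  for (i in 1:1000) {
    r <- elliptical_slice_step(eta, ll, cur_loglik = cur)
    expect_false(isTRUE(all.equal(r$eta, eta)))
    eta <- r$eta; cur <- r$loglik
  }
  expect_error(elliptical_slice_step(rnorm(3), function(e) NaN), "NaN")
})

test_that("adaptive RW-MH attains the 0.44 acceptance target on a normal target", {
  set.seed(109)
  lp <- function(x) dnorm(x, log = TRUE)
  th <- 0; st <- adaptive_rw_state(5)       # badly mistuned start
  n <- 50000
  acc <- logical(n)
  draws <- numeric(n)
  cur <- lp(th)
  for (i in seq_len(n)) {
    r <- adaptive_rw_step(th, lp, st, cur_logpost = cur)
    th <- r$theta; st <- r$state; cur <- r$logpost
    acc[i] <- r$accepted; draws[i] <- th
  }
  expect_equal(mean(acc[(n / 2 + 1):n]), 0.44, tolerance = 0.03)
  expect_equal(var(draws[(n / 2 + 1):n]), 1, tolerance = 0.1)
})

test_that("adaptation moves the step in the documented direction", {
  set.seed(113)
  st <- adaptive_rw_state(1)
  th <- 0
  steps <- numeric(50)
  for (i in 1:50) {               # flat target: every proposal accepted
    r <- adaptive_rw_step(th, function(x) 0, st)
    th <- r$theta; st <- r$state
    expect_true(r$accepted)
    steps[i] <- st$log_step
  }
  expect_true(all(diff(c(0, steps)) > 0))
})

test_that("adaptive RW-MH guards against NaN posteriors", {
  st <- adaptive_rw_state(1)
  expect_error(adaptive_rw_step(0, function(x) NaN, st), "NaN at the current")
  set.seed(127)
  expect_warning(
    r <- adaptive_rw_step(0, function(x) if (x == 0) 0 else NaN, st,
                          cur_logpost = 0),
    "rejecting")
  expect_false(r$accepted)
  expect_identical(r$theta, 0)
})

test_that("seeded chains are exactly reproducible", {
  run <- function() {
    set.seed(131)
    th <- 0; st <- adaptive_rw_state(1); eta <- rnorm(3); out <- list()
    for (i in 1:50) {
      r <- adaptive_rw_step(th, function(x) -x^2 / 2, st)
      th <- r$theta; st <- r$state
      e <- elliptical_slice_step(eta, function(v) -sum(v^2) / 4)
      eta <- e$eta
    }
    list(th = th, eta = eta)
  }
  expect_identical(run(), run())
})
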