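test_that("center_scale enforces the mean-variance-2 convention", {
  set.seed(3)
  cs <- center_scale(random_panel(30, 1:6))
  expect_equal(max(abs(colMeans(cs$panel$values))), 0, tolerance = 1e-12)
  expect_equal(mean(apply(cs$panel$values, 2, var)), 2, tolerance = 1e-12)
  # scale_factor maps analysis-scale variances back to the original scale
  raw <- random_panel(25, 1:4)
  cs2 <- center_scale(raw)
  expect_equal(mean(apply(sweep(raw$values, 2, colMeans(raw$values)), 2, var)),
               2 * cs2$scale_factor)
})

test_that("center_scale is a fixed point on conforming data and rejects constants", {
  v <- rbind(c(-1, -2), c(0, 0), c(1, 2))      # exactly centred
  v <- v * sqrt(2 / mean(apply(v, 2, var)))
  p <- phenotype_panel(v, c(1, 2))
  cs <- center_scale(p)
  expect_equal(cs$panel$values, p$values)
  expect_equal(cs$scale_factor, 1)
  expect_error(center_scale(phenotype_panel(matrix(5, 3, 2), 1:2)),
               "zero phenotypic variance")
})

test_that("phenotype_panel validates its inputs", {
  expect_error(phenotype_panel(matrix(c(1, NA, 2, 3), 2), 1:2),
               "missing phenotypes unsupported")
  expect_error(phenotype_panel(matrix(1:4, 2), c(2, 1)), "strictly increasing")
})

test_that("eigendecompose_grm reconstructs and clamps round-off negatives", {
  eg <- eigendecompose_grm(diag(3))
  expect_equal(eg$xi, rep(1, 3))
  expect_equal(crossprod(eg$U), diag(3), tolerance = 1e-8)

  G <- rbind(c(2, -2), c(-2, 2))
  expect_equal(eigendecompose_grm(G)$xi, c(4, 0))

  set.seed(9)
  G <- random_psd(20)
  eg <- eigendecompose_grm(G)
  expect_lt(norm(eg$U %*% (eg$xi * t(eg$U)) - G, "F"), 1e-8)
  expect_true(all(eg$xi >= 0))
  expect_error(eigendecompose_grm(matrix(1:4, 2)), "not symmetric")
  expect_error(eigendecompose_grm(diag(c(1, -1))), "not positive semidefinite")
})

test_that("joint_loglik equals the iid closed form when G = I and curves are 1", {
  set.seed(13)
  z <- matrix(rnorm(8 * 3), 8, 3)
  ll <- joint_loglik(z, rep(1, 8), rep(1, 3), rep(1, 3))
  expect_equal(ll, -(8 * 3 / 2) * log(4 * pi) - sum(z^2) / 4)
})

test_that("joint_loglik matches the dense block-diagonal oracle", {
  set.seed(17)
  for (rep in 1:8) {
    N <- sample(2:6, 1); T_ <- sample(1:3, 1)
    G <- random_psd(N) + diag(0.05, N)
    eg <- eigendecompose_grm(G)
    y <- matrix(rnorm(N * T_), N, T_)
    s2G <- runif(T_, 0.2, 3); s2E <- runif(T_, 0.2, 3)
    ll <- joint_loglik(crossprod(eg$U, y), eg$xi, s2G, s2E)
    expect_equal(ll, dense_joint_loglik(y, G, s2G, s2E), tolerance = 1e-8)
  }
})

test_that("joint_loglik is separable over time points and permutation invariant", {
  set.seed(19)
  N <- 5; T_ <- 4
  z <- matrix(rnorm(N * T_), N, T_)
  xi <- sort(runif(N), decreasing = TRUE)
  s2G <- runif(T_, 0.5, 2); s2E <- runif(T_, 0.5, 2)
  base <- joint_loglik(z, xi, s2G, s2E)
  # doubling sigma2_E at time point 2 changes only that summand
  s2E2 <- s2E; s2E2[2] <- 2 * s2E[2]
  delta <- joint_loglik(z[, 2, drop = FALSE], xi, s2G[2], s2E2[2]) -
    joint_loglik(z[, 2, drop = FALSE], xi, s2G[2], s2E[2])
  expect_equal(joint_loglik(z, xi, s2G, s2E2), base + delta)
  perm <- c(3, 1, 4, 2)
  expect_equal(joint_loglik(z[, perm], xi, s2G[perm], s2E[perm]), base)
  expect_error(joint_loglik(z, xi, s2G, -s2E), "nonpositive variance")
})
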