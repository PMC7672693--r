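# Synthetic-data generators: a random dense relationship matrix, the
# longitudinal polygenic design with separable time x individual covariance,
# and the twin-design kinship matrix.  Every other module is testable against
# these without external downloads.

#' Random dense relationship matrix
#'
#' G = S S' / N + 0.1 I with S an N x N matrix of independent standard
#' normals.  The added diagonal makes G positive definite with smallest
#' eigenvalue at least 0.1; the mean diagonal is about 1.1.
#'
#' @param N number of individuals (>= 2).
#' @param seed integer seed.
#' @return N x N relationship matrix.
#' @export
sim_grm <- function(N, seed) {
  if (N < 2) stop("N must be at least 2")
  set.seed(seed)
  S <- matrix(stats::rnorm(N * N), N, N)
  G <- tcrossprod(S) / N + diag(0.1, N)
  ids <- paste0("ind", seq_len(N))
  dimnames(G) <- list(ids, ids)
  G
}

#' Time covariance used by the longitudinal simulator
#'
#' Evaluates, entrywise on the grid,
#' C_ij = (1 + 5 d / (50/3) + 5 d^2 / (3 (50/3)^2)) exp(-5 d / (50/3)),
#' d = |t_i - t_j|: a Matern-5/2-type correlation with unit diagonal whose
#' effective range suits grids spanning a few tens of time units.
#'
#' @param times time grid.
#' @return T x T correlation-like matrix.
#' @export
sim_time_cov <- function(times) {
  times <- .check_grid(times)
  d <- abs(outer(times, times, "-"))
  l <- 50 / 3
  (1 + 5 * d / l + 5 * d^2 / (3 * l^2)) * exp(-5 * d / l)
}

#' Default truth curves for fixtures
#'
#' A smooth logistic rise of heritability from 0.2 to 0.7 across the grid,
#' with total variance 2 (matching the analysis-scale convention), split into
#' sigma2_G = 2 h2 and sigma2_E = 2 (1 - h2).
#'
#' @param times time grid.
#' @return list with `sigma2_G`, `sigma2_E`, `h2`.
#' @export
default_truth_curves <- function(times) {
  times <- .check_grid(times)
  span <- max(times) - min(times)
  mid <- (max(times) + min(times)) / 2
  h2 <- 0.2 + 0.5 * stats::plogis((times - mid) / (span / 8))
  list(sigma2_G = 2 * h2, sigma2_E = 2 * (1 - h2), h2 = h2)
}

# Lower-triangular-ish square root: Cholesky when positive definite, else the
# symmetric eigenvalue root.  Any L with L L' = A gives the same law.
.mat_sqrt_fast <- function(A) {
  tryCatch(t(chol(A)), error = function(e) cov_sqrt(A))
}

#' Simulate longitudinal polygenic phenotypes
#'
#' Draws a genetic component from N(0, C (x) G) and an environmental
#' component from N(0, C (x) I), where C is [sim_time_cov()] on the grid and
#' G is a fresh [sim_grm()] draw (or a user-supplied matrix, e.g. a twin
#' kinship).  Each component's column t is then scaled by the square root of
#' the corresponding target variance and the two are summed.  Kronecker
#' sampling uses L_G Z L_C' on an N x T standard-normal Z, so the NT x NT
#' covariance is never formed.
#'
#' @param N number of individuals.
#' @param times time grid of length T.
#' @param sigma2_G_true,sigma2_E_true nonnegative target variance curves
#'   (length T); default [default_truth_curves()].
#' @param seed integer seed.
#' @param G optional relationship matrix to use instead of a fresh
#'   [sim_grm()] draw.
#' @return list with `panel` (a [phenotype_panel()]) and `truth` (fields
#'   `sigma2_G_true`, `sigma2_E_true`, `h2_true`, `G_true`,
#'   `genetic_component`, `environmental_component`).
#' @export
simulate_longitudinal <- function(N, times, sigma2_G_true = NULL,
                                  sigma2_E_true = NULL, seed, G = NULL) {
  times <- .check_grid(times)
  T_ <- length(times)
  if (is.null(sigma2_G_true) || is.null(sigma2_E_true)) {
    def <- default_truth_curves(times)
    if (is.null(sigma2_G_true)) sigma2_G_true <- def$sigma2_G
    if (is.null(sigma2_E_true)) sigma2_E_true <- def$sigma2_E
  }
  if (length(sigma2_G_true) != T_ || length(sigma2_E_true) != T_)
    stop("truth curves must have one entry per time point")
  if (any(sigma2_G_true < 0) || any(sigma2_E_true < 0) ||
      any(sigma2_G_true + sigma2_E_true <= 0))
    stop("truth curves must be nonnegative with positive total variance")

  set.seed(seed)
  if (is.null(G)) {
    if (N < 2) stop("N must be at least 2")
    S <- matrix(stats::rnorm(N * N), N, N)
    G <- tcrossprod(S) / N + diag(0.1, N)
  } else {
    G <- .check_relmat(G)
    if (nrow(G) != N) stop("supplied G must be N x N")
  }
  Lg <- .mat_sqrt_fast(G)
  Lc <- .mat_sqrt_fast(sim_time_cov(times))
  gen <- Lg %*% matrix(stats::rnorm(N * T_), N, T_) %*% t(Lc)
  env <- matrix(stats::rnorm(N * T_), N, T_) %*% t(Lc)
  gen <- sweep(gen, 2L, sqrt(sigma2_G_true), "*")
  env <- sweep(env, 2L, sqrt(sigma2_E_true), "*")
  ids <- paste0("ind", seq_len(N))
  dimnames(G) <- list(ids, ids)
  panel <- phenotype_panel(gen + env, times, ids)
  list(panel = panel,
       truth = list(sigma2_G_true = sigma2_G_true,
                    sigma2_E_true = sigma2_E_true,
                    h2_true = sigma2_G_true / (sigma2_G_true + sigma2_E_true),
                    G_true = G,
                    genetic_component = gen,
                    environmental_component = env))
}

#' Twin-design kinship matrix
#'
#' Block-diagonal kinship for monozygotic (within-pair covariance 1) and
#' dizygotic (within-pair covariance 0.5) twin pairs; unit diagonal and zero
#' covariance between pairs.  MZ pairs come first.
#'
#' @param n_mz_pairs,n_dz_pairs pair counts; at least one pair in total.
#' @return 2 (n_mz + n_dz) square relationship matrix.
#' @export
sim_twin_kinship <- function(n_mz_pairs, n_dz_pairs) {
  if (n_mz_pairs < 0 || n_dz_pairs < 0 || n_mz_pairs + n_dz_pairs < 1)
    stop("need at least one twin pair")
  blocks <- c(rep(list(matrix(c(1, 1, 1, 1), 2)), n_mz_pairs),
              rep(list(matrix(c(1, 0.5, 0.5, 1), 2)), n_dz_pairs))
  N <- 2L * (n_mz_pairs + n_dz_pairs)
  G <- matrix(0, N, N)
  for (k in seq_along(blocks)) {
    i <- (2L * k - 1L):(2L * k)
    G[i, i] <- blocks[[k]]
  }
  ids <- c(if (n_mz_pairs > 0) paste0("mz", rep(seq_len(n_mz_pairs), each = 2),
                                      c("a", "b")),
           if (n_dz_pairs > 0) paste0("dz", rep(seq_len(n_dz_pairs), each = 2),
                                      c("a", "b")))
  dimnames(G) <- list(ids, ids)
  G
}
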