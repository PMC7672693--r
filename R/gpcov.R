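# Matern nu = 3/2 covariance machinery: kernel evaluation, covariance
# matrices on a time grid, symmetric PSD square roots for whitening, and the
# automatic length-scale hyperprior.

#' Matern kernel with fixed smoothness 3/2
#'
#' The model fixes the smoothness at nu = 1.5 (once mean-square
#' differentiable sample paths) and the magnitude at tau2 = 1; identifiability
#' of (tau2, lambda) is resolved by scaling the data instead (see
#' [center_scale()]).  Other smoothness values are rejected.
#'
#' @param lengthscale lambda > 0, in the units of the time grid.
#' @param magnitude tau2 > 0, variance of the process at lag 0.
#' @param smoothness must be 1.5.
#' @return an object of class `matern_kernel`.
#' @export
matern_kernel <- function(lengthscale, magnitude = 1, smoothness = 1.5) {
  if (!identical(as.numeric(smoothness), 1.5))
    stop("only smoothness nu = 1.5 is supported")
  if (!is.finite(lengthscale) || lengthscale <= 0) stop("lengthscale must be > 0")
  if (!is.finite(magnitude) || magnitude <= 0) stop("magnitude must be > 0")
  structure(list(lengthscale = lengthscale, magnitude = magnitude,
                 smoothness = 1.5), class = "matern_kernel")
}

#' Matern 3/2 covariance at a distance
#'
#' C(d) = tau2 (1 + d/lambda) exp(-d/lambda), strictly decreasing in d and
#' vanishing as d grows.
#'
#' @param distance nonnegative distance(s) |t - t'|.
#' @param kernel a [matern_kernel()].
#' @return covariance value(s), same shape as `distance`.
#' @export
matern15 <- function(distance, kernel = matern_kernel(1)) {
  stopifnot(inherits(kernel, "matern_kernel"))
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be finite and nonnegative")
  r <- distance / kernel$lengthscale
  kernel$magnitude * (1 + r) * exp(-r)
}

.check_grid <- function(times, min_len = 1L) {
  times <- as.numeric(times)
  if (length(times) < min_len) stop("time grid too short")
  if (any(!is.finite(times))) stop("time grid must be finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("time grid must be strictly increasing")
  times
}

#' Covariance matrix of a kernel on a time grid
#'
#' @param times strictly increasing time grid.
#' @param kernel a [matern_kernel()].
#' @return T x T symmetric covariance matrix with `kernel$magnitude` on the
#'   diagonal (no jitter is added here; see [cov_sqrt()]).
#' @export
cov_matrix <- function(times, kernel) {
  times <- .check_grid(times)
  D <- abs(outer(times, times, "-"))
  matern15(D, kernel)
}

#' Symmetric PSD square root of a covariance matrix
#'
#' Returns L with L L' = C (to round-off) via the eigendecomposition of C,
#' flooring eigenvalues at `max(eig) * 1e-12` so that nearly singular kernels
#' on dense grids still factorize.  A jitter of `jitter * mean(diag(C))` is
#' added to the diagonal first.  The symmetric root is used rather than
#' Cholesky: any L with L L' = C induces the same whitened prior law.
#'
#' @param C symmetric positive-semidefinite matrix.
#' @param jitter relative diagonal jitter, default 1e-10.
#' @return L, same dimension as C, symmetric.
#' @export
cov_sqrt <- function(C, jitter = 1e-10) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("C must be a square matrix")
  scale <- max(abs(C), 1)
  if (max(abs(C - t(C))) > 1e-8 * scale) stop("C is not symmetric")
  n <- nrow(C)
  Cj <- C + diag(jitter * mean(diag(C)), n)
  e <- eigen((Cj + t(Cj)) / 2, symmetric = TRUE)
  w <- e$values
  if (max(w) <= 0) stop("covariance factorization failed: no positive eigenvalues")
  w <- pmax(w, max(w) * 1e-12)
  L <- e$vectors %*% (sqrt(w) * t(e$vectors))
  (L + t(L)) / 2
}

#' Automatic hyperprior for the log length scale
#'
#' The length scale is identifiable roughly between the smallest nonzero and
#' the largest pairwise distance of the time grid, say \[a, b\].  A normal
#' prior on log(lambda) is solved from
#' mu - 1.96 zeta = log a, mu + 1.96 zeta = log b,
#' which places about 95% (2 Phi(1.96) - 1 = 0.950004) of the prior mass in
#' \[log a, log b\].  This removes the last free tuning parameter of the model.
#'
#' @param times strictly increasing time grid with at least two points and at
#'   least two distinct pairwise distances.
#' @return list with `mu_lambda` and `zeta_lambda`.
#' @export
lengthscale_hyperprior <- function(times) {
  times <- .check_grid(times, min_len = 2L)
  d <- abs(outer(times, times, "-"))
  d <- d[d > 0]
  a <- min(d)
  b <- max(d)
  if (!(b > a))
    stop("degenerate grid: smallest and largest pairwise distances coincide")
  list(mu_lambda = (log(a) + log(b)) / 2,
       zeta_lambda = (log(b) - log(a)) / (2 * 1.96))
}
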