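# Phenotype container, the data-scaling convention, and the factorized
# longitudinal likelihood.
#
# The joint model treats the NT-vector of centred phenotypes as
# N(0, diag(sigma2_G(t)) x G + diag(sigma2_E(t)) x I) (Kronecker over time),
# i.e. block-diagonal over time points.  With G = U diag(xi) U' the
# transformed columns z(t) = U' y_c(t) are independent with variances
# sigma2_G(t) xi_n + sigma2_E(t), so the log-likelihood is a plain double sum
# and the NT x NT covariance is never formed.

#' Longitudinal phenotype panel
#'
#' @param values numeric N x T matrix, individuals in rows, one column per
#'   measurement time.  Missing values are not supported.
#' @param times strictly increasing numeric time grid of length T.
#' @param ids individual labels, default taken from rownames.
#' @return object of class `phenotype_panel` with fields `values`, `times`,
#'   `ids`.
#' @export
phenotype_panel <- function(values, times, ids = rownames(values)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(values)) stop("phenotype values must be numeric")
  if (anyNA(values)) stop("missing phenotypes unsupported")
  if (any(!is.finite(values))) stop("non-finite phenotype values")
  if (nrow(values) < 2L) stop("need at least 2 individuals")
  times <- .check_grid(times)
  if (length(times) != ncol(values))
    stop("length(times) must equal the number of phenotype columns")
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(values)))
  dimnames(values) <- list(ids, NULL)
  structure(list(values = values, times = times, ids = ids),
            class = "phenotype_panel")
}

#' @export
print.phenotype_panel <- function(x, ...) {
  cat(sprintf("phenotype_panel: %d individuals x %d time points (t in [%g, %g])\n",
              nrow(x$values), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Centre and scale a phenotype panel
#'
#' Each time-point column is centred to mean zero, then the whole panel is
#' multiplied by one constant so that the mean over time points of the
#' per-time-point sample variance equals 2.  With the GP magnitude fixed at
#' tau2 = 1 this convention makes the genetic and environmental variances
#' each average about 1 when they are equal, resolving the (tau2, lambda)
#' identifiability without tuning.  Sample variances use the 1/(N-1)
#' denominator.
#'
#' @param panel a [phenotype_panel()].
#' @return list with `panel` (scaled) and `scale_factor`; a variance
#'   estimated on the analysis scale times `scale_factor` is on the original
#'   scale.
#' @export
center_scale <- function(panel) {
  stopifnot(inherits(panel, "phenotype_panel"))
  y <- panel$values
  yc <- sweep(y, 2L, colMeans(y))
  v <- apply(yc, 2L, stats::var)
  vbar <- mean(v)
  if (vbar <= .Machine$double.eps) stop("zero phenotypic variance")
  scaled <- yc * sqrt(2 / vbar)
  list(panel = phenotype_panel(scaled, panel$times, panel$ids),
       scale_factor = vbar / 2)
}

#' Eigendecomposition of a relationship matrix
#'
#' Computed once per analysis: the eigenvectors do not depend on the variance
#' components, so the data transformation z(t) = U' y_c(t) is done a single
#' time.  Tiny negative eigenvalues (round-off from a PSD G) are clamped to
#' zero; substantially negative ones are an error.
#'
#' @param G symmetric relationship matrix.
#' @param tol relative tolerance for symmetry and negative-eigenvalue checks.
#' @return object of class `eigen_grm`: list with orthogonal `U` and
#'   eigenvalues `xi` in decreasing order.
#' @export
eigendecompose_grm <- function(G, tol = 1e-8) {
  G <- .check_relmat(G, tol = tol)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  xi <- e$values
  floor_tol <- tol * max(abs(xi), 1)
  if (any(xi < -floor_tol))
    stop("relationship matrix is not positive semidefinite (eigenvalue ",
         format(min(xi)), ")")
  xi[xi < 0] <- 0
  structure(list(U = e$vectors, xi = xi, ids = rownames(G)),
            class = "eigen_grm")
}

#' Factorized longitudinal log-likelihood
#'
#' log p(y | 0, Ktilde) = sum_t sum_n log N(z_n(t); 0, sigma2_G(t) xi_n +
#' sigma2_E(t)) where z(t) = U' y_c(t).  Cost is O(NT) per evaluation after
#' the one-off eigendecomposition; the NT x NT covariance is never formed.
#'
#' @param z N x T matrix of transformed phenotypes, columns U' y_c(t).
#' @param xi N eigenvalues of G (nonnegative).
#' @param sigma2_G,sigma2_E strictly positive variance curves of length T.
#' @return scalar log-likelihood.
#' @export
joint_loglik <- function(z, xi, sigma2_G, sigma2_E) {
  if (!is.matrix(z)) z <- as.matrix(z)
  N <- nrow(z); T_ <- ncol(z)
  if (length(xi) != N) stop("length(xi) must equal nrow(z)")
  if (length(sigma2_G) != T_ || length(sigma2_E) != T_)
    stop("variance curves must have one entry per time point")
  if (any(!is.finite(sigma2_G)) || any(!is.finite(sigma2_E)))
    stop("non-finite variance curve")
  V <- outer(xi, sigma2_G) + rep(sigma2_E, each = N)
  if (any(V <= 0)) stop("nonpositive variance in the likelihood")
  -0.5 * sum(log(2 * pi * V) + z * z / V)
}

# U' y for a panel (or plain matrix) against a cached eigendecomposition.
transform_phenotypes <- function(eig, values) {
  if (inherits(values, "phenotype_panel")) values <- values$values
  crossprod(eig$U, values)
}
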