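# Genotype handling and the VanRaden genomic relationship matrix.
#
# Genotypes are plain numeric matrices, individuals in rows and markers in
# columns, coded -1 (one homozygote), 0 (heterozygote), 1 (the other
# homozygote).  After mean imputation entries may be fractional; all
# downstream formulas accept that.

.check_geno <- function(geno, allow_missing = FALSE) {
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  if (!is.numeric(geno)) stop("genotype matrix must be numeric")
  if (nrow(geno) < 2L) stop("need at least 2 individuals")
  if (ncol(geno) < 1L) stop("need at least 1 marker")
  obs <- geno[!is.na(geno)]
  if (any(!is.finite(obs))) stop("non-finite genotype values")
  if (any(obs < -1 | obs > 1)) stop("genotype codes must lie in [-1, 1]")
  if (!allow_missing && anyNA(geno))
    stop("missing genotypes present; run impute_missing() first")
  storage.mode(geno) <- "double"
  geno
}

.marker_names <- function(geno) {
  if (!is.null(colnames(geno))) colnames(geno) else as.character(seq_len(ncol(geno)))
}

#' Impute missing marker genotypes with per-marker means
#'
#' Each missing entry is replaced by the mean of the observed codes in its
#' marker column, computed over individuals.  Imputed values are left
#' fractional; they are not rounded back to the -1/0/1 codes.  Imputation is
#' done once, before the relationship matrix is built.
#'
#' @param geno numeric matrix, individuals x markers, codes in \{-1, 0, 1\}
#'   with `NA` for missing.
#' @return the matrix with no missing entries; observed entries unchanged.
#' @examples
#' g <- rbind(a = c(1, NA), b = c(-1, 0), c = c(NA, 1))
#' impute_missing(g)
#' @export
impute_missing <- function(geno) {
  geno <- .check_geno(geno, allow_missing = TRUE)
  miss <- is.na(geno)
  if (!any(miss)) return(geno)
  n_obs <- colSums(!miss)
  if (any(n_obs == 0L)) {
    bad <- .marker_names(geno)[n_obs == 0L]
    stop("marker has no observed genotypes: ", paste(bad, collapse = ", "))
  }
  mns <- colMeans(geno, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  geno[miss] <- mns[idx[, 2L]]
  geno
}

#' Allele frequencies of the second allele
#'
#' Under the -1/0/1 coding the second-allele dosage of an individual is
#' (g + 1)/2 in \[0, 1\], so the frequency at marker i is the mean dosage
#' p_i = mean((g_i + 1)/2) over individuals.
#'
#' @param geno imputed genotype matrix (no missing values).
#' @return vector of length M with entries in \[0, 1\].
#' @export
allele_freqs <- function(geno) {
  geno <- .check_geno(geno)
  p <- colMeans((geno + 1) / 2)
  names(p) <- colnames(geno)
  p
}

#' VanRaden genomic relationship matrix
#'
#' Builds G = QQ' / (2 * sum_i p_i (1 - p_i)) where Q = M - P and the i-th
#' column of P is the constant 2(p_i - 0.5).  G is symmetric and positive
#' semidefinite by construction; its diagonal averages to about 1 for
#' genotypes at Hardy-Weinberg proportions.
#'
#' No shrinkage is applied; a shrinkage-estimated G can be supplied
#' externally wherever a relationship matrix is accepted.
#'
#' @param geno imputed genotype matrix (no missing values).
#' @param p optional allele frequencies; defaults to [allele_freqs()] of
#'   `geno`.  Supplying external frequencies allows G to be built against a
#'   reference panel.
#' @return N x N relationship matrix with individual IDs as dimnames.
#' @examples
#' g <- rbind(a = c(1, -1), b = c(-1, 1))
#' vanraden_grm(g)  # [[2, -2], [-2, 2]]
#' @export
vanraden_grm <- function(geno, p = allele_freqs(geno)) {
  geno <- .check_geno(geno)
  if (length(p) != ncol(geno)) stop("length(p) must equal the number of markers")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero denominator: no polymorphic markers")
  Q <- sweep(geno, 2L, 2 * (p - 0.5))
  G <- tcrossprod(Q) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  G
}

#' Back-transform breeding values to per-SNP effects
#'
#' Given posterior mean breeding values mu_u at one time point, recovers SNP
#' effects m = R' G^- mu_u with \[R\]_ij = (\[M\]_ij + 1 - 2 p_j) / (2 p_j (1 - p_j)).
#' When G is singular (it is only guaranteed positive semidefinite) a
#' pseudo-inverse with a relative eigenvalue cutoff is used, so mu_u is
#' implicitly projected onto the range of G.
#'
#' @param G relationship matrix used to estimate the breeding values.
#' @param mu_u N-vector of (posterior mean) breeding values.
#' @param geno imputed genotype matrix the effects refer to.
#' @param p allele frequencies; all must be strictly inside (0, 1).
#' @param tol relative eigenvalue cutoff for the pseudo-inverse.
#' @return M-vector of SNP effects, named by marker.
#' @export
snp_backtransform <- function(G, mu_u, geno, p = allele_freqs(geno),
                              tol = 1e-10) {
  geno <- .check_geno(geno)
  G <- .check_relmat(G)
  if (length(mu_u) != nrow(G) || nrow(geno) != nrow(G))
    stop("dimension mismatch between G, mu_u and the genotype matrix")
  if (any(p <= 0 | p >= 1))
    stop("allele frequency 0 or 1: division by zero in the back-transformation")
  R <- sweep(geno + 1, 2L, 2 * p)
  R <- sweep(R, 2L, 2 * p * (1 - p), "/")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  if (!any(keep)) stop("G has no eigenvalues above the pseudo-inverse cutoff")
  U <- e$vectors[, keep, drop = FALSE]
  ginv_mu <- U %*% (crossprod(U, mu_u) / e$values[keep])
  m <- drop(crossprod(R, ginv_mu))
  names(m) <- colnames(geno)
  m
}

.check_relmat <- function(G, tol = 1e-8) {
  if (!is.matrix(G)) G <- as.matrix(G)
  if (!is.numeric(G) || nrow(G) != ncol(G)) stop("relationship matrix must be square numeric")
  scale <- max(abs(G), 1)
  if (max(abs(G - t(G))) > tol * scale) stop("relationship matrix is not symmetric")
  G
}
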