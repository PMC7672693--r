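# Fixtures are generated in code; nothing is stored on disk.

# Genotypes at Hardy-Weinberg proportions, coded -1/0/1.
hw_genotypes <- function(n, m, p = stats::runif(m, 0.1, 0.9)) {
  g <- vapply(p, function(pi) stats::rbinom(n, 2, pi) - 1, numeric(n))
  rownames(g) <- paste0("ind", seq_len(n))
  colnames(g) <- paste0("snp", seq_len(m))
  g
}

# Random symmetric PSD matrix with unit-scale eigenvalues.
random_psd <- function(n, rank = n) {
  A <- matrix(stats::rnorm(n * rank), n, rank)
  tcrossprod(A) / rank
}

# Small random phenotype panel.
random_panel <- function(n = 20, times = 1:5) {
  phenotype_panel(matrix(stats::rnorm(n * length(times)), n), times)
}

# Dense multivariate-normal log density, the brute-force likelihood oracle.
dense_mvn_logpdf <- function(y, K) {
  n <- length(y)
  -0.5 * (n * log(2 * pi) + determinant(K, logarithm = TRUE)$modulus +
            drop(y %*% solve(K, y)))
}

# Dense oracle for the block-diagonal longitudinal likelihood: sums the
# per-time-point dense densities of N(0, s2G[t] G + s2E[t] I).
dense_joint_loglik <- function(y, G, s2G, s2E) {
  sum(vapply(seq_along(s2G), function(t)
    dense_mvn_logpdf(y[, t], s2G[t] * G + s2E[t] * diag(nrow(G))),
    numeric(1)))
}
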