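# shared builders for small synthetic cohorts used across test files

null_cohort <- function(n_mz = 30, n_dz = 30, n_genes = 20,
                        exons = c(1, 3), seed = 1, ...) {
  simulate_cohort(sim_config(n_mz_pairs = n_mz, n_dz_pairs = n_dz,
                             n_genes = n_genes,
                             exons_per_gene_range = exons,
                             n_null_snps = 0, seed = seed, ...))
}

# within-pair correlation of a per-sample vector for one zygosity class
pair_cor <- function(y, samples, zygosity) {
  fams <- names(which(table(
    samples$family_id[samples$zygosity == zygosity]) == 2))
  i1 <- match(fams, samples$family_id)
  i2 <- which(duplicated(samples$family_id))
  i2 <- i2[match(fams, samples$family_id[i2])]
  cor(y[i1], y[i2])
}

# dense-matrix multivariate-normal log-likelihood oracle for the
# twin-block model at given correlations (ML) or its REML analogue
dense_twin_loglik <- function(y, X, samples, r_mz, r_dz, sigma2,
                              reml = FALSE) {
  n <- length(y)
  p <- ncol(X)
  R <- diag(n)
  for (fam in unique(samples$family_id)) {
    idx <- which(samples$family_id == fam)
    if (length(idx) == 2) {
      r <- if (samples$zygosity[idx[1]] == "MZ") r_mz else r_dz
      R[idx[1], idx[2]] <- R[idx[2], idx[1]] <- r
    }
  }
  V <- sigma2 * R
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  e <- y - X %*% beta
  quad <- as.numeric(t(e) %*% Vi %*% e)
  ldV <- determinant(V, logarithm = TRUE)$modulus
  if (!reml)
    return(-0.5 * (n * log(2 * pi) + as.numeric(ldV) + quad))
  ldX <- determinant(t(X) %*% Vi %*% X, logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(2 * pi) + as.numeric(ldV) + as.numeric(ldX) + quad)
}
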