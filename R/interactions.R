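# interaction lm on a 4-column design [1, partner, age, partner*age];
# returns coefficients for partner / age / interaction, plus interaction
# se, t, p
interaction_fit <- function(y, partner, age) {
  D <- cbind(1, partner, age, partner * age)
  f <- stats::.lm.fit(D, y)
  df <- length(y) - 4L
  s2 <- sum(f$residuals^2) / df
  XtXi <- tryCatch(chol2inv(chol(crossprod(D))), error = function(e) NULL)
  if (is.null(XtXi)) return(NULL)
  se3 <- sqrt(s2 * XtXi[4, 4])
  b <- f$coefficients
  t3 <- b[4] / se3
  c(beta_main = b[2], beta_age = b[3], beta_interaction = b[4],
    se = se3, t = t3, p = 2 * stats::pt(abs(t3), df, lower.tail = FALSE))
}

#' Cis genotype-by-age interaction scan
#'
#' For each feature, tests every cis variant (within `window` bp of the
#' gene's TSS, boundary included, and with MAF >= `maf_min`) for a
#' genotype-by-age interaction on expression:
#' \eqn{y = \beta_0 + \beta_1 g + \beta_2 age + \beta_3 g \cdot age},
#' where `y` are expression residuals with technical covariates and
#' family structure removed.  \eqn{\beta_3} and its two-sided p-value are
#' reported per (feature, variant) pair.
#'
#' @param residuals residual matrix with technical covariates and family
#'   structure removed (see [twin_conditional_residuals()]), features x
#'   samples.
#' @param geno a [genotype_matrix()] with columns matching the samples.
#' @param samples sample table aligned with the columns of `residuals`.
#' @param annotation feature annotation with `feature_id`, `gene_id`,
#'   `chrom`, `tss`.
#' @param eligible optional character vector of feature ids to scan
#'   (e.g. features with age-related mean, variance or discordance
#'   effects); `NULL` scans everything.
#' @param window cis half-width around the TSS in bp (default 1e6, i.e.
#'   TSS +/- 1 Mb).
#' @param maf_min minimum minor allele frequency (default 0.05; variants
#'   below are excluded).
#' @return data.frame with one row per tested (feature, variant) pair:
#'   effect estimates, interaction p, `maf`.  Monomorphic variants are
#'   skipped and counted in `attr(, "n_skipped")`.
#' @export
gxage_scan <- function(residuals, geno, samples, annotation,
                       eligible = NULL, window = 1e6, maf_min = 0.05) {
  age <- samples$age
  if (length(unique(age)) < 2L)
    stop_validation("age is constant; the interaction term is undefined")
  ann <- annotation[match(rownames(residuals), annotation$feature_id), ,
                    drop = FALSE]
  if (!is.null(eligible)) {
    keep <- rownames(residuals) %in% eligible
    residuals <- residuals[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]
  }
  dos <- geno$dosages[, samples$sample_id, drop = FALSE]
  vann <- geno$annotation
  p_hat <- rowMeans(dos) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  rows <- list()
  n_skipped <- 0L
  for (f in seq_len(nrow(residuals))) {
    tss <- ann$tss[f]
    cand <- which(vann$chrom == ann$chrom[f] &
                    abs((vann$pos - 1L) - tss) <= window &
                    maf >= maf_min)
    for (v in cand) {
      g <- dos[v, ]
      if (sd(g) == 0) { n_skipped <- n_skipped + 1L; next }
      r <- interaction_fit(residuals[f, ], g, age)
      if (is.null(r)) { n_skipped <- n_skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = ann$feature_id[f], gene_id = ann$gene_id[f],
        variant_id = vann$variant_id[v], maf = maf[v],
        beta_main = unname(r["beta_main"]),
        beta_age = unname(r["beta_age"]),
        beta_interaction = unname(r["beta_interaction"]),
        se = unname(r["se"]), p = unname(r["p"]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(), gene_id = character(),
               variant_id = character(), maf = numeric(),
               beta_main = numeric(), beta_age = numeric(),
               beta_interaction = numeric(), se = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Residual-permutation adjustment for the GxAge scan
#'
#' For each tested (feature, variant) pair, the main-effects model
#' \eqn{y = \beta_0 + \beta_1 g + \beta_2 age} is fitted and its
#' residuals permuted `n_perm` times; each permuted residual vector is
#' refitted with the full interaction model and the interaction p-values
#' collected.  Per feature, the observed statistic is the smallest
#' interaction p across its cis variants; null statistics (per
#' permutation, minimum across the same variants) are pooled within
#' exon-count strata with +1 smoothing.  Benjamini-Hochberg FDR across
#' features on the adjusted p-values gives the final call at `fdr`.
#'
#' @param scan data.frame from [gxage_scan()].
#' @param residuals,geno,samples as passed to [gxage_scan()].
#' @param exons_per_gene named integer vector (gene_id -> exon count)
#'   used for stratification.
#' @param n_perm residual permutations (default 10).  The same `n_perm`
#'   twin-pair-preserving index permutations ([permute_pair_blocks()])
#'   are applied to every (feature, variant) pair: sharing permutations
#'   preserves the dependence between tests of one feature or gene, and
#'   moving pairs as blocks preserves the within-pair dependence of the
#'   residuals, keeping the empirical null calibrated in twin cohorts.
#' @param n_strata exon-count strata (default 16).
#' @param fdr false discovery rate for the final call (default 0.05).
#' @param seed RNG seed.
#' @return list with `features` (per feature: best nominal interaction p
#'   `p_min`, best `variant_id`, `p_adjusted`, `fdr` across features,
#'   `significant`), `genes` (same rollup with the minimum over the
#'   gene's feature-variant pairs), and `null_pvalues` (all pooled null
#'   interaction p-values).
#' @export
gxage_adjust <- function(scan, residuals, geno, samples, exons_per_gene,
                         n_perm = 10, n_strata = 16, fdr = 0.05,
                         seed = 1) {
  empty <- data.frame(feature_id = character(), gene_id = character(),
                      variant_id = character(), p_min = numeric(),
                      p_adjusted = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (nrow(scan) == 0L)
    return(list(features = empty, genes = empty,
                null_pvalues = numeric(0)))
  age <- samples$age
  n <- length(age)
  dos <- geno$dosages[, samples$sample_id, drop = FALSE]
  feats <- unique(scan$feature_id)

  # null interaction p-values per scanned pair, one column per shared
  # sample-index permutation
  null_pair <- matrix(NA_real_, nrow(scan), n_perm)
  with_local_seed(seed, {
    perms <- replicate(n_perm, permute_pair_blocks(samples))
    for (k in seq_len(nrow(scan))) {
      y <- residuals[scan$feature_id[k], ]
      g <- dos[scan$variant_id[k], ]
      Dm <- cbind(1, g, age)
      r0 <- stats::.lm.fit(Dm, y)$residuals
      Df <- cbind(1, g, age, g * age)
      XtXi <- chol2inv(chol(crossprod(Df)))
      H <- XtXi %*% t(Df)
      dfree <- n - 4L
      P <- matrix(r0[perms], n, n_perm)
      B <- H %*% P                          # 4 x n_perm coefficients
      R <- P - Df %*% B
      s2 <- colSums(R^2) / dfree
      t3 <- B[4, ] / sqrt(s2 * XtXi[4, 4])
      null_pair[k, ] <- 2 * stats::pt(abs(t3), dfree, lower.tail = FALSE)
    }
  })

  rollup <- function(group) {
    ids <- unique(group)
    obs <- vapply(ids, function(i) min(scan$p[group == i]), numeric(1))
    nul <- t(vapply(ids, function(i)
      apply(null_pair[group == i, , drop = FALSE], 2, min),
      numeric(n_perm)))
    gene_of <- scan$gene_id[match(ids, group)]
    strata <- assign_exon_strata(
      as.integer(exons_per_gene[gene_of]), n_strata)
    p_adj <- adjust_empirical(-log(obs), -log(nul), strata)
    best <- vapply(ids, function(i) {
      sub <- which(group == i)
      scan$variant_id[sub[which.min(scan$p[sub])]]
    }, character(1))
    out <- data.frame(feature_id = ids, gene_id = gene_of,
                      variant_id = best, p_min = obs, p_adjusted = p_adj,
                      fdr = p.adjust(p_adj, "BH"),
                      stringsAsFactors = FALSE)
    out$significant <- out$fdr < fdr
    out
  }

  features <- rollup(scan$feature_id)
  genes <- rollup(scan$gene_id)
  names(genes)[1] <- "id"
  list(features = features, genes = genes,
       null_pvalues = as.numeric(null_pair))
}

#' Methylation-by-age interaction test on expression
#'
#' For each (feature, probe) pair with the probe mapped to the feature's
#' gene, fits \eqn{y = \beta_0 + \beta_1 m + \beta_2 age +
#' \beta_3 m \cdot age} on residualized expression and methylation, and
#' calls the interaction significant when its p-value is strictly below
#' `p_threshold` (a Bonferroni-style fixed threshold, default 1e-4).
#'
#' @param expr_residuals expression residual matrix (technical
#'   covariates and family structure removed), features x samples.
#' @param meth_residuals methylation residual matrix (same removal),
#'   probes x samples, columns aligned with expression.
#' @param ages numeric ages per sample.
#' @param feature_genes named character vector feature_id -> gene_id.
#' @param probe_genes named character vector probe_id -> gene_id.
#' @param genes optional gene subset (e.g. genes with an age-variance
#'   signal at a prescreen threshold); `NULL` tests all shared genes.
#' @param p_threshold strict significance cutoff on the interaction p.
#' @return data.frame with one row per tested pair: `beta_meth`,
#'   `beta_age`, `beta_interaction`, `p`, `significant`.  Probes with
#'   zero variance are skipped.
#' @export
meth_age_test <- function(expr_residuals, meth_residuals, ages,
                          feature_genes, probe_genes, genes = NULL,
                          p_threshold = 1e-4) {
  if (is.null(genes))
    genes <- intersect(unique(feature_genes), unique(probe_genes))
  rows <- list()
  for (f in rownames(expr_residuals)) {
    g <- feature_genes[[f]]
    if (is.null(g) || !(g %in% genes)) next
    for (pr in names(probe_genes)[probe_genes == g]) {
      if (!(pr %in% rownames(meth_residuals))) next
      m <- meth_residuals[pr, ]
      if (sd(m) == 0) next
      r <- interaction_fit(expr_residuals[f, ], m, ages)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = f, gene_id = g, probe_id = pr,
        beta_meth = unname(r["beta_main"]),
        beta_age = unname(r["beta_age"]),
        beta_interaction = unname(r["beta_interaction"]),
        p = unname(r["p"]),
        significant = unname(r["p"]) < p_threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(feature_id = character(), gene_id = character(),
                      probe_id = character(), beta_meth = numeric(),
                      beta_age = numeric(), beta_interaction = numeric(),
                      p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
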