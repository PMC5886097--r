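#' Residuals for the variance-with-age analysis
#'
#' Removes the technical covariates (but not age) from each feature with
#' the familial covariance accounted for: a REML twin-block fit per
#' feature, returning the marginal residuals (response minus GLS fixed
#' effects).  Family structure is modelled in the fit — and handled in
#' the permutation null by moving twin pairs as units — but the
#' pair-shared component is deliberately not subtracted from the
#' residual values: subtracting its BLUP would cancel exactly the
#' pair-shared dispersion changes this analysis is designed to detect,
#' and would leave residuals with strong negative within-pair
#' correlation.
#'
#' @param values rank-normalized expression, features x samples.
#' @param samples sample table aligned with the columns.
#' @param fixed technical fixed-effect columns (age must not be listed).
#' @return Residual matrix, features x samples.
#' @export
residualize_for_variance <- function(values, samples,
                                     fixed = c("insert_size", "gc_mean")) {
  if ("age" %in% fixed)
    stop_validation("age must not be removed before the variance test")
  X <- build_design(samples, fixed)
  twin_marginal_residuals(values, X, samples)
}

#' LOESS-based test for age-dependent expression variance
#'
#' A LOESS curve of the expression residuals on age absorbs any smooth
#' age trend in the mean; the square root of the absolute LOESS residuals
#' is a variance-stabilized distance from the age trend, and its Spearman
#' correlation with age measures whether dispersion changes with age.
#'
#' @param residuals numeric vector of expression residuals (technical
#'   covariates and family structure removed).
#' @param age numeric ages; at least 30 samples and 10 distinct ages.
#' @param span,degree LOESS parameters (defaults 0.75 and 2).
#' @return list with `rho` (Spearman correlation of distance with age),
#'   `p` (two-sided), `direction` ("increasing" or "decreasing").
#' @export
variance_age_test <- function(residuals, age, span = 0.75, degree = 2) {
  if (length(residuals) != length(age))
    stop_validation("residuals and age differ in length")
  if (length(residuals) < 30)
    stop_validation("variance test needs at least 30 samples")
  if (length(unique(age)) < 10)
    stop_validation("variance test needs at least 10 distinct ages")
  d <- variance_distance(residuals, age, span, degree)
  if (sd(d) == 0)
    return(list(rho = 0, p = 1, direction = "increasing"))
  ct <- suppressWarnings(cor.test(d, age, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value,
       direction = if (ct$estimate < 0) "decreasing" else "increasing")
}

variance_distance <- function(residuals, age, span = 0.75, degree = 2) {
  fit <- tryCatch(
    loess(residuals ~ age, span = span, degree = degree,
          family = "gaussian"),
    error = function(e)
      stop_validation("LOESS failed at span %.3g: %s", span,
                      conditionMessage(e)))
  sqrt(abs(resid(fit)))
}

#' Age effect on expression variance across all features, with
#' permutation adjustment
#'
#' Applies [variance_age_test()] per feature; the gene-level statistic is
#' the maximum |rho| over the gene's features.  Ages are permuted
#' preserving twin pairs and the full LOESS + Spearman statistic is
#' recomputed per permutation; nulls are pooled within exon-count strata
#' with +1 smoothing as in [age_mean_scan()].
#'
#' @param residuals residual matrix from [residualize_for_variance()],
#'   features x samples.
#' @param samples sample table aligned with the columns.
#' @param annotation feature annotation (feature_id, gene_id).
#' @param span,degree LOESS parameters.
#' @param n_perm,n_strata,alpha,seed as in [age_mean_scan()].
#' @return A `variance_scan` list with `features`, `genes`, `settings`.
#' @export
age_variance_scan <- function(residuals, samples, annotation,
                              span = 0.75, degree = 2, n_perm = 100,
                              n_strata = 16, alpha = 0.05, seed = 1) {
  ann <- annotation[match(rownames(residuals), annotation$feature_id), ,
                    drop = FALSE]
  if (anyNA(ann$feature_id))
    stop_validation("features missing from annotation")
  age <- samples$age
  F_ <- nrow(residuals)

  one_pass <- function(a) {
    vapply(seq_len(F_), function(f) {
      d <- variance_distance(residuals[f, ], a, span, degree)
      if (sd(d) == 0) return(c(0, 1))
      ct <- suppressWarnings(cor.test(d, a, method = "spearman",
                                      exact = FALSE))
      c(unname(ct$estimate), ct$p.value)
    }, numeric(2))
  }

  obs <- one_pass(age)
  rho <- obs[1, ]
  p_nom <- obs[2, ]

  genes <- unique(ann$gene_id)
  gidx <- match(ann$gene_id, genes)
  n_exons <- as.integer(table(gidx))
  strata_g <- assign_exon_strata(n_exons, n_strata)
  obs_gene <- gene_max_stat(abs(rho), ann$gene_id)

  null_gene <- matrix(NA_real_, length(genes), n_perm)
  null_feat <- matrix(NA_real_, F_, n_perm)
  with_local_seed(seed, {
    for (b in seq_len(n_perm)) {
      st <- abs(one_pass(permute_pairs(samples))[1, ])
      null_feat[, b] <- st
      null_gene[, b] <- gene_max_stat(st, ann$gene_id)
    }
  })

  p_adj_gene <- adjust_empirical(obs_gene, null_gene, strata_g)
  p_adj_feat <- adjust_empirical(abs(rho), null_feat, strata_g[gidx])

  genes_df <- data.frame(gene_id = genes, n_exons = n_exons,
                         stratum = strata_g, stat = unname(obs_gene),
                         p_adjusted = p_adj_gene,
                         significant = p_adj_gene < alpha,
                         stringsAsFactors = FALSE)
  feats_df <- data.frame(feature_id = ann$feature_id,
                         gene_id = ann$gene_id, spearman_rho = rho,
                         p_nominal = p_nom, p_adjusted = p_adj_feat,
                         direction = ifelse(rho < 0, "decreasing",
                                            "increasing"),
                         significant = genes_df$significant[gidx],
                         stringsAsFactors = FALSE)
  structure(list(features = feats_df, genes = genes_df,
                 settings = list(span = span, degree = degree,
                                 n_perm = n_perm, n_strata = n_strata,
                                 alpha = alpha, seed = seed)),
            class = "variance_scan")
}

#' @export
print.variance_scan <- function(x, ...) {
  sig <- x$features[x$features$p_adjusted < x$settings$alpha, ]
  cat(sprintf(
    "<variance_scan> %d features / %d genes; %d genes significant\n",
    nrow(x$features), nrow(x$genes), sum(x$genes$significant)))
  cat(sprintf("  significant features: %d increasing, %d decreasing\n",
              sum(sig$direction == "increasing"),
              sum(sig$direction == "decreasing")))
  invisible(x)
}
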