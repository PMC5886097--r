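#' Likelihood-ratio test of an age effect on one feature's mean expression
#'
#' Fits the twin-block mixed model with and without age among the fixed
#' effects (both by ML) and compares them by likelihood ratio against
#' \eqn{\chi^2_1}.
#'
#' @param y rank-normalized feature values, one per sample.
#' @param samples sample table aligned with `y`.
#' @param fixed character vector of technical fixed-effect columns.
#' @return list with `beta_age` (signed age coefficient), `statistic`,
#'   `p`.
#' @export
test_feature_age <- function(y, samples, fixed = c("insert_size",
                                                   "gc_mean")) {
  Xr <- build_design(samples, fixed)
  Xf <- cbind(Xr, age = samples$age)
  full <- fit_twin_lmm(y, Xf, samples, method = "ML")
  red <- fit_twin_lmm(y, Xr, samples, method = "ML")
  lrt <- lrt_nested(full, red)
  list(beta_age = unname(full$beta["age"]), statistic = lrt$statistic,
       p = lrt$p)
}

#' Age effect on mean expression across all features, with permutation
#' adjustment
#'
#' Per feature, an ML likelihood-ratio test of age in the twin-block mixed
#' model (technical covariates fixed; family/zygosity covariance).  The
#' gene-level statistic is the maximum LRT over the gene's features.
#' Multiple testing is controlled empirically: ages are permuted
#' `n_perm` times preserving twin pairs, the gene-level maxima are
#' recomputed, and nulls are pooled within exon-count strata
#' ([assign_exon_strata()]) with +1 smoothing.  A gene is called
#' significant when its adjusted p-value is below `alpha`; features
#' inherit the call through their gene, and feature-level adjusted
#' p-values from the same pools are also reported.
#'
#' @param values rank-normalized expression, features x samples.
#' @param samples sample table aligned with the columns.
#' @param annotation feature annotation containing `feature_id`,
#'   `gene_id` (rows of `values` must all be present).
#' @param fixed technical fixed-effect columns.
#' @param n_perm number of pair-preserving permutations (default 100).
#' @param n_strata exon-count strata for the null pools (default 16).
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return An `age_scan` list: `features` (beta_age, lrt, p_nominal,
#'   p_adjusted, p_bh diagnostic, significant), `genes` (stat,
#'   p_adjusted, significant), `direction` (share of positive /
#'   negative age effects among significant features), `settings`.
#' @export
age_mean_scan <- function(values, samples, annotation,
                          fixed = c("insert_size", "gc_mean"),
                          n_perm = 100, n_strata = 16, alpha = 0.05,
                          seed = 1) {
  ann <- annotation[match(rownames(values), annotation$feature_id), ,
                    drop = FALSE]
  if (anyNA(ann$feature_id))
    stop_validation("features missing from annotation")
  Xr <- build_design(samples, fixed)
  Xf <- cbind(Xr, age = samples$age)
  bl <- twin_blocks(samples)
  Yt <- t(values[, bl$ord, drop = FALSE])
  Xr_o <- Xr[bl$ord, , drop = FALSE]
  Xf_o <- Xf[bl$ord, , drop = FALSE]

  obs <- cpp_lrt_scan(Yt, Xf_o, Xr_o, bl$first, bl$size, bl$zyg, 1e-8, 500L)
  lrt <- pmax(0, 2 * (obs[, 3] - obs[, 4]))
  p_nom <- pchisq(lrt, df = 1, lower.tail = FALSE)

  genes <- unique(ann$gene_id)
  gidx <- match(ann$gene_id, genes)
  n_exons <- as.integer(table(gidx))
  strata_g <- assign_exon_strata(n_exons, n_strata)
  obs_gene <- gene_max_stat(lrt, ann$gene_id)

  ll_red <- obs[, 4]
  null_gene <- matrix(NA_real_, length(genes), n_perm)
  null_feat <- matrix(NA_real_, nrow(values), n_perm)
  with_local_seed(seed, {
    for (b in seq_len(n_perm)) {
      age_b <- permute_pairs(samples)
      Xb <- Xf
      Xb[, "age"] <- age_b
      fb <- cpp_ml_loglik_scan(Yt, Xb[bl$ord, , drop = FALSE], bl$first,
                               bl$size, bl$zyg, 1e-8, 500L,
                               starts = obs[, 5:6, drop = FALSE])
      stat_b <- pmax(0, 2 * (fb[, 1] - ll_red))
      null_feat[, b] <- stat_b
      null_gene[, b] <- gene_max_stat(stat_b, ann$gene_id)
    }
  })

  p_adj_gene <- adjust_empirical(obs_gene, null_gene, strata_g)
  p_adj_feat <- adjust_empirical(lrt, null_feat, strata_g[gidx])

  genes_df <- data.frame(gene_id = genes, n_exons = n_exons,
                         stratum = strata_g, stat = unname(obs_gene),
                         p_adjusted = p_adj_gene,
                         significant = p_adj_gene < alpha,
                         stringsAsFactors = FALSE)
  feats_df <- data.frame(feature_id = ann$feature_id,
                         gene_id = ann$gene_id, beta_age = obs[, 1],
                         lrt = lrt, p_nominal = p_nom,
                         p_adjusted = p_adj_feat,
                         p_bh = p.adjust(p_nom, "BH"),
                         significant = genes_df$significant[gidx],
                         stringsAsFactors = FALSE)
  sig_beta <- feats_df$beta_age[feats_df$significant &
                                  feats_df$p_adjusted < alpha]
  structure(list(
    features = feats_df, genes = genes_df,
    direction = c(positive = sum(sig_beta > 0),
                  negative = sum(sig_beta < 0)),
    settings = list(fixed = fixed, n_perm = n_perm, n_strata = n_strata,
                    alpha = alpha, seed = seed)),
    class = "age_scan")
}

#' @export
print.age_scan <- function(x, ...) {
  cat(sprintf(
    "<age_scan> %d features / %d genes; %d genes significant at %.2g\n",
    nrow(x$features), nrow(x$genes), sum(x$genes$significant),
    x$settings$alpha))
  cat(sprintf("  direction among significant features: %d up, %d down\n",
              x$direction[["positive"]], x$direction[["negative"]]))
  invisible(x)
}
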