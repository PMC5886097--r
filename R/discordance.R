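#' Residuals removing technical covariates only
#'
#' Ordinary least-squares residuals on the technical fixed effects,
#' leaving family structure (and age) in place — the input for the MZ
#' discordance analysis, where the within-pair contrast itself carries
#' the signal.
#'
#' @param values rank-normalized expression, features x samples.
#' @param samples sample table aligned with the columns.
#' @param fixed technical fixed-effect columns.
#' @return Residual matrix, features x samples.
#' @export
residualize_technical <- function(values, samples,
                                  fixed = c("insert_size", "gc_mean")) {
  X <- build_design(samples, fixed)
  q <- qr(X)
  t(qr.resid(q, t(values)))
}

#' Per-pair (max, min) expression table for complete MZ pairs
#'
#' @param values residual matrix (technical covariates removed),
#'   features x samples.
#' @param samples sample table aligned with the columns.
#' @param min_pairs minimum number of complete MZ pairs (default 20).
#' @return A `pair_table` list: `family_id`, `age` (per pair),
#'   `expr_max` and `expr_min` (features x pairs matrices,
#'   `expr_max >= expr_min` elementwise).
#' @export
build_pairs <- function(values, samples, min_pairs = 20) {
  mz <- samples$zygosity == "MZ"
  tab <- table(samples$family_id[mz])
  fams <- names(tab)[tab == 2L]
  if (length(fams) == 0L)
    stop_validation("no complete MZ pairs in the cohort")
  if (length(fams) < min_pairs)
    stop_validation("fewer than %d complete MZ pairs (found %d)",
                    min_pairs, length(fams))
  i1 <- match(fams, samples$family_id)
  idx2 <- which(duplicated(samples$family_id))
  i2 <- idx2[match(fams, samples$family_id[idx2])]
  v1 <- values[, i1, drop = FALSE]
  v2 <- values[, i2, drop = FALSE]
  structure(list(family_id = fams, age = samples$age[i1],
                 expr_max = pmax(v1, v2), expr_min = pmin(v1, v2)),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("<pair_table> %d features x %d complete MZ pairs\n",
              nrow(x$expr_max), length(x$family_id)))
  invisible(x)
}

# gamma (age) coefficient and |t| for
#   expr_max ~ expr_min + age + expr_min:age
# The expr_min:age interaction absorbs age-dependent changes in the
# max-on-min slope, which arise when a PAIR-SHARED component changes
# variance with age; without it those shifts leak into gamma and the
# test loses its ability to isolate non-shared (discordance) effects.
# The t-statistic uses an HC3 heteroscedasticity-robust standard error:
# pair-shared variance trends make the regression residual variance a
# function of age, which would otherwise overdisperse gamma-hat relative
# to both the homoscedastic t reference and the age-permutation null.
disc_fit_one <- function(mx, mn, age) {
  D <- cbind(1, mn, age, mn * age)
  f <- stats::.lm.fit(D, mx)
  e <- f$residuals
  df <- length(mx) - 4L
  s2 <- sum(e^2) / df
  if (s2 < 1e-24)  # exact fit (e.g. perfectly concordant pairs)
    return(c(gamma = f$coefficients[3], t = 0, p = 1))
  XtXi <- chol2inv(chol(crossprod(D)))
  H <- D %*% XtXi
  h <- rowSums(H * D)
  u <- e / pmax(1 - h, 1e-8)
  V <- XtXi %*% crossprod(D * u) %*% XtXi    # HC3 sandwich
  se <- sqrt(V[3, 3])
  g <- f$coefficients[3]
  c(gamma = g, t = g / se,
    p = 2 * stats::pt(abs(g / se), df, lower.tail = FALSE))
}

#' Test whether MZ-pair discordance in expression changes with age
#'
#' For one feature, regresses the larger co-twin value on the smaller
#' plus age (`expr_max ~ expr_min + age + expr_min:age`); the age
#' coefficient \eqn{\gamma} measures whether the max/min relationship is
#' conditional on age, i.e. whether co-twins diverge (or converge) as
#' they grow older.  The `expr_min:age` term absorbs slope changes
#' caused by pair-shared variance trends, so \eqn{\gamma} responds to
#' non-shared divergence only.  Since MZ co-twins share genome and age,
#' a nonzero \eqn{\gamma} points to non-shared environmental effects.
#'
#' @param pairs a `pair_table` from [build_pairs()].
#' @param feature feature id (row) to test; default first row.
#' @return list with `gamma_age`, `t`, `p` (two-sided t-test).
#' @export
discordance_age_test <- function(pairs, feature = 1L) {
  mx <- pairs$expr_max[feature, ]
  mn <- pairs$expr_min[feature, ]
  if (sd(mn) == 0)
    stop_validation("expr_min constant across pairs")
  r <- disc_fit_one(mx, mn, pairs$age)
  list(gamma_age = unname(r["gamma"]), t = unname(r["t"]),
       p = unname(r["p"]))
}

#' Age effect on MZ discordance across all features, with permutation
#' adjustment
#'
#' Applies the max-on-min-plus-age regression per feature; the gene-level
#' statistic is the maximum |t| of the age coefficient over the gene's
#' features.  Pair ages are permuted across pairs (pairs are indivisible
#' units) and nulls pooled within exon-count strata as in
#' [age_mean_scan()].
#'
#' @param values residual matrix from [residualize_technical()].
#' @param samples sample table aligned with the columns.
#' @param annotation feature annotation (feature_id, gene_id).
#' @param min_pairs minimum complete MZ pairs.
#' @param n_perm,n_strata,alpha,seed as in [age_mean_scan()].
#' @return A `discordance_scan` list with `features`, `genes`,
#'   `settings`.
#' @export
discordance_scan <- function(values, samples, annotation, min_pairs = 20,
                             n_perm = 100, n_strata = 16, alpha = 0.05,
                             seed = 1) {
  ann <- annotation[match(rownames(values), annotation$feature_id), ,
                    drop = FALSE]
  pairs <- build_pairs(values, samples, min_pairs = min_pairs)
  F_ <- nrow(values)

  one_pass <- function(age) {
    vapply(seq_len(F_), function(f)
      disc_fit_one(pairs$expr_max[f, ], pairs$expr_min[f, ], age),
      numeric(3))
  }
  obs <- one_pass(pairs$age)

  genes <- unique(ann$gene_id)
  gidx <- match(ann$gene_id, genes)
  n_exons <- as.integer(table(gidx))
  strata_g <- assign_exon_strata(n_exons, n_strata)
  obs_gene <- gene_max_stat(abs(obs["t", ]), ann$gene_id)

  null_gene <- matrix(NA_real_, length(genes), n_perm)
  null_feat <- matrix(NA_real_, F_, n_perm)
  with_local_seed(seed, {
    for (b in seq_len(n_perm)) {
      st <- abs(one_pass(sample(pairs$age))["t", ])
      null_feat[, b] <- st
      null_gene[, b] <- gene_max_stat(st, ann$gene_id)
    }
  })

  p_adj_gene <- adjust_empirical(obs_gene, null_gene, strata_g)
  p_adj_feat <- adjust_empirical(abs(obs["t", ]), null_feat,
                                 strata_g[gidx])

  genes_df <- data.frame(gene_id = genes, n_exons = n_exons,
                         stratum = strata_g, stat = unname(obs_gene),
                         p_adjusted = p_adj_gene,
                         significant = p_adj_gene < alpha,
                         stringsAsFactors = FALSE)
  feats_df <- data.frame(feature_id = ann$feature_id,
                         gene_id = ann$gene_id,
                         gamma_age = obs["gamma", ], t = obs["t", ],
                         p_nominal = obs["p", ],
                         p_adjusted = p_adj_feat,
                         significant = genes_df$significant[gidx],
                         stringsAsFactors = FALSE)
  structure(list(features = feats_df, genes = genes_df,
                 n_pairs = length(pairs$family_id),
                 settings = list(n_perm = n_perm, n_strata = n_strata,
                                 alpha = alpha, seed = seed)),
            class = "discordance_scan")
}

#' @export
print.discordance_scan <- function(x, ...) {
  cat(sprintf(
    "<discordance_scan> %d features / %d genes over %d MZ pairs; %d genes significant\n",
    nrow(x$features), nrow(x$genes), x$n_pairs,
    sum(x$genes$significant)))
  invisible(x)
}
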