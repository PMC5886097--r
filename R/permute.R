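#' Twin-pair-preserving permutation of ages
#'
#' Permutes the age (and any other person-level label under test) across
#' family units while keeping co-twins together: complete pairs exchange
#' ages only with other pairs, singletons only with singletons.  After
#' permutation co-twins still share their family id and have equal ages.
#' Sample-attached technical covariates stay with their expression values.
#'
#' @param samples sample table.
#' @param seed integer seed; the same seed yields the same assignment.
#'   `NULL` uses the current RNG stream.
#' @return Numeric vector of permuted ages aligned with the rows of
#'   `samples`.
#' @export
permute_pairs <- function(samples, seed = NULL) {
  with_local_seed(seed, {
    fam <- samples$family_id
    units <- unique(fam)
    first <- match(units, fam)
    usize <- as.integer(table(fam)[units])
    uage <- samples$age[first]
    new_age <- uage
    pairs <- which(usize == 2L)
    singles <- which(usize == 1L)
    if (length(pairs) > 1L) new_age[pairs] <- uage[sample(pairs)]
    if (length(singles) > 1L) new_age[singles] <- uage[sample(singles)]
    new_age[match(fam, units)]
  })
}

#' Twin-pair-preserving permutation of sample indices
#'
#' Returns an index vector `idx` such that `x[idx]` moves complete family
#' pairs onto other pair slots and singletons onto singleton slots,
#' keeping co-twin values adjacent to each other.  Used to permute
#' residual vectors without destroying their within-pair dependence.
#'
#' @param samples sample table.
#' @param seed integer seed or `NULL` for the current stream.
#' @return Integer permutation of `seq_len(nrow(samples))`.
#' @export
permute_pair_blocks <- function(samples, seed = NULL) {
  with_local_seed(seed, {
    fam <- samples$family_id
    units <- unique(fam)
    usize <- as.integer(table(fam)[units])
    members <- split(seq_along(fam), match(fam, units))
    idx <- integer(length(fam))
    for (sz in unique(usize)) {
      slots <- which(usize == sz)
      from <- if (length(slots) > 1L) slots[sample.int(length(slots))]
      else slots
      idx[unlist(members[slots])] <- unlist(members[from])
    }
    idx
  })
}

#' Assign genes to exon-count strata
#'
#' Partitions genes into (up to) `n_strata` groups of similar exon count
#' using quantile bins; duplicate quantile boundaries (many genes sharing
#' an exon count) merge bins, so every stratum is non-empty and every gene
#' falls in exactly one stratum.
#'
#' @param n_exons integer vector, exons per gene.
#' @param n_strata target number of strata (default 16).
#' @return Integer vector of stratum ids (1-based), same length as
#'   `n_exons`.
#' @export
assign_exon_strata <- function(n_exons, n_strata = 16) {
  br <- unique(quantile(n_exons, probs = seq(0, 1, length.out =
                                               n_strata + 1)))
  if (length(br) < 2L) return(rep(1L, length(n_exons)))
  as.integer(cut(n_exons, breaks = br, include.lowest = TRUE))
}

#' Stratified empirical p-values from a permutation null
#'
#' For each gene, the adjusted p-value is the +1-smoothed proportion of
#' pooled null statistics at least as large as the observed statistic,
#' pooling across all genes of the gene's exon-count stratum and across
#' all permutations:
#' \eqn{p_{adj} = (1 + \#\{null \ge obs\}) / (1 + pool size)}.
#'
#' @param obs numeric vector of observed statistics (larger = more
#'   significant), one per gene/feature.
#' @param null_mat matrix of null statistics, rows aligned with `obs`,
#'   one column per permutation.
#' @param strata integer stratum per row (from [assign_exon_strata()]);
#'   `NULL` pools everything.
#' @return Numeric vector of adjusted p-values in (0, 1].
#' @export
adjust_empirical <- function(obs, null_mat, strata = NULL) {
  null_mat <- as.matrix(null_mat)
  if (nrow(null_mat) != length(obs))
    stop_validation("null matrix rows do not match observed statistics")
  if (is.null(strata)) strata <- rep(1L, length(obs))
  adj <- rep(NA_real_, length(obs))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    pool <- sort(as.numeric(null_mat[idx, , drop = FALSE]))
    pool <- pool[!is.na(pool)]
    n_ge <- length(pool) - findInterval(obs[idx], pool, left.open = TRUE)
    adj[idx] <- (1 + n_ge) / (1 + length(pool))
  }
  adj
}

#' Collapse feature-level statistics to gene level by maximum
#'
#' @param stat numeric vector of per-feature statistics.
#' @param gene_id gene id per feature.
#' @return Named numeric vector, max statistic per gene (NA-features
#'   ignored; all-NA genes give NA).
#' @export
gene_max_stat <- function(stat, gene_id) {
  out <- tapply(stat, gene_id, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  as.numeric(out)[match(unique(gene_id), names(out))] |>
    setNames(unique(gene_id))
}
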