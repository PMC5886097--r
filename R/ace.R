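#' ACE(+age) variance decomposition for one feature
#'
#' Decomposes the variance of an expression phenotype measured on twins
#' into additive-genetic (A), common-environment (C) and unique-environment
#' (E) components using the classical MZ/DZ covariance contrast, with age
#' as a fixed effect.  The model is fitted by REML over block-diagonal
#' family covariance: within-MZ-pair covariance \eqn{\sigma^2_A +
#' \sigma^2_C}, within-DZ \eqn{\sigma^2_A/2 + \sigma^2_C}, total
#' \eqn{\sigma^2_A + \sigma^2_C + \sigma^2_E}.  Components are constrained
#' non-negative: when the unconstrained optimum implies a negative A or C,
#' the model is refitted on the corresponding boundary (equal correlations
#' for A = 0; half-ratio DZ correlation for C = 0).  The age variance is
#' \eqn{\sigma^2_{age} = \hat\beta^2_{age} \mathrm{Var}(age)} so that all
#' components share one scale; `h2` and `pve_age` are the A and age shares
#' of the total.
#'
#' @param y numeric phenotype (typically residualized, rank-normalized
#'   expression), one value per sample.
#' @param samples sample table aligned with `y`; must contain complete MZ
#'   and DZ pairs (A and C are not identifiable from a single zygosity).
#' @param min_pairs minimum number of complete pairs (default 20; fewer is
#'   an error).
#' @return A `variance_components` list: `sigma2_A`, `sigma2_C`,
#'   `sigma2_E`, `sigma2_age`, `h2`, `pve_age`, `beta_age`, `r_mz`,
#'   `r_dz`, `boundary` ("none", "A0" or "C0").
#' @export
fit_ace <- function(y, samples, min_pairs = 20) {
  tab <- table(samples$family_id)
  pair_fams <- names(tab)[tab == 2L]
  zyg_of_pair <- samples$zygosity[match(pair_fams, samples$family_id)]
  n_mz <- sum(zyg_of_pair == "MZ")
  n_dz <- sum(zyg_of_pair == "DZ")
  if (n_mz == 0L || n_dz == 0L)
    stop_validation(paste("ACE decomposition needs both MZ and DZ pairs;",
                          "found %d MZ and %d DZ"), n_mz, n_dz)
  if (n_mz + n_dz < min_pairs)
    stop_validation("fewer than %d complete twin pairs", min_pairs)
  if (anyNA(samples$age)) stop_validation("missing ages")

  X <- cbind("(Intercept)" = 1, age = samples$age)
  fit <- fit_twin_lmm(y, X, samples, method = "REML", mode = "free")
  boundary <- "none"
  if (fit$r_dz > fit$r_mz) {          # negative A: equal-correlation limit
    fit <- fit_twin_lmm(y, X, samples, method = "REML", mode = "equal")
    boundary <- "A0"
  } else if (fit$r_dz < fit$r_mz / 2) {  # negative C
    fit <- fit_twin_lmm(y, X, samples, method = "REML", mode = "no_common")
    boundary <- "C0"
  }
  s2 <- fit$sigma2
  sigma2_A <- max(0, 2 * (fit$r_mz - fit$r_dz) * s2)
  sigma2_C <- max(0, (2 * fit$r_dz - fit$r_mz) * s2)
  sigma2_E <- max(0, (1 - fit$r_mz) * s2)
  beta_age <- unname(fit$beta["age"])
  sigma2_age <- beta_age^2 * var(samples$age)
  total <- sigma2_A + sigma2_C + sigma2_E + sigma2_age
  structure(list(sigma2_A = sigma2_A, sigma2_C = sigma2_C,
                 sigma2_E = sigma2_E, sigma2_age = sigma2_age,
                 h2 = sigma2_A / total, pve_age = sigma2_age / total,
                 beta_age = beta_age, r_mz = fit$r_mz, r_dz = fit$r_dz,
                 n_mz_pairs = n_mz, n_dz_pairs = n_dz,
                 boundary = boundary, loglik = fit$loglik),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> A = %.4f, C = %.4f, E = %.4f, age = %.4f\n",
    x$sigma2_A, x$sigma2_C, x$sigma2_E, x$sigma2_age))
  cat(sprintf("  h2 = %.3f, pve_age = %.3f (%d MZ + %d DZ pairs%s)\n",
              x$h2, x$pve_age, x$n_mz_pairs, x$n_dz_pairs,
              if (x$boundary == "none") "" else
                paste0(", boundary ", x$boundary)))
  invisible(x)
}

#' ACE(+age) decomposition for every feature of a residual matrix
#'
#' @param values features x samples matrix (e.g. rank-normalized
#'   expression residualized for technical covariates).
#' @param samples sample table aligned with the columns.
#' @param min_pairs passed to [fit_ace()].
#' @return data.frame with one row per feature: the variance components,
#'   `h2` and `pve_age`.
#' @export
ace_scan <- function(values, samples, min_pairs = 20) {
  res <- lapply(rownames(values), function(f) {
    vc <- fit_ace(values[f, ], samples, min_pairs = min_pairs)
    data.frame(feature_id = f, sigma2_A = vc$sigma2_A,
               sigma2_C = vc$sigma2_C, sigma2_E = vc$sigma2_E,
               sigma2_age = vc$sigma2_age, h2 = vc$h2,
               pve_age = vc$pve_age, beta_age = vc$beta_age,
               boundary = vc$boundary, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
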