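#' Replication p-values for features discovered in another tissue
#'
#' Extracts the nominal p-values, in a replication tissue, of the
#' features significantly associated with age in a discovery tissue.
#' The distribution of these p-values measures how much of the
#' discovery-tissue age signal is shared.
#'
#' @param discovery an `age_scan` (or any result with a `features`
#'   data.frame carrying `feature_id`, `p_adjusted`) for the discovery
#'   tissue.
#' @param replication the corresponding result for the replication
#'   tissue (needs `feature_id`, `p_nominal`).
#' @param alpha adjusted-p threshold defining discovery hits.
#' @return Numeric vector of replication p-values, with attribute
#'   `n_dropped` counting discovery hits absent from the replication
#'   results.
#' @export
crosstissue_pvalues <- function(discovery, replication, alpha = 0.05) {
  dfeat <- discovery$features
  rfeat <- replication$features
  if (!length(intersect(dfeat$feature_id, rfeat$feature_id)))
    stop_validation("no features shared between discovery and replication")
  hits <- dfeat$feature_id[dfeat$p_adjusted < alpha]
  if (!length(hits))
    stop_validation("no significant features in the discovery tissue")
  idx <- match(hits, rfeat$feature_id)
  p <- rfeat$p_nominal[idx[!is.na(idx)]]
  attr(p, "n_dropped") <- sum(is.na(idx))
  p
}

#' Storey estimate of the proportion of true alternatives (pi1)
#'
#' Estimates \eqn{\pi_0(\lambda) = \#\{p > \lambda\} / (n (1 -
#' \lambda))} over a grid of \eqn{\lambda}, smooths with a cubic
#' smoothing spline (df = 3) and evaluates at the largest \eqn{\lambda}
#' ("smoother" method), or picks \eqn{\lambda} by minimising a bootstrap
#' mean-squared-error estimate ("bootstrap").  \eqn{\pi_1 = 1 - \pi_0},
#' clipped to \[0, 1\].
#'
#' @param pvalues numeric p-values in \[0, 1\], length >= 100.
#' @param lambda tuning grid (default 0.05 to 0.95 by 0.05).
#' @param method "smoother" (default) or "bootstrap".
#' @param n_boot bootstrap resamples when `method = "bootstrap"`.
#' @param seed RNG seed for the bootstrap.
#' @return A `pi1_estimate` list: `pi0`, `pi1`, `lambda`, `pi0_lambda`,
#'   `method`, `n`.
#' @export
estimate_pi1 <- function(pvalues, lambda = seq(0.05, 0.95, by = 0.05),
                         method = c("smoother", "bootstrap"),
                         n_boot = 100, seed = 1) {
  method <- match.arg(method)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_validation("p-values must lie in [0, 1] with no missing values")
  if (length(pvalues) < 100)
    stop_validation("pi1 estimation needs at least 100 p-values")
  lambda <- sort(lambda)
  n <- length(pvalues)
  pi0_l <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l),
                  numeric(1))
  if (method == "smoother") {
    sp <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- predict(sp, x = max(lambda))$y
  } else {
    pi0_min <- min(pi0_l)
    mse <- with_local_seed(seed, {
      boot <- replicate(n_boot, {
        pb <- sample(pvalues, n, replace = TRUE)
        vapply(lambda, function(l) mean(pb > l) / (1 - l), numeric(1))
      })
      rowMeans((boot - pi0_min)^2)
    })
    pi0 <- pi0_l[which.min(mse)]
  }
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi0 = pi0, pi1 = 1 - pi0, lambda = lambda,
                 pi0_lambda = pi0_l, method = method, n = n),
            class = "pi1_estimate")
}

#' @export
print.pi1_estimate <- function(x, ...) {
  cat(sprintf("<pi1_estimate> pi1 = %.3f (pi0 = %.3f, %s, n = %d)\n",
              x$pi1, x$pi0, x$method, x$n))
  invisible(x)
}

#' Directed pi1 sharing matrix across tissues
#'
#' Entry \[i, j\] is the estimated proportion of tissue-i age hits whose
#' signal replicates in tissue j.  The matrix is directional (discovery
#' vs replication roles differ) and need not be symmetric.
#'
#' @param results named list of `age_scan`-like results, one per tissue.
#' @param alpha discovery threshold.
#' @param ... passed to [estimate_pi1()].
#' @return Numeric matrix, discovery tissues in rows, replication in
#'   columns, `NA` on the diagonal.
#' @export
pi1_matrix <- function(results, alpha = 0.05, ...) {
  tn <- names(results)
  out <- matrix(NA_real_, length(tn), length(tn),
                dimnames = list(discovery = tn, replication = tn))
  for (i in tn) for (j in setdiff(tn, i)) {
    p <- tryCatch(crosstissue_pvalues(results[[i]], results[[j]],
                                      alpha = alpha),
                  twinage_validation_error = function(e) NULL)
    if (!is.null(p) && length(p) >= 100)
      out[i, j] <- estimate_pi1(p, ...)$pi1
  }
  out
}
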