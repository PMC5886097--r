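#' Build a fixed-effects design matrix, dropping aliased columns
#'
#' @param data data.frame of covariates.
#' @param fixed character vector of column names (may be empty).
#' @return Numeric matrix with an intercept column; aliased (rank-deficient)
#'   columns are dropped with a warning.
#' @export
build_design <- function(data, fixed = character()) {
  X <- if (length(fixed))
    model.matrix(stats::as.formula(paste("~", paste(fixed, collapse = "+"))),
                 data = data)
  else matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    warning(sprintf("dropping aliased design column(s): %s",
                    paste(drop, collapse = ", ")), call. = FALSE)
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  X
}

#' Linear mixed model with crossed random intercepts
#'
#' Fits \eqn{y = X\beta + \sum_j Z_j u_j + \epsilon} with independent
#' random intercepts for each grouping factor, by profiled ML or REML over
#' the variance ratios \eqn{\gamma_j = \sigma^2_j / \sigma^2_e}
#' (optimised on the log scale from deterministic starting values
#' \eqn{\gamma_j = 1}).  Fixed effects and the residual variance are
#' profiled out analytically at each evaluation.
#'
#' @param y numeric response.
#' @param data data.frame holding covariates and grouping factors.
#' @param fixed character vector of fixed-effect column names.
#' @param random character vector of grouping-factor column names; each
#'   must have at least 2 levels.
#' @param method "REML" or "ML".
#' @param reltol relative log-likelihood convergence tolerance.
#' @return An `lmm_fit` object: `beta`, `se`, `sigma2` (residual variance),
#'   `varcomp` (named random-effect variances plus `residual`), `loglik`,
#'   `residuals_marginal` (y minus fixed effects), `residuals_conditional`
#'   (additionally removing predicted random effects), `converged`.
#' @export
fit_lmm <- function(y, data, fixed = character(), random = character(),
                    method = c("REML", "ML"), reltol = 1e-8) {
  method <- match.arg(method)
  if (length(y) != nrow(data))
    stop_validation("length(y) != nrow(data)")
  if (anyNA(y)) stop_validation("missing values in response")
  X <- build_design(data, fixed)
  n <- length(y)
  p <- ncol(X)
  Z <- lapply(random, function(f) {
    g <- factor(data[[f]])
    if (nlevels(g) < 2L)
      stop_validation("grouping factor `%s` has fewer than 2 levels", f)
    model.matrix(~ 0 + g)
  })
  k <- length(Z)

  prof <- function(lgam, want_fit = FALSE) {
    V <- diag(n)
    for (j in seq_len(k)) V <- V + exp(lgam[j]) * tcrossprod(Z[[j]])
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(if (want_fit) NULL else 1e300)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    f <- stats::lm.fit(Xi, yi)
    rss <- sum(f$residuals^2)
    logdet <- 2 * sum(log(diag(ch)))
    if (method == "ML") {
      s2 <- max(rss / n, 1e-12)
      ll <- -0.5 * (n * (log(2 * pi * s2)) + logdet + n)
    } else {
      s2 <- max(rss / (n - p), 1e-12)
      ldx <- determinant(crossprod(Xi), logarithm = TRUE)$modulus
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdet + as.numeric(ldx) +
                      (n - p))
    }
    if (!want_fit) return(-ll)
    XtVX <- crossprod(Xi)
    beta <- f$coefficients
    se <- sqrt(s2 * diag(solve(XtVX)))
    e <- as.numeric(y - X %*% beta)
    cond <- as.numeric(solve(V, e))
    list(loglik = ll, beta = setNames(beta, colnames(X)),
         se = setNames(se, colnames(X)), sigma2 = s2,
         varcomp = c(setNames(s2 * exp(lgam), random), residual = s2),
         residuals_marginal = e, residuals_conditional = cond)
  }

  conv <- TRUE
  lgam <- rep(0, k)
  if (k > 0) {
    opt <- if (k == 1L)
      optim(lgam, prof, method = "BFGS",
            control = list(reltol = reltol, maxit = 500))
    else
      optim(lgam, prof, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = 2000))
    lgam <- opt$par
    conv <- opt$convergence == 0
    # parsimony tie-break: a component whose removal does not change the
    # likelihood (non-identifiable grouping, e.g. all-singleton groups)
    # is set to the zero boundary
    ll_opt <- prof(lgam)
    for (j in seq_len(k)) {
      lg0 <- lgam
      lg0[j] <- -30
      if (prof(lg0) <= ll_opt + 1e-7) {
        lgam <- lg0
        ll_opt <- prof(lgam)
      }
    }
  }
  out <- prof(lgam, want_fit = TRUE)
  if (is.null(out))
    return(structure(list(converged = FALSE, loglik = NA_real_,
                          method = method, n = n, p = p),
                     class = "lmm_fit"))
  structure(c(out, list(method = method, n = n, p = p, converged = conv,
                        random = random)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s, n = %d, logLik = %.3f%s\n", x$method, x$n,
              x$loglik, if (isTRUE(x$converged)) "" else " (NOT converged)"))
  if (!is.null(x$beta)) {
    print(round(rbind(estimate = x$beta, se = x$se), 4))
    cat("variance components:\n")
    print(round(x$varcomp, 4))
  }
  invisible(x)
}

#' Twin-block linear mixed model
#'
#' Fits the family-block marginal model in which co-twins share a
#' within-pair correlation that depends on zygosity (the marginal form of
#' family plus MZ-pair random intercepts): \eqn{V = \sigma^2 R} with 2x2
#' blocks \eqn{[[1, r], [r, 1]]}, \eqn{r = r_{MZ}} or \eqn{r_{DZ}}.  Fixed
#' effects and \eqn{\sigma^2} are profiled analytically; the remaining 1-2
#' correlation parameters are optimised by Nelder-Mead (tolerance 1e-8 on
#' the relative log-likelihood).
#'
#' @param y numeric response, one value per sample row.
#' @param X numeric design matrix including an intercept column.
#' @param samples sample table (see [validate_samples()]); rows align with
#'   `y` and `X`.
#' @param method "ML" or "REML".
#' @param mode "free" (both correlations), "equal" (r_mz = r_dz, single
#'   family intercept) or "no_common" (r_dz = r_mz / 2, no shared
#'   environment).
#' @return An `lmm_fit` object with additional elements `r_mz`, `r_dz`.
#' @export
fit_twin_lmm <- function(y, X, samples, method = c("ML", "REML"),
                         mode = c("free", "equal", "no_common")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  bl <- twin_blocks(samples)
  X <- as.matrix(X)
  fit <- cpp_twin_fit(y[bl$ord], X[bl$ord, , drop = FALSE], bl$first,
                      bl$size, bl$zyg, method == "REML",
                      c(free = 0L, equal = 1L, no_common = 2L)[[mode]],
                      1e-8, 500L)
  e <- as.numeric(y - X %*% fit$beta)
  structure(list(loglik = fit$loglik,
                 beta = setNames(as.numeric(fit$beta), colnames(X)),
                 se = setNames(as.numeric(fit$se), colnames(X)),
                 sigma2 = fit$sigma2, r_mz = fit$r_mz, r_dz = fit$r_dz,
                 varcomp = twin_varcomp(fit),
                 residuals_marginal = e, method = method, n = length(y),
                 p = ncol(X), converged = fit$converged, mode = mode),
            class = "lmm_fit")
}

twin_varcomp <- function(fit) {
  s2 <- fit$sigma2
  c(family = s2 * fit$r_dz, mz_pair = s2 * (fit$r_mz - fit$r_dz),
    residual = s2 * (1 - fit$r_mz))
}

#' Likelihood-ratio test of nested ML fits
#'
#' @param full,reduced `lmm_fit` objects fitted by ML on the same rows;
#'   `full` must have exactly one extra fixed-effect column.
#' @return list with `statistic` (clipped at 0) and `p` from the upper
#'   tail of \eqn{\chi^2_1}.
#' @export
lrt_nested <- function(full, reduced) {
  if (!inherits(full, "lmm_fit") || !inherits(reduced, "lmm_fit"))
    stop_validation("lrt_nested expects lmm_fit objects")
  if (full$method != "ML" || reduced$method != "ML")
    stop_validation("lrt_nested requires ML (not REML) fits")
  if (full$n != reduced$n)
    stop_validation("fits use different numbers of rows")
  if (full$p != reduced$p + 1L)
    stop_validation("full model must have exactly one extra fixed term")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Marginal residuals for a matrix of features under the twin model
#'
#' For each feature (row of `values`), fits the twin-block model by REML
#' and returns the response minus the GLS fixed-effect fit.  Familial
#' covariance is used to weight the fit but is left in the residual
#' values.
#'
#' @param values features x samples matrix.
#' @param X fixed-effects design matrix (samples x p, with intercept).
#' @param samples sample table aligned with the columns of `values`.
#' @return Matrix of marginal residuals with the dimnames of `values`.
#' @export
twin_marginal_residuals <- function(values, X, samples) {
  bl <- twin_blocks(samples)
  X <- as.matrix(X)
  Xo <- X[bl$ord, , drop = FALSE]
  out <- matrix(NA_real_, nrow(values), ncol(values),
                dimnames = dimnames(values))
  for (f in seq_len(nrow(values))) {
    y <- values[f, bl$ord]
    fit <- cpp_twin_fit(y, Xo, bl$first, bl$size, bl$zyg, TRUE, 0L,
                        1e-8, 500L)
    out[f, bl$ord] <- y - as.numeric(Xo %*% fit$beta)
  }
  out
}

#' Conditional residuals for a matrix of features under the twin model
#'
#' For each feature (row of `values`), fits the twin-block model by REML
#' and returns the response minus fixed effects and the BLUP of the
#' pair-shared component ("removing technical covariates and family
#' structure").
#'
#' @param values features x samples matrix (rank-normalized expression).
#' @param X fixed-effects design matrix (samples x p, with intercept).
#' @param samples sample table aligned with the columns of `values`.
#' @return Matrix of conditional residuals, features x samples, same
#'   dimnames as `values`.
#' @export
twin_conditional_residuals <- function(values, X, samples) {
  bl <- twin_blocks(samples)
  X <- as.matrix(X)
  R <- cpp_cond_residuals(t(values[, bl$ord, drop = FALSE]),
                          X[bl$ord, , drop = FALSE], bl$first, bl$size,
                          bl$zyg, 1e-8, 500L)
  out <- matrix(NA_real_, nrow(values), ncol(values),
                dimnames = dimnames(values))
  out[, bl$ord] <- t(R)
  out
}
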