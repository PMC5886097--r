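test_that("singleton-only data collapses to ordinary least squares", {
  set.seed(1)
  n <- 80
  s <- data.frame(sample_id = sprintf("s%d", 1:n),
                  individual_id = sprintf("i%d", 1:n),
                  family_id = sprintf("f%d", 1:n),
                  zygosity = "singleton", age = runif(n, 39, 85),
                  tissue = "skin")
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  X <- cbind(1, x = x)
  fit <- fit_twin_lmm(y, X, s, method = "ML")
  ols <- lm(y ~ x)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$r_mz, 0)
  # generic engine: groups of size 1 drive the variance component to ~0
  d <- data.frame(x = x, g = factor(seq_len(n)))
  gf <- fit_lmm(y, d, fixed = "x", random = "g", method = "ML")
  expect_equal(unname(gf$beta), unname(coef(ols)), tolerance = 1e-5)
  expect_lt(gf$varcomp[["g"]], 0.05)
})

test_that("the engine recovers simulated fixed and random effects", {
  set.seed(2)
  n_fam <- 500
  fam <- rep(seq_len(n_fam), each = 2)
  u <- rnorm(n_fam)                       # family variance 1
  x <- rnorm(2 * n_fam)
  y <- 2 + 0.5 * x + u[fam] + rnorm(2 * n_fam)
  s <- data.frame(sample_id = sprintf("s%d", 1:(2 * n_fam)),
                  individual_id = sprintf("i%d", 1:(2 * n_fam)),
                  family_id = sprintf("f%d", fam), zygosity = "DZ",
                  age = rep(runif(n_fam, 39, 85), each = 2),
                  tissue = "skin")
  fit <- fit_twin_lmm(y, cbind(1, x = x), s, method = "REML",
                      mode = "equal")
  expect_equal(unname(fit$beta["x"]), 0.5, tolerance = 0.1)
  expect_equal(unname(fit$varcomp[["family"]] + fit$varcomp[["mz_pair"]]),
               1, tolerance = 0.1)
  expect_equal(unname(fit$varcomp[["residual"]]), 1, tolerance = 0.1)
})

test_that("an exact linear response is fitted with ~zero residual variance", {
  set.seed(3)
  s <- null_cohort(n_mz = 10, n_dz = 10, n_genes = 1)$samples
  x <- rnorm(nrow(s))
  fit <- fit_twin_lmm(x, cbind(1, x = x), s, method = "ML")
  expect_equal(unname(fit$beta["x"]), 1, tolerance = 1e-6)
  expect_lt(fit$sigma2, 1e-8)
})

test_that("likelihood-ratio mechanics: clipping, df and the chi-square map", {
  mk <- function(ll, p, method = "ML")
    structure(list(loglik = ll, p = p, n = 100, method = method),
              class = "lmm_fit")
  # identical models -> statistic 0, p 1
  r <- lrt_nested(mk(-50, 3), mk(-50, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # numerically negative statistics clip to 0
  expect_equal(lrt_nested(mk(-50.001, 3), mk(-50, 2))$statistic, 0)
  # the 5% chi-square quantile: statistic 3.841459 -> p 0.050
  r <- lrt_nested(mk(-50 + 3.841459 / 2, 3), mk(-50, 2))
  expect_equal(r$p, 0.05, tolerance = 1e-6)
  expect_error(lrt_nested(mk(-50, 3, "REML"), mk(-50, 2, "REML")),
               "REML")
  expect_error(lrt_nested(mk(-50, 4), mk(-50, 2)), "extra fixed term")
})

test_that("block likelihood equals the dense multivariate-normal oracle", {
  co <- null_cohort(n_mz = 4, n_dz = 4, n_singletons = 2, n_genes = 1,
                    exons = c(1, 1), seed = 11)
  s <- co$samples
  y <- co$truth$latent[1, ]
  X <- cbind(1, age = s$age)
  for (m in c("ML", "REML")) {
    fit <- fit_twin_lmm(y, X, s, method = m)
    dense <- dense_twin_loglik(y, X, s, fit$r_mz, fit$r_dz, fit$sigma2,
                               reml = (m == "REML"))
    expect_equal(fit$loglik, dense, tolerance = 1e-8)
  }
})

test_that("twin and crossed-random-effects fits agree with lme4", {
  co <- simulate_cohort(sim_config(
    n_mz_pairs = 60, n_dz_pairs = 60, n_genes = 1,
    exons_per_gene_range = c(1, 1), n_null_snps = 0,
    effect_profiles = gene_profile(beta_age = 0.02, sigma2_A = 0.5,
                                   sigma2_C = 0.2, sigma2_E = 0.3),
    seed = 7))
  s <- co$samples
  y <- co$truth$latent[1, ]
  d <- data.frame(y = y, age = s$age, fam = s$family_id,
                  mz = ifelse(s$zygosity == "MZ", s$family_id,
                              s$sample_id))
  ctl <- lme4::lmerControl(check.conv.singular = "ignore")
  for (reml in c(FALSE, TRUE)) {
    lf <- lme4::lmer(y ~ age + (1 | fam) + (1 | mz), data = d,
                     REML = reml, control = ctl)
    fit <- fit_twin_lmm(y, cbind(1, age = s$age), s,
                        method = if (reml) "REML" else "ML")
    expect_equal(fit$loglik, as.numeric(stats::logLik(lf)),
                 tolerance = 1e-5)
    expect_equal(unname(fit$beta), unname(lme4::fixef(lf)),
                 tolerance = 1e-3)
  }
  gf <- fit_lmm(y, d, fixed = "age", random = c("fam", "mz"),
                method = "ML")
  lf <- lme4::lmer(y ~ age + (1 | fam) + (1 | mz), data = d,
                   REML = FALSE, control = ctl)
  expect_equal(gf$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
})

test_that("conditional residuals are orthogonal to the fixed covariates", {
  set.seed(4)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  g = factor(rep(1:30, each = 4)))
  y <- 0.3 * d$x1 - 0.2 * d$x2 + rnorm(30)[d$g] + rnorm(n)
  fit <- fit_lmm(y, d, fixed = c("x1", "x2"), random = "g")
  expect_lt(abs(cor(fit$residuals_conditional, d$x1)), 1e-6)
  expect_lt(abs(cor(fit$residuals_conditional, d$x2)), 1e-6)
  expect_lt(abs(sum(fit$residuals_conditional)) / n, 1e-6)
})

test_that("ACE decomposition respects boundaries and the Falconer limits", {
  # independent co-twins: everything loads on E
  set.seed(5)
  co <- null_cohort(n_mz = 150, n_dz = 150, n_genes = 1, exons = c(1, 1),
                    seed = 12)
  s <- co$samples
  y <- rnorm(nrow(s))
  vc <- fit_ace(y, s)
  expect_lt(vc$sigma2_A + vc$sigma2_C, 0.25 * vc$sigma2_E)
  expect_true(all(c(vc$sigma2_A, vc$sigma2_C, vc$sigma2_E,
                    vc$sigma2_age) >= 0))
  # equal MZ/DZ correlation c: A -> 0 boundary, C -> c * total
  co2 <- null_cohort(n_mz = 400, n_dz = 400, n_genes = 1,
                     exons = c(1, 1), seed = 14)
  s2 <- co2$samples
  fam <- match(s2$family_id, unique(s2$family_id))
  shared <- rnorm(max(fam))
  y2 <- sqrt(0.5) * shared[fam] + sqrt(0.5) * rnorm(nrow(s2))
  vc2 <- fit_ace(y2, s2)
  tot2 <- vc2$sigma2_A + vc2$sigma2_C + vc2$sigma2_E
  expect_lt(vc2$sigma2_A, 0.15)
  # familial (A + C) share is well determined at c = 0.5 even though the
  # A/C split is noisy near the boundary
  expect_equal((vc2$sigma2_A + vc2$sigma2_C) / tot2, 0.5,
               tolerance = 0.12)
  expect_gt(vc2$sigma2_C, vc2$sigma2_A)
  # a single zygosity cannot identify A vs C
  expect_error(fit_ace(y[s$zygosity == "MZ"],
                       s[s$zygosity == "MZ", ]), "MZ and DZ")
  few <- c(which(s$zygosity == "MZ")[1:4], which(s$zygosity == "DZ")[1:4])
  expect_error(fit_ace(y[few], s[few, ]), "complete twin pairs")
})

test_that("proportions from the decomposition sum to one", {
  co <- simulate_cohort(sim_config(
    n_mz_pairs = 100, n_dz_pairs = 100, n_genes = 1,
    exons_per_gene_range = c(1, 1), n_null_snps = 0,
    effect_profiles = gene_profile(beta_age = 0.03, sigma2_A = 0.4,
                                   sigma2_C = 0.3, sigma2_E = 0.3),
    seed = 13))
  vc <- fit_ace(co$truth$latent[1, ], co$samples)
  tot <- vc$sigma2_A + vc$sigma2_C + vc$sigma2_E + vc$sigma2_age
  props <- c(vc$sigma2_A, vc$sigma2_C, vc$sigma2_E, vc$sigma2_age) / tot
  expect_true(all(props >= 0 & props <= 1))
  expect_equal(sum(props), 1, tolerance = 1e-6)
  expect_equal(vc$h2, props[1], tolerance = 1e-9)
})
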