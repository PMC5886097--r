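test_that("residualization without covariates or families centers the data", {
  n <- 40
  s <- data.frame(sample_id = sprintf("s%d", 1:n),
                  individual_id = sprintf("i%d", 1:n),
                  family_id = sprintf("f%d", 1:n),
                  zygosity = "singleton", age = seq(39, 85, length.out = n),
                  tissue = "skin")
  set.seed(31)
  v <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("a", "b"), s$sample_id))
  r <- residualize_for_variance(v, s, fixed = character())
  expect_equal(r, v - rowMeans(v), tolerance = 1e-8)
  expect_error(residualize_for_variance(v, s, fixed = c("age")), "age")
})

test_that("familial covariance is modelled while pair-shared dispersion
           signals survive residualization", {
  co <- simulate_cohort(sim_config(
    n_mz_pairs = 250, n_dz_pairs = 50, n_genes = 1,
    exons_per_gene_range = c(1, 1), n_null_snps = 0,
    effect_profiles = gene_profile(var_slope = 1.04, sigma2_A = 0,
                                   sigma2_C = 0.6, sigma2_E = 0.4),
    seed = 32))
  s <- co$samples
  v <- co$truth$latent
  # the REML fit sees the familial correlation
  fit <- fit_twin_lmm(v[1, ], matrix(1, ncol(v), 1), s, method = "REML")
  expect_gt(fit$r_mz, 0.3)
  # marginal residuals keep the pair-shared dispersion trend, so the
  # age-variance statistic can still see shared-environment changes;
  # BLUP-subtracted conditional residuals would cancel it
  r <- residualize_for_variance(v, s, fixed = character())
  expect_lt(variance_age_test(r[1, ], s$age)$p, 0.05)
  rc <- twin_conditional_residuals(v, matrix(1, ncol(v), 1), s)
  expect_lt(pair_cor(rc[1, ], s, "MZ"), 0.1)
})

test_that("the variance scan stays calibrated under strong family effects", {
  co <- simulate_cohort(sim_config(
    n_mz_pairs = 60, n_dz_pairs = 60, n_genes = 40,
    exons_per_gene_range = c(1, 1), n_null_snps = 0,
    effect_profiles = gene_profile(sigma2_A = 0.4, sigma2_C = 0.4,
                                   sigma2_E = 0.2),
    seed = 38))
  rint <- rint_matrix(scale_counts(co$expression)$values)
  r <- residualize_for_variance(rint, co$samples)
  vs <- age_variance_scan(r, co$samples, co$expression$annotation,
                          n_perm = 50, seed = 6)
  expect_lte(mean(vs$genes$significant), 0.15)
})

test_that("technical covariates are removed from the residuals", {
  co <- null_cohort(n_mz = 40, n_dz = 0, n_genes = 2, exons = c(1, 1),
                    seed = 33)
  s <- co$samples
  rint <- rint_matrix(scale_counts(co$expression)$values)
  # OLS technical residuals are exactly orthogonal to the covariates
  rt <- residualize_technical(rint, s)
  expect_lt(abs(cor(rt[1, ], s$insert_size)), 1e-8)
  expect_lt(abs(cor(rt[1, ], s$gc_mean)), 1e-8)
  # GLS (twin-weighted) residuals remove the effect up to the metric
  # difference between the GLS and OLS projections
  r <- residualize_for_variance(rint, s)
  expect_lt(abs(cor(r[1, ], s$insert_size)), 0.2)
  expect_lt(abs(cor(r[1, ], s$gc_mean)), 0.2)
  expect_gt(cor(r[1, ], rt[1, ]), 0.95)
})

test_that("degenerate and invalid inputs are rejected cleanly", {
  age <- seq(39, 85, length.out = 50)
  # zero-dispersion distance: exact linear residuals -> rho 0, p 1
  out <- variance_age_test(rep(0, 50), age)
  expect_equal(out$rho, 0)
  expect_equal(out$p, 1)
  expect_error(variance_age_test(rnorm(20), age[1:20]), "30")
  expect_error(variance_age_test(rnorm(50), rep(c(40, 50), 25)),
               "distinct ages")
})

test_that("the statistic is invariant to residual shifts and affine age", {
  set.seed(34)
  age <- runif(200, 39, 85)
  y <- rnorm(200, 0, 1 + (age - 39) / 46)
  a <- variance_age_test(y, age)
  b <- variance_age_test(y + 100, age)
  expect_equal(a$rho, b$rho, tolerance = 1e-8)
  cc <- variance_age_test(y, 2 * age + 5)
  expect_equal(a$rho, cc$rho, tolerance = 1e-6)
  expect_equal(a$direction, "increasing")
})

test_that("type-I error of the dispersion test is nominal under the null", {
  set.seed(35)
  age <- runif(600, 39, 85)
  rej <- mean(replicate(1000, {
    variance_age_test(rnorm(600), age)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("dispersion growth is detected and matches a Levene-style oracle", {
  set.seed(36)
  age <- runif(300, 39, 85)
  agree <- 0; rej <- 0; rejo <- 0; reps <- 60
  for (i in seq_len(reps)) {
    y <- rnorm(300, 0, 1 + (age - 39) / 46)     # sd doubles over the range
    mine <- variance_age_test(y, age)$p < 0.05
    oracle <- summary(lm(abs(y - mean(y)) ~ age))$coefficients[2, 4] < 0.05
    agree <- agree + (mine == oracle)
    rej <- rej + mine; rejo <- rejo + oracle
  }
  expect_gte(agree / reps, 0.8)
  expect_gt(rej / reps, 0.6)
})

test_that("variance scan rolls features to genes and is seed-stable", {
  co <- null_cohort(n_mz = 25, n_dz = 25, n_genes = 10, exons = c(1, 2),
                    seed = 37)
  rint <- rint_matrix(scale_counts(co$expression)$values)
  r <- residualize_for_variance(rint, co$samples)
  a <- age_variance_scan(r, co$samples, co$expression$annotation,
                         n_perm = 5, seed = 4)
  b <- age_variance_scan(r, co$samples, co$expression$annotation,
                         n_perm = 5, seed = 4)
  expect_identical(a$genes$p_adjusted, b$genes$p_adjusted)
  expect_equal(nrow(a$genes), 10)
  expect_setequal(unique(a$features$gene_id), a$genes$gene_id)
  expect_true(all(a$features$direction %in%
                    c("increasing", "decreasing")))
})
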