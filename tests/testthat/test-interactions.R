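singleton_frame <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%d", 1:n),
             individual_id = sprintf("i%d", 1:n),
             family_id = sprintf("f%d", 1:n), zygosity = "singleton",
             age = runif(n, 39, 85), tissue = "skin")
}

toy_gxage <- function(n = 200, maf = 0.3, beta3 = 0, beta1 = 0,
                      seed = 1, n_var = 1, positions = 5000L) {
  s <- singleton_frame(n, seed)
  g <- matrix(rbinom(n_var * n, 2, maf), n_var, n,
              dimnames = list(sprintf("v%d", 1:n_var), s$sample_id))
  geno <- genotype_matrix(g, data.frame(
    variant_id = rownames(g), chrom = "1",
    pos = rep_len(positions, n_var), ref = "A", alt = "G"))
  y <- beta1 * g[1, ] + beta3 * g[1, ] * (s$age - 62) + rnorm(n)
  v <- matrix(y, 1, dimnames = list("gA_ex1", s$sample_id))
  ann <- data.frame(feature_id = "gA_ex1", gene_id = "gA",
                    feature_kind = "exon", chrom = "1", start = 1000L,
                    end = 1200L, strand = "+", tss = 1000L)
  list(s = s, geno = geno, v = v, ann = ann)
}

test_that("MAF and window filters follow the cis conventions", {
  d <- toy_gxage(n = 300, maf = 0.04, seed = 51)
  # MAF below 0.05 -> variant excluded from the scan
  out <- gxage_scan(d$v, d$geno, d$s, d$ann)
  expect_equal(nrow(out), 0L)
  # a variant at exactly 1 Mb from the TSS is included
  d2 <- toy_gxage(n = 100, maf = 0.3, seed = 52,
                  positions = 1000L + 1e6L + 1L)  # 1-based pos, 0-based tss
  out2 <- gxage_scan(d2$v, d2$geno, d2$s, d2$ann)
  expect_equal(nrow(out2), 1L)
  # one bp further is excluded
  d3 <- toy_gxage(n = 100, maf = 0.3, seed = 52,
                  positions = 1000L + 1e6L + 2L)
  expect_equal(nrow(gxage_scan(d3$v, d3$geno, d3$s, d3$ann)), 0L)
})

test_that("constant age and monomorphic variants are handled explicitly", {
  d <- toy_gxage(n = 100, seed = 53)
  d$s$age <- 50
  expect_error(gxage_scan(d$v, d$geno, d$s, d$ann), "constant")
  d2 <- toy_gxage(n = 100, seed = 54)
  d2$geno$dosages[1, ] <- 1          # monomorphic: maf 0.5 but sd 0
  out <- gxage_scan(d2$v, d2$geno, d2$s, d2$ann)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("interaction p-values are uniform under main effects only", {
  set.seed(55)
  ps <- replicate(300, {
    d <- toy_gxage(n = 150, beta1 = 1, beta3 = 0,
                   seed = sample.int(1e6, 1))
    gxage_scan(d$v, d$geno, d$s, d$ann)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a true interaction is recovered with the right sign", {
  set.seed(56)
  hits <- replicate(30, {
    d <- toy_gxage(n = 600, beta3 = 0.02, seed = sample.int(1e6, 1))
    r <- gxage_scan(d$v, d$geno, d$s, d$ann)
    c(sign_ok = r$beta_interaction > 0, rej = r$p < 0.05)
  })
  expect_gte(mean(hits["sign_ok", ]), 0.9)
  expect_gte(mean(hits["rej", ]), 0.8)
})

test_that("residual-permutation adjustment: extreme case and determinism", {
  d <- toy_gxage(n = 400, beta3 = 0.05, seed = 57)  # very strong signal
  scan <- gxage_scan(d$v, d$geno, d$s, d$ann)
  adj <- gxage_adjust(scan, d$v, d$geno, d$s, c(gA = 1L), n_perm = 10,
                      seed = 6)
  # single feature, one variant: pool 10, +1 smoothing -> 1/11
  expect_equal(adj$features$p_adjusted, 1 / 11)
  expect_equal(length(adj$null_pvalues), 10L)
  adj2 <- gxage_adjust(scan, d$v, d$geno, d$s, c(gA = 1L), n_perm = 10,
                       seed = 6)
  expect_identical(adj$null_pvalues, adj2$null_pvalues)
  expect_false(identical(
    adj$null_pvalues,
    gxage_adjust(scan, d$v, d$geno, d$s, c(gA = 1L), n_perm = 10,
                 seed = 7)$null_pvalues))
})

test_that("no features survive FDR control under a global null", {
  co <- simulate_cohort(sim_config(n_mz_pairs = 40, n_dz_pairs = 40,
                                   n_genes = 50,
                                   exons_per_gene_range = c(1, 2),
                                   n_null_snps = 2, seed = 58))
  rint <- rint_matrix(scale_counts(co$expression)$values)
  resid <- residualize_for_variance(rint, co$samples)
  scan <- gxage_scan(resid, co$genotypes, co$samples,
                     co$expression$annotation)
  n_ex <- table(co$expression$annotation$gene_id)
  adj <- gxage_adjust(scan, resid, co$genotypes, co$samples,
                      setNames(as.integer(n_ex), names(n_ex)), seed = 8)
  expect_lte(sum(adj$features$significant), 5L)
  expect_lte(sum(adj$genes$significant), 3L)
})

test_that("methylation interaction threshold is strict and probes with
           zero variance are skipped", {
  set.seed(59)
  n <- 300
  age <- runif(n, 39, 85)
  m <- rbeta(n, 2, 2)
  y <- 0.15 * (m - 0.5) * (age - 62) + rnorm(n)
  er <- matrix(y, 1, dimnames = list("gB_ex1", NULL))
  mr <- rbind(cg1 = m, cg2 = rep(0.5, n))
  out <- meth_age_test(er, mr, age,
                       feature_genes = c(gB_ex1 = "gB"),
                       probe_genes = c(cg1 = "gB", cg2 = "gB"))
  expect_equal(out$probe_id, "cg1")          # cg2 has zero variance
  expect_true(out$significant[1])
  # p equal to the threshold is NOT significant (strict inequality)
  out2 <- meth_age_test(er, mr, age,
                        feature_genes = c(gB_ex1 = "gB"),
                        probe_genes = c(cg1 = "gB"),
                        p_threshold = out$p[1])
  expect_false(out2$significant[1])
})

test_that("hypomethylation-restricted age decline yields a positive
           interaction matching stratified slopes", {
  set.seed(60)
  ok <- replicate(100, {
    n <- 500
    age <- runif(n, 39, 85)
    m <- rbeta(n, 2, 2)
    y <- ifelse(m < 0.3, -0.05 * (age - 62), 0) + rnorm(n)
    er <- matrix(y, 1, dimnames = list("g_ex1", NULL))
    fit <- meth_age_test(er, rbind(cg = m), age,
                         feature_genes = c(g_ex1 = "g"),
                         probe_genes = c(cg = "g"))
    lo <- coef(lm(y[m < 0.3] ~ age[m < 0.3]))[2]
    hi <- coef(lm(y[m > 0.5] ~ age[m > 0.5]))[2]
    sign(fit$beta_interaction) == sign(hi - lo)
  })
  expect_gte(mean(ok), 0.95)
})
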