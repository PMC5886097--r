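test_that("rank inverse normal matches the normal-quantile oracle", {
  # ranks of (5, 1, 9) are (2, 1, 3) -> Phi^-1 at (3/6, 1/6, 5/6)
  got <- rank_inverse_normal(c(5, 1, 9))
  expect_equal(got, c(0, -0.967421566101701, 0.967421566101701),
               tolerance = 1e-12)
  # ties get average ranks: (1, 1, 2) -> ranks (1.5, 1.5, 3)
  expect_equal(rank_inverse_normal(c(1, 1, 2)),
               qnorm(c(1/3, 1/3, 5/6)), tolerance = 1e-12)
})

test_that("rank inverse normal is rank-equivariant, symmetric and scaled", {
  set.seed(1)
  x <- rnorm(51)
  y <- rank_inverse_normal(x)
  # permutation of the input permutes the output identically
  pm <- sample(51)
  expect_equal(rank_inverse_normal(x[pm]), y[pm])
  # odd-length tie-free input sums to zero by symmetry of the offsets
  expect_lt(abs(sum(y)), 1e-10)
  expect_lt(abs(mean(y)), 1e-8 * length(y))
  expect_gt(var(y), 0.8)
  expect_lt(var(y), 1.0)
  # order is preserved
  expect_equal(order(y), order(x))
})

test_that("rank inverse normal rejects degenerate input", {
  expect_error(rank_inverse_normal(rep(1, 10)), "constant")
  expect_error(rank_inverse_normal(c(1, 2)), "length")
  m <- rbind(a = rep(1, 5), b = c(1, 3, 2, 5, 4))
  expect_message(out <- rint_matrix(m), "constant feature")
  expect_equal(rownames(out), "b")
})

test_that("count scaling is linear, idempotent and scale-invariant", {
  ann <- data.frame(feature_id = c("f1", "f2"), gene_id = "g1",
                    feature_kind = "exon", chrom = "1", start = 0,
                    end = 10, strand = "+")
  m <- matrix(c(2e6, 3e6, 4e6, 6e6), 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  fm <- feature_matrix(m, ann)
  sc <- scale_counts(fm, target = 1e7)
  expect_equal(sc$values[, "s1"], m[, "s1"] * 2)    # 5e6 column doubled
  expect_equal(unname(colSums(sc$values)), c(1e7, 1e7))
  expect_equal(scale_counts(sc, target = 1e7)$values, sc$values)
  # proportional columns scale to identical columns
  expect_equal(unname(sc$values[, 1]), unname(sc$values[, 2]))
  fm$values[, 1] <- 0
  expect_error(scale_counts(fm), "s1")
})

test_that("gene-level zero-count filter is strict at the threshold", {
  ann <- data.frame(feature_id = c("a1", "b1"), gene_id = c("gA", "gB"),
                    feature_kind = "exon", chrom = "1", start = 0,
                    end = 10, strand = "+")
  m <- matrix(1, 2, 100, dimnames = list(c("a1", "b1"), sprintf("s%d", 1:100)))
  m[1, 1:11] <- 0                        # gene A: 11% zeros -> flagged
  m[2, 1:10] <- 0                        # gene B: exactly 10% -> kept
  fm <- feature_matrix(m, ann)
  expect_equal(flag_zero_genes(fm, 0.10), "gA")
})

test_that("expression reader validates ids and sample referential integrity", {
  dir <- withr::local_tempdir()
  co <- null_cohort(n_mz = 3, n_dz = 2, n_genes = 3, exons = c(1, 2),
                    seed = 5)
  write_cohort(co, dir)
  samples <- read_samples(file.path(dir, "samples.tsv"))
  fm <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "features.tsv"), samples = samples)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(ncol(fm$values), nrow(samples))
  # a matrix sample absent from the metadata is an error naming it
  expect_error(
    read_expression(file.path(dir, "expression.tsv"),
                    file.path(dir, "features.tsv"),
                    samples = samples[-1, ]),
    samples$sample_id[1])
})

test_that("VCF round-trips genotypes and recomputes MAF", {
  dir <- withr::local_tempdir()
  dos <- matrix(c(0, 1, 2, 1, 0.95, 1.9, 0.5, 0.05), 2, byrow = TRUE,
                dimnames = list(c("v1", "v2"), sprintf("s%d", 1:4)))
  ann <- data.frame(variant_id = c("v1", "v2"), chrom = "1",
                    pos = c(100L, 200L), ref = "A", alt = "G")
  g <- genotype_matrix(dos, ann)
  write_vcf(g, file.path(dir, "x.vcf"))
  g2 <- read_vcf(file.path(dir, "x.vcf"))
  expect_equal(g2$dosages, g$dosages, tolerance = 1e-6)
  # GT 0/1 decodes to dosage 1 even without a DS field
  gt_vcf <- file.path(dir, "gt.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "50", "v9", "A", "T", ".", "PASS", ".", "GT",
          "0/1", "1|1", "0/0", sep = "\t")), gt_vcf)
  g3 <- read_vcf(gt_vcf)
  expect_equal(unname(g3$dosages["v9", ]), c(1, 2, 0))
  # maf = min(p, 1-p) with p = dosage mean / 2; mean 1.9 -> maf 0.05
  site <- genotype_matrix(matrix(rep(1.9, 10), 1,
                                 dimnames = list("v", NULL)),
                          data.frame(variant_id = "v", chrom = "1",
                                     pos = 1L, ref = "A", alt = "G"))
  expect_equal(site$annotation$maf, 0.05, tolerance = 1e-9)
  expect_error(read_vcf(file.path(dir, "x.vcf"), samples = "nope"),
               "nope")
})

test_that("a simulated cohort round-trips losslessly through disk", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(
    n_mz_pairs = 4, n_dz_pairs = 4, n_genes = 4,
    exons_per_gene_range = c(1, 2), n_null_snps = 1,
    effect_profiles = gene_profile(
      gxage = list(maf = 0.3, beta_main = 0.1, beta_interaction = 0.01),
      meth = list(beta_meth = 0.2, beta_meth_x_age = 0.01)),
    seed = 9))
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_equal(co2$expression$values, co$expression$values)
  expect_equal(co2$samples$age, co$samples$age, tolerance = 1e-9)
  expect_equal(co2$genotypes$dosages, co$genotypes$dosages,
               tolerance = 1e-6)
  expect_equal(co2$methylation$betas, co$methylation$betas,
               tolerance = 1e-9)
  expect_equal(co2$truth$latent, co$truth$latent, tolerance = 1e-9)
  expect_error(read_cohort(file.path(dir, "missing")), "not found")
})

test_that("methylation probes with missing values are excluded", {
  m <- matrix(runif(20), 4, 5,
              dimnames = list(sprintf("p%d", 1:4), sprintf("s%d", 1:5)))
  m[2, 3] <- NA
  ann <- data.frame(probe_id = rownames(m), chrom = "1", pos = 1:4,
                    gene_id = "g")
  expect_message(mm <- methylation_matrix(m, ann), "1 probe")
  expect_equal(nrow(mm$betas), 3L)
  m[1, 1] <- 1.5
  expect_error(methylation_matrix(m[1, , drop = FALSE],
                                  ann[1, , drop = FALSE]), "\\[0, 1\\]")
})
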