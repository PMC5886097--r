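#' Per-gene effect profile for the synthetic twin cohort
#'
#' Describes the ground-truth generative effects for one gene: an age trend
#' on the mean, age-dependent dispersion, age-growing divergence between MZ
#' co-twins, the ACE split of the residual variance, and optional cis
#' SNP-by-age and methylation-by-age interaction effects.
#'
#' `var_slope` multiplies the standard deviation of the *pair-shared*
#' environmental component per year away from the cohort age midpoint
#' (1 = homoscedastic).  Modelling the dispersion change as acting on
#' exposures shared by co-twins makes population variance change with age
#' without driving co-twins apart, so the variance test and the MZ
#' discordance test can dissociate.  `discordance_slope`, in contrast, adds
#' individual-level (non-shared) noise whose sd grows linearly from the
#' youngest age, which both inflates variance and separates co-twins.
#'
#' @param beta_age age effect on mean expression, in residual-sd units per
#'   year (applied to age centred at the cohort midpoint).
#' @param var_slope multiplicative change in the pair-shared residual sd
#'   per year; must be > 0.
#' @param discordance_slope sd of extra non-shared noise per year of age
#'   above the cohort minimum.
#' @param sigma2_A,sigma2_C,sigma2_E additive-genetic, common-environment
#'   and unique-environment fractions of the (non-age) residual variance;
#'   must sum to 1.
#' @param gxage optional list `list(maf =, beta_main =, beta_interaction =)`
#'   describing a causal cis SNP; `maf` must lie in \[0.05, 0.5\], matching
#'   the allele-frequency range of variants the scan tests.
#'   `beta_interaction` is in sd units per allele per year.
#' @param meth optional list `list(beta_meth =, beta_meth_x_age =)` for a
#'   causal methylation probe (beta values drawn from Beta(2, 2)).
#' @return A `gene_profile` object.
#' @export
gene_profile <- function(beta_age = 0, var_slope = 1, discordance_slope = 0,
                         sigma2_A = 1 / 3, sigma2_C = 1 / 3,
                         sigma2_E = 1 / 3, gxage = NULL, meth = NULL) {
  if (!is.numeric(var_slope) || var_slope <= 0)
    stop_config("var_slope", "must be > 0")
  if (any(c(sigma2_A, sigma2_C, sigma2_E) < 0))
    stop_config("sigma2_A/C/E", "variance fractions must be >= 0")
  if (abs(sigma2_A + sigma2_C + sigma2_E - 1) > 1e-9)
    stop_config("sigma2_A/C/E", "variance fractions must sum to 1")
  if (discordance_slope < 0)
    stop_config("discordance_slope", "must be >= 0")
  if (!is.null(gxage)) {
    need <- c("maf", "beta_main", "beta_interaction")
    if (!all(need %in% names(gxage)))
      stop_config("gxage", paste("needs fields", paste(need, collapse = ", ")))
    if (gxage$maf < 0.05 || gxage$maf > 0.5)
      stop_config("gxage$maf", "must lie in [0.05, 0.5]")
  }
  if (!is.null(meth) &&
      !all(c("beta_meth", "beta_meth_x_age") %in% names(meth)))
    stop_config("meth", "needs fields beta_meth, beta_meth_x_age")
  structure(list(beta_age = beta_age, var_slope = var_slope,
                 discordance_slope = discordance_slope,
                 sigma2_A = sigma2_A, sigma2_C = sigma2_C,
                 sigma2_E = sigma2_E, gxage = gxage, meth = meth),
            class = "gene_profile")
}

#' Simulation configuration for a synthetic twin cohort
#'
#' Defaults mirror an adult female twin registry design: co-twins sampled
#' at the same visit (identical ages), ages uniform on 39-85 years, and an
#' MZ:DZ ratio of roughly 1:1.5, scaled down from registry size.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons cohort composition; at least
#'   one pair type must be nonzero.
#' @param age_range numeric length-2, years; must lie within \[18, 110\].
#' @param n_genes number of simulated genes.
#' @param exons_per_gene_range integer length-2 (min, max) exons per gene.
#' @param effect_profiles list of [gene_profile()] objects, recycled over
#'   genes; `NULL` means all-null profiles (no age effects, equal ACE).
#' @param library_scale target library size used when emitting counts.
#' @param n_null_snps number of non-causal cis SNPs simulated per gene.
#' @param tissue tissue label for the sample table.
#' @param seed integer; fully determines the output.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_mz_pairs = 84, n_dz_pairs = 130, n_singletons = 0,
                       age_range = c(39, 85), n_genes = 100,
                       exons_per_gene_range = c(1, 4),
                       effect_profiles = NULL, library_scale = 1e7,
                       n_null_snps = 2, tissue = "skin", seed = 1) {
  for (f in c("n_mz_pairs", "n_dz_pairs", "n_singletons", "n_genes",
              "n_null_snps")) {
    v <- get(f)
    if (!is_count(v)) stop_config(f, "must be a nonnegative integer")
  }
  if (n_mz_pairs + n_dz_pairs == 0)
    stop_config("n_mz_pairs", "at least one pair type must be nonzero")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop_config("age_range", "must be (min, max) with min < max")
  if (age_range[1] < 18 || age_range[2] > 110)
    stop_config("age_range", "must lie within [18, 110]")
  if (length(exons_per_gene_range) != 2 ||
      !is_count(exons_per_gene_range[1]) ||
      !is_count(exons_per_gene_range[2]) ||
      exons_per_gene_range[1] < 1 ||
      exons_per_gene_range[1] > exons_per_gene_range[2])
    stop_config("exons_per_gene_range", "must be integers 1 <= min <= max")
  if (!is.numeric(library_scale) || library_scale <= 0)
    stop_config("library_scale", "must be > 0")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_config("seed", "must be a single integer")
  if (is.null(effect_profiles)) effect_profiles <- list(gene_profile())
  if (inherits(effect_profiles, "gene_profile"))
    effect_profiles <- list(effect_profiles)
  if (!all(vapply(effect_profiles, inherits, TRUE, "gene_profile")))
    stop_config("effect_profiles", "must be a list of gene_profile objects")
  structure(list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
                 n_singletons = n_singletons, age_range = age_range,
                 n_genes = n_genes,
                 exons_per_gene_range = exons_per_gene_range,
                 effect_profiles = effect_profiles,
                 library_scale = library_scale, n_null_snps = n_null_snps,
                 tissue = tissue, seed = seed),
            class = "sim_config")
}

# one cis SNP simulated through parental haplotypes: MZ co-twins share the
# transmitted genotype, DZ co-twins share each parental allele with
# probability 1/2, giving the expected IBD distribution exactly.
sim_snp_dosages <- function(samples, p_alt) {
  fams <- unique(samples$family_id)
  dos <- numeric(nrow(samples))
  names(dos) <- samples$sample_id
  for (fam in fams) {
    idx <- which(samples$family_id == fam)
    mother <- rbinom(2, 1, p_alt)
    father <- rbinom(2, 1, p_alt)
    draw_child <- function()
      mother[sample.int(2, 1)] + father[sample.int(2, 1)]
    g1 <- draw_child()
    if (length(idx) == 1L) {
      dos[idx] <- g1
    } else if (samples$zygosity[idx[1]] == "MZ") {
      dos[idx] <- g1
    } else {
      dos[idx] <- c(g1, draw_child())
    }
  }
  dos
}

#' Simulate a twin cohort with known ground truth
#'
#' Generates a complete synthetic dataset: sample metadata (twin structure,
#' ages, technical covariates), exon-level expression counts with an
#' ACE-structured latent signal (MZ co-twin covariance
#' \eqn{\sigma^2_A + \sigma^2_C}, DZ
#' \eqn{\sigma^2_A/2 + \sigma^2_C}), age effects on the mean,
#' age-dependent dispersion and MZ divergence, cis genotypes transmitted
#' through simulated parental haplotypes, and methylation probes.  Counts
#' are produced by mapping the latent Gaussian signal through `exp()`,
#' scaling columns to the configured library size and Poisson sampling;
#' the noise-free latent matrix is kept in the ground truth.
#'
#' @param config a [sim_config()] object.
#' @return A `twin_cohort` list with elements `samples`, `expression`
#'   ([feature_matrix()]), `genotypes` ([genotype_matrix()]), `methylation`
#'   ([methylation_matrix()] or `NULL`), `truth` (per-gene generating
#'   parameters plus the latent matrix), and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_config("config", "must be a sim_config object")
  with_local_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n_fam <- config$n_mz_pairs + config$n_dz_pairs + config$n_singletons
  fam_zyg <- rep(c("MZ", "DZ", "singleton"),
                 c(config$n_mz_pairs, config$n_dz_pairs,
                   config$n_singletons))
  fam_size <- ifelse(fam_zyg == "singleton", 1L, 2L)
  fam_id <- sprintf("F%04d", seq_len(n_fam))
  fam_age <- runif(n_fam, config$age_range[1], config$age_range[2])

  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(sum(fam_size))),
    individual_id = unlist(lapply(seq_len(n_fam), function(i)
      sprintf("%s.%d", fam_id[i], seq_len(fam_size[i])))),
    family_id = rep(fam_id, fam_size),
    zygosity = rep(fam_zyg, fam_size),
    age = rep(fam_age, fam_size),
    tissue = config$tissue,
    stringsAsFactors = FALSE)
  n <- nrow(samples)

  # technical covariates; fixed-effect sizes below are small but nonzero so
  # covariate removal is exercised
  samples$insert_size <- rnorm(n, 280, 20)
  samples$gc_mean <- rnorm(n, 0.47, 0.02)
  samples$batch <- sample(c("b1", "b2"), n, replace = TRUE)
  samples$primer_index <- sample(sprintf("idx%02d", 1:8), n, replace = TRUE)
  samples$seq_date <- sample(sprintf("d%02d", 1:6), n, replace = TRUE)
  tech_shift <- 0.15 * scale(samples$insert_size)[, 1] +
    0.15 * scale(samples$gc_mean)[, 1] +
    0.10 * (samples$batch == "b2")

  age_mid <- mean(config$age_range)
  age_c <- samples$age - age_mid
  age_from_min <- samples$age - config$age_range[1]

  profiles <- rep(config$effect_profiles,
                  length.out = config$n_genes)
  n_ex <- if (config$exons_per_gene_range[1] ==
              config$exons_per_gene_range[2])
    rep(config$exons_per_gene_range[1], config$n_genes)
  else sample(config$exons_per_gene_range[1]:config$exons_per_gene_range[2],
              config$n_genes, replace = TRUE)

  gene_id <- sprintf("G%04d", seq_len(config$n_genes))
  gene_start <- seq_len(config$n_genes) * 3e6
  fam_index <- match(samples$family_id, fam_id)

  feat_rows <- vector("list", config$n_genes)
  latent_rows <- vector("list", config$n_genes)
  geno_rows <- list()
  geno_ann <- list()
  meth_rows <- list()
  meth_ann <- list()
  truth <- vector("list", config$n_genes)

  for (g in seq_len(config$n_genes)) {
    pr <- profiles[[g]]
    # ACE latent components (unit total non-age variance)
    z_fam <- rnorm(n_fam)
    z_ind <- rnorm(n)
    a <- sqrt(pr$sigma2_A) * ifelse(
      samples$zygosity == "MZ", z_fam[fam_index],
      ifelse(samples$zygosity == "DZ",
             sqrt(0.5) * (z_fam[fam_index] + z_ind), z_ind))
    svec <- pr$var_slope ^ age_c
    c_comp <- sqrt(pr$sigma2_C) * rnorm(n_fam)[fam_index] * svec
    e_fam_part <- sqrt(pr$sigma2_E) * sqrt(0.5) * rnorm(n)
    disc <- rnorm(n, 0, pr$discordance_slope * age_from_min)

    core <- pr$beta_age * age_c + a + c_comp + e_fam_part + disc

    snp_id <- NA_character_
    if (!is.null(pr$gxage)) {
      p_alt <- pr$gxage$maf
      dos <- sim_snp_dosages(samples, p_alt)
      gc_dos <- dos - 2 * p_alt
      core <- core + pr$gxage$beta_main * gc_dos +
        pr$gxage$beta_interaction * gc_dos * age_c
      snp_id <- sprintf("%s_snp0", gene_id[g])
      geno_rows[[snp_id]] <- dos
      geno_ann[[snp_id]] <- data.frame(
        variant_id = snp_id, chrom = "1",
        pos = gene_start[g] + 1L - sample(1e3:9e5, 1), ref = "A", alt = "G",
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(config$n_null_snps)) {
      vid <- sprintf("%s_null%d", gene_id[g], k)
      geno_rows[[vid]] <- sim_snp_dosages(samples, runif(1, 0.1, 0.5))
      geno_ann[[vid]] <- data.frame(
        variant_id = vid, chrom = "1",
        pos = gene_start[g] + 1L + sample(1e3:9e5, 1), ref = "A", alt = "C",
        stringsAsFactors = FALSE)
    }

    probe_id <- NA_character_
    if (!is.null(pr$meth)) {
      m <- rbeta(n, 2, 2)
      core <- core + pr$meth$beta_meth * (m - 0.5) +
        pr$meth$beta_meth_x_age * (m - 0.5) * age_c
      probe_id <- sprintf("%s_cg1", gene_id[g])
      meth_rows[[probe_id]] <- m
      meth_ann[[probe_id]] <- data.frame(
        probe_id = probe_id, chrom = "1", pos = gene_start[g] + 500L,
        gene_id = gene_id[g], stringsAsFactors = FALSE)
    }

    # exon-level values: gene core plus exon-specific unique environment
    ex <- matrix(0, n_ex[g], n)
    for (e in seq_len(n_ex[g]))
      ex[e, ] <- core + sqrt(pr$sigma2_E) * sqrt(0.5) * rnorm(n)
    latent_rows[[g]] <- ex
    feat_rows[[g]] <- data.frame(
      feature_id = sprintf("%s_ex%02d", gene_id[g], seq_len(n_ex[g])),
      gene_id = gene_id[g], feature_kind = "exon", chrom = "1",
      start = gene_start[g] + (seq_len(n_ex[g]) - 1L) * 1000L,
      end = gene_start[g] + (seq_len(n_ex[g]) - 1L) * 1000L + 200L,
      strand = "+", tss = gene_start[g], stringsAsFactors = FALSE)

    truth[[g]] <- data.frame(
      gene_id = gene_id[g], n_exons = n_ex[g], beta_age = pr$beta_age,
      var_slope = pr$var_slope, discordance_slope = pr$discordance_slope,
      sigma2_A = pr$sigma2_A, sigma2_C = pr$sigma2_C,
      sigma2_E = pr$sigma2_E,
      gxage_maf = if (is.null(pr$gxage)) NA_real_ else pr$gxage$maf,
      gxage_beta_main = if (is.null(pr$gxage)) NA_real_ else
        pr$gxage$beta_main,
      gxage_beta_interaction = if (is.null(pr$gxage)) NA_real_ else
        pr$gxage$beta_interaction,
      snp_id = snp_id,
      meth_beta = if (is.null(pr$meth)) NA_real_ else pr$meth$beta_meth,
      meth_beta_x_age = if (is.null(pr$meth)) NA_real_ else
        pr$meth$beta_meth_x_age,
      probe_id = probe_id, stringsAsFactors = FALSE)
  }

  if (config$n_genes == 0L) {
    feat_rows <- list(data.frame(
      feature_id = character(), gene_id = character(),
      feature_kind = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), tss = integer(),
      stringsAsFactors = FALSE))
    latent_rows <- list(matrix(numeric(0), 0, n))
  }
  annotation <- do.call(rbind, feat_rows)
  latent <- do.call(rbind, latent_rows)
  rownames(latent) <- annotation$feature_id
  colnames(latent) <- samples$sample_id

  # counts: exp-mapped latent signal, columns scaled to the library size,
  # then Poisson-rounded
  log_base <- rnorm(nrow(latent), log(200), 0.7)
  lam <- exp(0.5 * sweep(latent, 2, tech_shift, `+`) + log_base)
  lam <- sweep(lam, 2, config$library_scale / colSums(lam), `*`)
  counts <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam),
                   dimnames = dimnames(latent))
  expr <- feature_matrix(counts, annotation)

  genotypes <- NULL
  if (length(geno_rows)) {
    dos <- do.call(rbind, geno_rows)
    colnames(dos) <- samples$sample_id
    genotypes <- genotype_matrix(dos, do.call(rbind, geno_ann))
  }
  methylation <- NULL
  if (length(meth_rows)) {
    mb <- do.call(rbind, meth_rows)
    colnames(mb) <- samples$sample_id
    methylation <- methylation_matrix(mb, do.call(rbind, meth_ann))
  }

  truth_genes <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), n_exons = integer(),
               beta_age = numeric(), stringsAsFactors = FALSE)
  structure(list(samples = validate_samples(samples), expression = expr,
                 genotypes = genotypes, methylation = methylation,
                 truth = list(genes = truth_genes, latent = latent),
                 config = config),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  zt <- table(factor(x$samples$zygosity, c("MZ", "DZ", "singleton")))
  cat(sprintf(
    "<twin_cohort> %d samples (%d MZ, %d DZ, %d singletons)\n",
    nrow(x$samples), zt[["MZ"]], zt[["DZ"]], zt[["singleton"]]))
  cat(sprintf("  %d features / %d genes; ages %.1f-%.1f\n",
              nrow(x$expression$values),
              length(unique(x$expression$annotation$gene_id)),
              min(x$samples$age), max(x$samples$age)))
  invisible(x)
}
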