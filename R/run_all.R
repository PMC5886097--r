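#' Pipeline configuration
#'
#' Bundles the thresholds and covariate lists used by [run_all()].
#' Defaults follow the analysis design the package implements: adjusted-p
#' significance at 0.05, gene zero-count filter at 10%, library scale 1e7
#' reads, cis window TSS +/- 1 Mb, MAF floor 0.05, methylation
#' interaction threshold 1e-4, variance-gene prescreen at nominal p <
#' 0.1, 100 permutations for the expression/variance/discordance scans
#' and 10 residual permutations for GxAge.
#'
#' @param tissue tissue label; "blood" adds `batch` to the fixed
#'   covariates.
#' @param fixed technical fixed-effect columns; `NULL` picks the
#'   tissue-appropriate default.
#' @param alpha,zero_fraction,maf_min,window,meth_threshold,variance_prescreen
#'   analysis thresholds (see above).
#' @param n_perm,n_perm_gxage permutation counts.
#' @param n_strata exon-count strata for empirical adjustment.
#' @param library_scale count-scaling target.
#' @param min_mz_pairs minimum complete MZ pairs for the discordance
#'   stage.
#' @param seed master seed; stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(tissue = "skin", fixed = NULL, alpha = 0.05,
                       zero_fraction = 0.10, maf_min = 0.05,
                       window = 1e6, meth_threshold = 1e-4,
                       variance_prescreen = 0.1, n_perm = 100,
                       n_perm_gxage = 10, n_strata = 16,
                       library_scale = 1e7, min_mz_pairs = 20, seed = 1) {
  if (is.null(fixed))
    fixed <- c("insert_size", "gc_mean",
               if (tissue == "blood") "batch")
  for (f in c("alpha", "zero_fraction", "maf_min")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_config(f, "must lie in [0, 1]")
  }
  if (window <= 0) stop_config("window", "must be > 0")
  if (!is_count(n_perm) || n_perm < 1)
    stop_config("n_perm", "must be a positive integer")
  if (!is_count(n_perm_gxage) || n_perm_gxage < 1)
    stop_config("n_perm_gxage", "must be a positive integer")
  structure(list(tissue = tissue, fixed = fixed, alpha = alpha,
                 zero_fraction = zero_fraction, maf_min = maf_min,
                 window = window, meth_threshold = meth_threshold,
                 variance_prescreen = variance_prescreen, n_perm = n_perm,
                 n_perm_gxage = n_perm_gxage, n_strata = n_strata,
                 library_scale = library_scale,
                 min_mz_pairs = min_mz_pairs, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline on one cohort
#'
#' Drives every stage on a cohort (simulated in memory or read from a
#' [write_cohort()] directory): validation, gene zero-count filtering,
#' library scaling, rank-inverse-normal transform, the age-mean LRT scan,
#' the age-variance scan, the MZ discordance scan, per-feature ACE(+age)
#' decomposition, the cis GxAge interaction scan on features with any
#' age-related effect, and the methylation-by-age test on variance
#' prescreen genes.  Results are written as TSV files plus a
#' `manifest.json` recording the configuration, seed, package version
#' and file checksums.  Reruns with the same cohort, config and seed are
#' identical.
#'
#' @param cohort a `twin_cohort` or a directory path.
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with each stage's result object.
#' @export
run_all <- function(cohort, config = run_config(), out_dir) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!inherits(cohort, "twin_cohort"))
    stop_validation("`cohort` must be a twin_cohort or a directory path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)

  samples <- validate_samples(cohort$samples)
  fm <- cohort$expression
  flagged <- flag_zero_genes(fm, config$zero_fraction)
  if (length(flagged)) {
    logf("zero_filter: removing %d gene(s): %s", length(flagged),
         paste(flagged, collapse = ","))
    keep <- !(fm$annotation$gene_id %in% flagged)
    fm <- feature_matrix(fm$values[keep, , drop = FALSE],
                         fm$annotation[keep, , drop = FALSE])
  }
  fm <- scale_counts(fm, target = config$library_scale)
  rint <- rint_matrix(fm$values)
  ann <- fm$annotation[match(rownames(rint), fm$annotation$feature_id), ]

  wt <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  mean_scan <- age_mean_scan(rint, samples, ann, fixed = config$fixed,
                             n_perm = config$n_perm,
                             n_strata = config$n_strata,
                             alpha = config$alpha,
                             seed = config$seed + 101)
  wt(mean_scan$features, "age_mean_features.tsv")
  wt(mean_scan$genes, "age_mean_genes.tsv")
  logf("age_mean: %d/%d genes significant",
       sum(mean_scan$genes$significant), nrow(mean_scan$genes))

  resid_var <- residualize_for_variance(rint, samples,
                                        fixed = config$fixed)
  var_scan <- age_variance_scan(resid_var, samples, ann,
                                n_perm = config$n_perm,
                                n_strata = config$n_strata,
                                alpha = config$alpha,
                                seed = config$seed + 202)
  wt(var_scan$features, "age_variance_features.tsv")
  wt(var_scan$genes, "age_variance_genes.tsv")
  logf("age_variance: %d/%d genes significant",
       sum(var_scan$genes$significant), nrow(var_scan$genes))

  resid_tech <- residualize_technical(rint, samples, fixed = config$fixed)
  disc_scan <- NULL
  n_mz <- sum(table(samples$family_id[samples$zygosity == "MZ"]) == 2L)
  if (n_mz >= config$min_mz_pairs) {
    disc_scan <- discordance_scan(resid_tech, samples, ann,
                                  min_pairs = config$min_mz_pairs,
                                  n_perm = config$n_perm,
                                  n_strata = config$n_strata,
                                  alpha = config$alpha,
                                  seed = config$seed + 303)
    wt(disc_scan$features, "discordance_features.tsv")
    wt(disc_scan$genes, "discordance_genes.tsv")
    logf("discordance: %d/%d genes significant",
         sum(disc_scan$genes$significant), nrow(disc_scan$genes))
  } else {
    logf("discordance: skipped, only %d complete MZ pairs", n_mz)
  }

  herit <- tryCatch(ace_scan(resid_tech, samples),
                    twinage_validation_error = function(e) {
                      logf("heritability: skipped (%s)",
                           conditionMessage(e))
                      NULL
                    })
  if (!is.null(herit)) {
    herit$gene_id <- ann$gene_id[match(herit$feature_id,
                                       ann$feature_id)]
    wt(herit, "heritability.tsv")
    logf("heritability: median h2 = %.3f, median pve_age = %.3f",
         median(herit$h2), median(herit$pve_age))
  }

  # interaction scans use conditional residuals (family BLUP removed)
  resid_cond <- NULL
  if (!is.null(cohort$genotypes) || !is.null(cohort$methylation))
    resid_cond <- twin_conditional_residuals(
      rint, build_design(samples, config$fixed), samples)

  gxage <- NULL
  if (!is.null(cohort$genotypes)) {
    eligible <- unique(c(
      mean_scan$features$feature_id[mean_scan$features$significant],
      var_scan$features$feature_id[var_scan$features$significant],
      if (!is.null(disc_scan))
        disc_scan$features$feature_id[disc_scan$features$significant]))
    if (length(eligible)) {
      scan <- gxage_scan(resid_cond, cohort$genotypes, samples, ann,
                         eligible = eligible, window = config$window,
                         maf_min = config$maf_min)
      n_ex <- table(ann$gene_id)
      gxage <- gxage_adjust(scan, resid_cond, cohort$genotypes, samples,
                            setNames(as.integer(n_ex), names(n_ex)),
                            n_perm = config$n_perm_gxage,
                            n_strata = config$n_strata,
                            fdr = config$alpha,
                            seed = config$seed + 404)
      wt(gxage$features, "gxage_features.tsv")
      wt(gxage$genes, "gxage_genes.tsv")
      logf("gxage: %d eligible features, %d significant at FDR %.2g",
           length(eligible), sum(gxage$features$significant),
           config$alpha)
    } else logf("gxage: skipped, no eligible features")
  }

  meth <- NULL
  if (!is.null(cohort$methylation)) {
    pre_genes <- unique(var_scan$features$gene_id[
      var_scan$features$p_nominal < config$variance_prescreen])
    if (length(pre_genes)) {
      meth_resid <- twin_conditional_residuals(
        cohort$methylation$betas, build_design(samples, config$fixed),
        samples)
      meth <- meth_age_test(
        resid_cond, meth_resid, samples$age,
        setNames(ann$gene_id, ann$feature_id),
        setNames(cohort$methylation$annotation$gene_id,
                 cohort$methylation$annotation$probe_id),
        genes = pre_genes, p_threshold = config$meth_threshold)
      wt(meth, "meth_age.tsv")
      logf("meth_age: %d pairs tested, %d significant", nrow(meth),
           sum(meth$significant))
    } else logf("meth_age: skipped, no prescreen genes")
  }

  manifest <- list(
    package = "twinage",
    version = as.character(packageVersion("twinage")),
    seed = config$seed,
    config = unclass(config),
    n_samples = nrow(samples), n_features = nrow(rint),
    flagged_genes = as.list(flagged),
    files = as.list(tools::md5sum(list.files(out_dir,
                                             pattern = "\\.tsv$",
                                             full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(age_mean = mean_scan, age_variance = var_scan,
                 discordance = disc_scan, heritability = herit,
                 gxage = gxage, meth = meth, flagged_genes = flagged))
}
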