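#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits `expression.tsv` (features x samples, first column `feature_id`),
#' `features.tsv` (BED-like annotation: chrom, start, end, feature_id,
#' gene_id, strand, tss; 0-based half-open), `samples.tsv`,
#' `genotypes.vcf` (VCF 4.2 with GT and DS), `methylation.tsv` +
#' `probes.tsv`, and `truth.tsv`.  Files round-trip losslessly through
#' [read_cohort()].
#'
#' @param cohort a `twin_cohort` from [simulate_cohort()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "twin_cohort"))
    stop_validation("`cohort` must be a twin_cohort object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop_validation("cannot create directory `%s`", dir)

  write_matrix_tsv(cohort$expression$values, "feature_id",
                   file.path(dir, "expression.tsv"))
  ann <- cohort$expression$annotation
  write.table(ann[, c("chrom", "start", "end", "feature_id", "gene_id",
                      "strand", "tss", "feature_kind")],
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$genotypes))
    write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  if (!is.null(cohort$methylation)) {
    write_matrix_tsv(cohort$methylation$betas, "probe_id",
                     file.path(dir, "methylation.tsv"))
    write.table(cohort$methylation$annotation, file.path(dir, "probes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(cohort$truth$genes, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(cohort$truth$latent, "feature_id",
                   file.path(dir, "latent.tsv"))
  invisible(dir)
}

write_matrix_tsv <- function(m, id_col, path) {
  df <- data.frame(rownames(m) %||% character(0), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop_validation("%s: no columns", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (length(ids) && !is.numeric(m))
    stop_validation("%s: non-numeric values in matrix body", path)
  rownames(m) <- ids
  m
}

#' Read an expression matrix with its feature annotation
#'
#' Joins the count matrix to the annotation, validates ids, and flags genes
#' exceeding the zero-count threshold: a gene is flagged for removal when
#' more than `zero_fraction` of its count entries (across its features and
#' all samples) are zero.
#'
#' @param matrix_path TSV, first column `feature_id`, one column per sample.
#' @param annotation_path TSV with columns chrom, start, end, feature_id,
#'   gene_id, strand and optionally tss, feature_kind.
#' @param samples optional sample table; when given, matrix columns must
#'   match `samples$sample_id` exactly (any mismatch is an error naming the
#'   offending samples).
#' @param zero_fraction threshold for the gene-level zero-count filter
#'   (default 0.10).
#' @return A [feature_matrix()] with attribute `flagged_genes` (character
#'   vector of gene ids exceeding the threshold).
#' @export
read_expression <- function(matrix_path, annotation_path, samples = NULL,
                            zero_fraction = 0.10) {
  m <- read_matrix_tsv(matrix_path)
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "feature_id", "gene_id", "strand")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop_validation("%s: missing column(s) %s", annotation_path,
                    paste(miss, collapse = ", "))
  if (anyDuplicated(ann$feature_id))
    stop_validation("%s: duplicated feature ids: %s", annotation_path,
                    paste(unique(ann$feature_id[duplicated(ann$feature_id)]),
                          collapse = ", "))
  missing_feat <- setdiff(rownames(m), ann$feature_id)
  if (length(missing_feat))
    stop_validation("%s: features absent from annotation: %s", matrix_path,
                    paste(utils::head(missing_feat, 5), collapse = ", "))
  ann <- ann[match(rownames(m), ann$feature_id), , drop = FALSE]
  if (is.null(ann$feature_kind)) ann$feature_kind <- "exon"
  if (!is.null(samples)) {
    extra <- setdiff(colnames(m), samples$sample_id)
    if (length(extra))
      stop_validation("expression samples absent from metadata: %s",
                      paste(extra, collapse = ", "))
    m <- m[, samples$sample_id, drop = FALSE]
  }
  if (any(m < 0)) stop_validation("%s: negative counts", matrix_path)
  fm <- feature_matrix(m, ann)
  attr(fm, "flagged_genes") <- flag_zero_genes(fm, zero_fraction)
  fm
}

#' Genes exceeding the zero-count fraction threshold
#'
#' @param fm a [feature_matrix()] of raw counts.
#' @param zero_fraction maximum tolerated fraction of zero entries per gene.
#' @return Character vector of gene ids whose zero fraction exceeds the
#'   threshold (strictly greater).
#' @export
flag_zero_genes <- function(fm, zero_fraction = 0.10) {
  zf <- tapply(rowMeans(fm$values == 0), fm$annotation$gene_id, mean)
  names(zf)[zf > zero_fraction]
}

#' Scale count columns to a common library size
#'
#' Multiplies each sample column by `target / column sum`.
#'
#' @param fm a [feature_matrix()] of non-negative counts.
#' @param target library size to scale to (default 1e7 reads).
#' @return A [feature_matrix()] with scaled values.
#' @export
scale_counts <- function(fm, target = 1e7) {
  cs <- colSums(fm$values)
  if (any(cs == 0))
    stop_validation("zero-sum sample column(s): %s",
                    paste(colnames(fm$values)[cs == 0], collapse = ", "))
  fm$values <- sweep(fm$values, 2, target / cs, `*`)
  fm
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles of their (mid-offset) ranks:
#' \eqn{\Phi^{-1}((r_i - c) / n)} with offset `c = 0.5`.  Ties receive the
#' average rank; the output order matches the input order.
#'
#' @param x numeric vector, length >= 3, not all values identical.
#' @param offset rank offset `c` in the quantile argument (default 0.5,
#'   symmetric and finite at the extremes).
#' @return Numeric vector of the same length.
#' @export
rank_inverse_normal <- function(x, offset = 0.5) {
  if (length(x) < 3L)
    stop_validation("rank_inverse_normal needs length >= 3")
  if (anyNA(x)) stop_validation("rank_inverse_normal: missing values")
  if (max(x) == min(x))
    stop_validation("rank_inverse_normal: constant (degenerate) feature")
  qnorm((rank(x, ties.method = "average") - offset) / length(x))
}

#' Rank-inverse-normal transform every feature of a matrix
#'
#' Constant (degenerate) features are dropped with a message naming them.
#'
#' @param values numeric matrix, features x samples.
#' @return Transformed matrix, possibly with fewer rows.
#' @export
rint_matrix <- function(values) {
  const <- apply(values, 1L, function(r) max(r) == min(r))
  if (any(const))
    message(sprintf("dropping %d constant feature(s): %s", sum(const),
                    paste(utils::head(rownames(values)[const], 5),
                          collapse = ", ")))
  t(apply(values[!const, , drop = FALSE], 1L, rank_inverse_normal))
}

#' Read the sample metadata table
#'
#' @param path TSV with the columns documented in [validate_samples()].
#' @return Validated sample data.frame.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  validate_samples(read.delim(path, stringsAsFactors = FALSE))
}

#' Write genotype dosages as VCF 4.2
#'
#' Integer dosages are emitted as GT plus a DS field; fractional dosages as
#' `./.` GT with DS carrying the value.
#'
#' @param geno a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  ann <- geno$annotation
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=twinage",
    paste0("##contig=<ID=", paste(unique(ann$chrom)), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
           "Description=\"Alternate allele dosage\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno$dosages)), collapse = "\t")), con)
  gt_of <- function(d) {
    if (is.na(d)) return("./.:.")
    gt <- if (abs(d - round(d)) < 1e-9)
      c("0/0", "0/1", "1/1")[round(d) + 1L] else "./."
    sprintf("%s:%s", gt, format(d, trim = TRUE, digits = 6))
  }
  for (i in seq_len(nrow(ann))) {
    fields <- vapply(geno$dosages[i, ], gt_of, character(1))
    writeLines(paste(c(ann$chrom[i], ann$pos[i], ann$variant_id[i],
                       ann$ref[i], ann$alt[i], ".", "PASS", ".", "GT:DS",
                       fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Dosages are taken from the DS field when present, otherwise computed
#' from GT (alternate-allele count).  Multi-allelic sites are skipped with
#' a message.  MAF is recomputed from the loaded samples.
#'
#' @param path VCF 4.x file (plain or gzipped).
#' @param samples optional character vector restricting and ordering the
#'   sample columns; missing samples are an error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    message(sprintf("skipping %d multi-allelic site(s)", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(vapply(gt, function(g) {
      if (is.na(g) || g %in% c("./.", ".")) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
    }, numeric(1)), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(ds))
    if (length(miss))
      stop_validation("samples absent from VCF: %s",
                      paste(miss, collapse = ", "))
    ds <- ds[, samples, drop = FALSE]
  }
  ann <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF,
                    alt = fix$ALT, stringsAsFactors = FALSE)
  rownames(ds) <- ann$variant_id
  genotype_matrix(ds, ann)
}

#' Read a methylation beta matrix with its probe annotation
#'
#' @param path TSV, first column `probe_id`, one column per sample.
#' @param annotation_path TSV with columns probe_id, chrom, pos, gene_id.
#' @return A [methylation_matrix()]; probes with missing values excluded.
#' @export
read_methylation <- function(path, annotation_path) {
  m <- read_matrix_tsv(path)
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos", "gene_id")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop_validation("%s: missing column(s) %s", annotation_path,
                    paste(miss, collapse = ", "))
  ann <- ann[match(rownames(m), ann$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id))
    stop_validation("%s: probes absent from annotation", path)
  methylation_matrix(m, ann)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the files emitted by [write_cohort()].
#' @return A `twin_cohort`-like list (without the generating config).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop_validation("directory not found: %s", dir)
  samples <- read_samples(file.path(dir, "samples.tsv"))
  expr <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "features.tsv"), samples = samples)
  geno <- NULL
  if (file.exists(file.path(dir, "genotypes.vcf")))
    geno <- read_vcf(file.path(dir, "genotypes.vcf"),
                     samples = samples$sample_id)
  meth <- NULL
  if (file.exists(file.path(dir, "methylation.tsv")))
    meth <- read_methylation(file.path(dir, "methylation.tsv"),
                             file.path(dir, "probes.tsv"))
  truth <- NULL
  if (file.exists(file.path(dir, "truth.tsv")))
    truth <- list(genes = read.delim(file.path(dir, "truth.tsv"),
                                     stringsAsFactors = FALSE),
                  latent = if (file.exists(file.path(dir, "latent.tsv")))
                    read_matrix_tsv(file.path(dir, "latent.tsv")) else NULL)
  structure(list(samples = samples, expression = expr, genotypes = geno,
                 methylation = meth, truth = truth, config = NULL),
            class = "twin_cohort")
}
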