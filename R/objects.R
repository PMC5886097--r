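#' Expression feature matrix with genomic annotation
#'
#' Container for exon- or splicing-link-level expression values together
#' with their feature annotation.  Rows are features, columns samples.
#' Coordinates are stored 0-based half-open; `tss` defaults to `start` on
#' the + strand and `end` on the - strand.
#'
#' @param values numeric matrix, features x samples, non-negative for raw
#'   counts.  Row names are feature ids.
#' @param annotation data.frame with columns `feature_id`, `gene_id`,
#'   `feature_kind` ("exon" or "link"), `chrom`, `start`, `end`, `strand`
#'   and optionally `tss`.
#' @return An object of class `feature_matrix` with elements `values` and
#'   `annotation`.
#' @export
feature_matrix <- function(values, annotation) {
  values <- as.matrix(values)
  if (anyDuplicated(annotation$feature_id))
    stop_validation("duplicated feature ids: %s",
                    paste(unique(annotation$feature_id[
                      duplicated(annotation$feature_id)]), collapse = ", "))
  if (nrow(values) != nrow(annotation))
    stop_validation("values has %d rows but annotation has %d",
                    nrow(values), nrow(annotation))
  if (is.null(rownames(values))) rownames(values) <- annotation$feature_id
  if (nrow(values) > 0L &&
      !identical(rownames(values), as.character(annotation$feature_id)))
    stop_validation("row names of values do not match annotation$feature_id")
  need <- c("feature_id", "gene_id", "feature_kind", "chrom", "start",
            "end", "strand")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop_validation("annotation missing column(s): %s",
                    paste(miss, collapse = ", "))
  if (is.null(annotation$tss))
    annotation$tss <- ifelse(annotation$strand == "-", annotation$end,
                             annotation$start)
  structure(list(values = values, annotation = annotation),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d samples (%d genes)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$annotation$gene_id))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Genotype dosage matrix
#'
#' @param dosages numeric matrix, variants x samples, values in \[0, 2\]
#'   (alternate-allele dosage).  Row names are variant ids.
#' @param annotation data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based, as in VCF), `ref`, `alt`.  A `maf` column is recomputed from
#'   the loaded samples.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, annotation) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(annotation))
    stop_validation("dosages has %d rows but annotation has %d",
                    nrow(dosages), nrow(annotation))
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stop_validation("dosages outside [0, 2]")
  if (is.null(rownames(dosages))) rownames(dosages) <- annotation$variant_id
  p <- rowMeans(dosages, na.rm = TRUE) / 2
  annotation$maf <- pmin(p, 1 - p)
  structure(list(dosages = dosages, annotation = annotation),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variants x %d samples\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Methylation beta-value matrix
#'
#' @param betas numeric matrix, probes x samples, values in \[0, 1\].
#'   Probes with any missing value are excluded (with a message).
#' @param annotation data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `gene_id` mapping each probe to a gene.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(betas, annotation) {
  betas <- as.matrix(betas)
  if (nrow(betas) != nrow(annotation))
    stop_validation("betas has %d rows but annotation has %d",
                    nrow(betas), nrow(annotation))
  if (is.null(rownames(betas))) rownames(betas) <- annotation$probe_id
  keep <- stats::complete.cases(betas)
  if (!all(keep)) {
    message(sprintf("excluding %d probe(s) with missing values",
                    sum(!keep)))
    betas <- betas[keep, , drop = FALSE]
    annotation <- annotation[keep, , drop = FALSE]
  }
  if (any(betas < 0 | betas > 1))
    stop_validation("methylation betas outside [0, 1]")
  structure(list(betas = betas, annotation = annotation),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d probes x %d samples\n",
              nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' Checks the invariants of the twin design: unique sample ids, at most two
#' individuals per family, co-twins sharing zygosity and age (co-twins are
#' sampled on the same visit), ages within \[0, 120\].
#'
#' @param samples data.frame with columns `sample_id`, `individual_id`,
#'   `family_id`, `zygosity` ("MZ", "DZ" or "singleton"), `age`, `tissue`,
#'   plus any technical covariate columns.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "individual_id", "family_id", "zygosity", "age",
            "tissue")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop_validation("sample table missing column(s): %s",
                    paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop_validation("duplicated sample ids: %s",
                    paste(unique(samples$sample_id[
                      duplicated(samples$sample_id)]), collapse = ", "))
  if (!all(samples$zygosity %in% c("MZ", "DZ", "singleton")))
    stop_validation("zygosity values outside {MZ, DZ, singleton}")
  if (any(is.na(samples$age)) || any(samples$age < 0 | samples$age > 120))
    stop_validation("ages must lie within [0, 120]")
  sp <- split(samples, samples$family_id)
  for (fam in sp) {
    if (nrow(fam) > 2L)
      stop_validation("family `%s` has more than 2 samples",
                      fam$family_id[1L])
    if (nrow(fam) == 2L) {
      if (length(unique(fam$zygosity)) != 1L)
        stop_validation("co-twins in family `%s` differ in zygosity",
                        fam$family_id[1L])
      if (diff(range(fam$age)) > 1e-8)
        stop_validation("co-twins in family `%s` differ in age",
                        fam$family_id[1L])
    }
  }
  samples
}
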