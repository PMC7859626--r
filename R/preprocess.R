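# Gene/subject filtering and conditional upper-quartile normalization.
#
# Fixed pipeline order (enforced by preprocess_counts): zero-prevalence gene
# filter -> low-read subject filter -> UQ normalization -> low-normalized
# gene filter. All prevalence comparisons are strict ("over" a threshold),
# checked in integer arithmetic so boundary cases are exact.

#' Remove genes with zero counts in over one third of subjects
#'
#' A gene is removed when its zero-count fraction strictly exceeds 1/3;
#' a gene with zeros in exactly one third of subjects is retained.
#'
#' @param counts a [count_matrix()] (or coercible matrix).
#' @return filtered [count_matrix()], gene order preserved. Attribute
#'   `"removed"` holds the removed gene identifiers.
#' @export
filter_genes_zero_prevalence <- function(counts) {
  counts <- as_counts(counts)
  stopifnot(nrow(counts) >= 1, ncol(counts) >= 3)
  nzero <- rowSums(counts == 0)
  keep <- 3 * nzero <= ncol(counts)     # strict: remove iff nzero/n > 1/3
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("all genes removed by zero-prevalence filter")
  class(out) <- class(counts)
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}

#' Remove subjects dominated by zero/low raw counts
#'
#' A subject is removed when the fraction of genes with raw count at or
#' below `raw_low` strictly exceeds `prevalence`.
#'
#' @inheritParams filter_genes_zero_prevalence
#' @param raw_low raw-count threshold defining a "low" gene (default 5).
#' @param prevalence fraction of low genes above which the subject is
#'   excluded (default 0.75, strict).
#' @return filtered [count_matrix()]; attribute `"removed"` as above.
#' @export
filter_subjects_low_reads <- function(counts, raw_low = 5, prevalence = 0.75) {
  counts <- as_counts(counts)
  stopifnot(raw_low > 0, prevalence > 0)
  nlow <- colSums(counts <= raw_low)
  # strict inequality via rationals: nlow/n > prevalence
  keep <- nlow <= prevalence * nrow(counts)
  if (!any(keep)) stop("low-read subject filter removed every subject")
  out <- counts[, keep, drop = FALSE]
  class(out) <- class(counts)
  attr(out, "removed") <- colnames(counts)[!keep]
  out
}

#' Conditional upper-quartile normalization
#'
#' For each subject the conditional upper quartile `UQ_s` is the 75th
#' percentile of that subject's non-zero counts (quantile type 7, linear
#' interpolation). The normalization factor is `f_s = UQ_s / mean(UQ)`, the
#' mean taken over all subjects in the matrix, so factors average to 1 by
#' construction. Normalized values are `raw / f_s`; after adding 1 to
#' accommodate zeros, values are log2 transformed.
#'
#' @inheritParams filter_genes_zero_prevalence
#' @param quantile_type quantile convention passed to [stats::quantile()]
#'   (default 7).
#' @return an object of class `uq_norm`: list with `log2_values`
#'   (genes x subjects), `norm_factors`, `conditional_uq`, and a
#'   `filter_report` (populated by [preprocess_counts()]).
#' @export
uq_normalize <- function(counts, quantile_type = 7) {
  counts <- as_counts(counts)
  nz_count <- colSums(counts > 0)
  if (any(nz_count == 0)) {
    stop("subject(s) with all-zero counts: ",
         paste(colnames(counts)[nz_count == 0], collapse = ", "))
  }
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    v <- counts[, j]
    quantile(v[v > 0], probs = 0.75, type = quantile_type, names = FALSE)
  }, numeric(1))
  names(uq) <- colnames(counts)
  f <- uq / mean(uq)
  norm <- sweep(unclass(counts), 2L, f, `/`)
  structure(
    list(
      log2_values = log2(norm + 1),
      norm_factors = f,
      conditional_uq = uq,
      filter_report = list()
    ),
    class = "uq_norm"
  )
}

#' @export
print.uq_norm <- function(x, ...) {
  cat(sprintf("uq_norm: %d genes x %d subjects (log2 UQ-normalized)\n",
              nrow(x$log2_values), ncol(x$log2_values)))
  invisible(x)
}

#' Pre-log normalized values of a `uq_norm` object
#'
#' Recovers `raw / f_s` from the stored log2 values (the +1 offset is
#' removed).
#' @param norm a `uq_norm` object.
#' @return numeric matrix of normalized (pre-log) values.
#' @export
norm_values <- function(norm) {
  stopifnot(inherits(norm, "uq_norm"))
  2^norm$log2_values - 1
}

#' Remove genes with a high prevalence of low normalized values
#'
#' A gene is removed when the fraction of subjects whose normalized
#' (pre-log) value is at or below `low` strictly exceeds `prevalence`.
#'
#' @param norm a `uq_norm` object from [uq_normalize()].
#' @param low normalized-count threshold (default 3).
#' @param prevalence strict exclusion fraction (default 0.75).
#' @return the filtered `uq_norm` object; attribute `"removed"`.
#' @export
filter_genes_low_normalized <- function(norm, low = 3, prevalence = 0.75) {
  stopifnot(inherits(norm, "uq_norm"))
  pre <- norm_values(norm)
  nlow <- rowSums(pre <= low + 1e-9)   # tolerate representation error at the boundary
  keep <- nlow <= prevalence * ncol(pre)
  removed <- rownames(pre)[!keep]
  norm$log2_values <- norm$log2_values[keep, , drop = FALSE]
  attr(norm, "removed") <- removed
  norm
}

#' Full preprocessing pipeline
#'
#' Applies, in fixed order: the zero-prevalence gene filter, the low-read
#' subject filter, conditional UQ normalization, and the low-normalized gene
#' filter. The order is not configurable; permuting it changes results, so
#' the pipeline exposes no reordering knobs.
#'
#' @inheritParams filter_genes_zero_prevalence
#' @inheritParams filter_subjects_low_reads
#' @inheritParams filter_genes_low_normalized
#' @return a `uq_norm` object whose `filter_report` records genes/subjects
#'   removed at each rule and the input/output dimensions.
#' @export
preprocess_counts <- function(counts, raw_low = 5, subject_prevalence = 0.75,
                              low = 3, gene_prevalence = 0.75) {
  counts <- as_counts(counts)
  dim_in <- dim(counts)
  s1 <- filter_genes_zero_prevalence(counts)
  s2 <- filter_subjects_low_reads(s1, raw_low = raw_low, prevalence = subject_prevalence)
  norm <- uq_normalize(s2)
  norm <- filter_genes_low_normalized(norm, low = low, prevalence = gene_prevalence)
  norm$filter_report <- list(
    input_genes = dim_in[1], input_subjects = dim_in[2],
    genes_removed_zero_prevalence = length(attr(s1, "removed")),
    subjects_removed_low_reads = length(attr(s2, "removed")),
    genes_removed_low_normalized = length(attr(norm, "removed")),
    output_genes = nrow(norm$log2_values),
    output_subjects = ncol(norm$log2_values),
    removed_subject_ids = attr(s2, "removed"),
    thresholds = list(raw_low = raw_low, subject_prevalence = subject_prevalence,
                      low = low, gene_prevalence = gene_prevalence)
  )
  norm
}

#' PCA-based sample outlier diagnostic (report only)
#'
#' Flags subjects whose PC1 or PC2 score (on the log2 matrix) lies more than
#' `k_sd` standard deviations from the mean. The flag is purely diagnostic:
#' no subject is ever excluded automatically, since outlier exclusion in
#' practice requires judgment (read-mapping quality, clustering review).
#'
#' @param norm a `uq_norm` object.
#' @param k_sd flagging threshold in SD units (default 4).
#' @return data.frame with subject_id, pc1, pc2, and `flagged`.
#' @export
flag_pca_outliers <- function(norm, k_sd = 4) {
  stopifnot(inherits(norm, "uq_norm"))
  x <- norm$log2_values
  xc <- x - rowMeans(x)
  sv <- svd(t(xc), nu = 2, nv = 0)
  pcs <- sv$u %*% diag(sv$d[1:2], 2, 2)
  z1 <- (pcs[, 1] - mean(pcs[, 1])) / sd(pcs[, 1])
  z2 <- (pcs[, 2] - mean(pcs[, 2])) / sd(pcs[, 2])
  data.frame(
    subject_id = colnames(x),
    pc1 = pcs[, 1], pc2 = pcs[, 2],
    flagged = abs(z1) > k_sd | abs(z2) > k_sd
  )
}
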