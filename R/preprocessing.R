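#' Filter genes with low read support
#'
#' Keeps genes observed at `min_count` reads or more in at least `min_samples`
#' samples. The default (10 reads in 16 samples, the exposure-group size)
#' retains genes that are reliably detectable in at least one full exposure
#' group.
#'
#' @param counts Integer matrix of counts, genes in rows (rownames = gene
#'   ids), samples in columns.
#' @param min_count Minimum read count for a sample to support a gene.
#' @param min_samples Minimum number of supporting samples.
#' @return The count matrix restricted to retained genes, row order preserved.
#' @export
filter_low_expression <- function(counts, min_count = 10, min_samples = 16) {
  counts <- validate_counts(counts)
  if (min_samples > ncol(counts)) {
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         ncol(counts), ")")
  }
  keep <- rowSums(counts >= min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants following the median-of-ratios convention:
#' each sample's counts are divided by the per-gene geometric mean across
#' samples, and the size factor is the median of these ratios over the
#' reference genes (genes with strictly positive counts in every sample).
#'
#' @param counts Count matrix, genes in rows.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
median_of_ratios_size_factors <- function(counts) {
  counts <- validate_counts(counts, allow_real = TRUE)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene has all-positive counts; size factors are undefined. ",
         "Filter samples or use a pseudo-reference normalization instead.")
  }
  logc <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(logc)
  # median over reference genes of count/geometric-mean; ties -> midpoint
  s <- apply(exp(logc - geo), 2, stats::median)
  names(s) <- colnames(counts)
  s
}

#' Log2 normalized expression
#'
#' `log2(count / size_factor + 1)`, the transform used for the network stage.
#'
#' @param counts Count matrix, genes in rows.
#' @param size_factors Positive per-sample size factors (recycled names
#'   checked against columns when both are named).
#' @return Real matrix of the same shape, all values >= 0.
#' @export
log2_normalize <- function(counts, size_factors) {
  counts <- validate_counts(counts, allow_real = TRUE)
  if (length(size_factors) != ncol(counts)) {
    stop("need one size factor per sample")
  }
  if (any(!is.finite(size_factors)) || any(size_factors <= 0)) {
    stop("size factors must be positive and finite")
  }
  if (!is.null(names(size_factors)) && !is.null(colnames(counts)) &&
      !identical(names(size_factors), colnames(counts))) {
    stop("size factor names do not match sample ids")
  }
  log2(sweep(counts, 2, size_factors, "/") + 1)
}

validate_counts <- function(counts, allow_real = FALSE) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (genes x samples)")
  }
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!allow_real && any(counts != round(counts))) {
    stop("counts must be integers")
  }
  if (!is.null(rownames(counts)) && anyDuplicated(rownames(counts))) {
    stop("duplicated gene ids")
  }
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts))) {
    stop("duplicated sample ids")
  }
  counts
}
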