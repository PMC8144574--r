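#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors estimated the way the NB-GLM RNA-Seq
#' family does it: for each sample, the median over genes of the ratio of its
#' count to the gene's geometric mean across samples, computed over genes
#' expressed in every sample, then rescaled to geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @return numeric vector of positive size factors, one per sample, with
#'   geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no gene has nonzero counts in all samples; ",
         "filter the matrix or check the input")
  lc <- log(counts[ok, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- exp(apply(lc - loggeo, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Filter features with low mean counts
#'
#' @param counts feature x sample matrix.
#' @param min_mean minimum mean raw count to retain a row (default 5).
#' @return filtered matrix; the fraction removed is reported via `message()`
#'   and stored in `attr(, "frac_removed")`.
#' @export
filter_low_counts <- function(counts, min_mean = 5) {
  keep <- rowMeans(counts) >= min_mean
  out <- counts[keep, , drop = FALSE]
  frac <- 1 - sum(keep) / nrow(counts)
  message(sprintf("filter_low_counts: removed %d/%d features (%.1f%%) with mean < %g",
                  sum(!keep), nrow(counts), 100 * frac, min_mean))
  attr(out, "frac_removed") <- frac
  out
}
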