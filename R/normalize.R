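# Library-size normalization and variance stabilization shared by all
# downstream modules.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes whose counts are positive in every sample, i.e. finite log geometric
#' mean) of the ratio between the sample's count and the gene's geometric
#' mean across samples.
#'
#' @param counts gene x sample count matrix.
#' @return named positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  zero_samples <- colnames(counts)[colSums(counts) == 0]
  if (length(zero_samples))
    stop("sample(s) with all-zero counts: ", paste(zero_samples, collapse = ", "))
  log_geo <- rowMeans(log(counts))
  if (!any(is.finite(log_geo)))
    stop("no gene has positive counts in every sample; size factors undefined")
  sf <- apply(counts, 2L, function(cnts) {
    ok <- is.finite(log_geo) & cnts > 0
    if (!any(ok))
      stop("a sample shares no all-positive gene with the cohort; size factor undefined")
    exp(stats::median(log(cnts[ok]) - log_geo[ok]))
  })
  stats::setNames(sf, colnames(counts))
}

#' Variance-stabilizing shifted-log transform
#'
#' Library-size-adjusted shifted log: `log2(count / size_factor + 1)`.
#' Monotone in counts for a fixed size factor and invariant under jointly
#' rescaling counts and size factors.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors from [size_factors()]; computed if `NULL`.
#' @return list of class `norm_matrix` with `values` (same shape as
#'   `counts`) and `size_factors`.
#' @export
vst <- function(counts, sf = NULL) {
  check_count_matrix(counts)
  sf <- sf %||% size_factors(counts)
  if (any(sf <= 0)) stop("size factors must be positive")
  if (length(sf) != ncol(counts)) stop("one size factor per sample required")
  values <- log2(sweep(counts, 2L, sf, "/") + 1)
  structure(list(values = values, size_factors = sf), class = "norm_matrix")
}

#' Normalize a count matrix (size factors + shifted-log transform)
#'
#' Convenience wrapper around [size_factors()] and [vst()].
#'
#' @param counts gene x sample count matrix.
#' @return a `norm_matrix` (see [vst()]).
#' @export
normalize_counts <- function(counts) vst(counts)

#' @export
print.norm_matrix <- function(x, ...) {
  cat("norm_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples; ",
      "size factors in [", round(min(x$size_factors), 3), ",",
      round(max(x$size_factors), 3), "]\n")
  invisible(x)
}
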