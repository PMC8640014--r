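# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

STAGES <- c("NORMAL", "PRIMARY", "CRPC", "NEPC")
TECHS  <- c("POLYA", "TOTAL", "HCS")

#' Derive a purpose-specific RNG seed from a root seed
#'
#' One root seed per generator call is split deterministically by purpose so
#' that adding a downstream output (e.g. survival) never perturbs draws made
#' for an earlier one (e.g. counts).  Kept below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param purpose one of "latent", "counts", "genotype", "survival", "cells",
#'   "folds".
#' @return an integer seed.
#' @keywords internal
split_seed <- function(seed, purpose) {
  offsets <- c(latent = 1L, counts = 2L, genotype = 3L, survival = 4L,
               cells = 5L, folds = 6L)
  if (!purpose %in% names(offsets)) stop("unknown RNG purpose: ", purpose)
  as.integer((abs(as.numeric(seed)) %% 499979) * 3581 +
               offsets[[purpose]] * 7919)
}

# Row variances without matrixStats.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least two columns to compute variances")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

#' Validate a gene x sample count matrix
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty dimnames and non-negative finite entries.
#' @return the matrix, invisibly, after validation.
#' @export
check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  dg <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dg)) stop("duplicate gene id(s): ", paste(unique(dg), collapse = ", "))
  ds <- colnames(counts)[duplicated(colnames(counts))]
  if (length(ds)) stop("duplicate sample id(s): ", paste(unique(ds), collapse = ", "))
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("counts contain missing or non-finite values")
  if (any(counts < 0)) stop("counts contain negative entries")
  invisible(counts)
}

# match manifest rows to matrix columns, erroring informatively
manifest_for_samples <- function(manifest, sample_ids) {
  idx <- match(sample_ids, manifest$sample_id)
  if (anyNA(idx))
    stop("samples missing from manifest: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  manifest[idx, , drop = FALSE]
}
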