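# High-variance gene selection and the frozen PCA atlas embedding.

#' Select high-variance genes on a training subset
#'
#' Genes are ranked by their variance of normalized expression across the
#' training samples only (by default the PolyA+ subset, so that genes whose
#' variance is driven by library technology cannot be selected).  Ties are
#' broken lexicographically by gene id, making the selection deterministic.
#'
#' @param X normalized gene x sample matrix.
#' @param training_samples sample ids defining the training subset.
#' @param n_genes number of genes to return (default 2000).
#' @return character vector of gene ids in rank order.
#' @export
select_hvg <- function(X, training_samples, n_genes = 2000L) {
  missing <- setdiff(training_samples, colnames(X))
  if (length(missing))
    stop("training sample(s) absent from X: ", paste(missing, collapse = ", "))
  if (n_genes > nrow(X))
    stop("n_genes (", n_genes, ") exceeds available genes (", nrow(X), ")")
  v <- row_vars(X[, training_samples, drop = FALSE])
  ord <- order(-v, rownames(X))
  rownames(X)[ord][seq_len(n_genes)]
}

#' Fit the frozen PCA embedding
#'
#' Centers the selected genes (no unit scaling), runs an SVD, and fixes each
#' component's sign so its largest-magnitude loading is positive, making
#' serialized embeddings reproducible.
#'
#' @param X normalized gene x sample matrix.
#' @param hvg_ids genes to embed (from [select_hvg()]).
#' @param n_components number of components kept (default 3).
#' @return list of class `atlas_embedding`: `hvg_ids`, `centers`, orthonormal
#'   `rotation` (gene x component), `explained_variance_fraction`,
#'   `eigenvalues`, and reference `coordinates` (sample x component).
#' @export
fit_embedding <- function(X, hvg_ids, n_components = 3L) {
  missing <- setdiff(hvg_ids, rownames(X))
  if (length(missing))
    stop("hvg id(s) absent from X: ", paste(missing, collapse = ", "))
  if (ncol(X) < n_components + 1L)
    stop("need at least ", n_components + 1L, " samples for ", n_components,
         " components")
  Xh <- t(X[hvg_ids, , drop = FALSE])       # samples x genes
  pr <- stats::prcomp(Xh, center = TRUE, scale. = FALSE)
  k <- n_components
  rotation <- pr$rotation[, seq_len(k), drop = FALSE]
  coords <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                   # deterministic sign convention
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      coords[, j] <- -coords[, j]
    }
  }
  ev <- pr$sdev^2
  colnames(rotation) <- colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(hvg_ids = hvg_ids,
                 centers = pr$center,
                 rotation = rotation,
                 explained_variance_fraction = ev[seq_len(k)] / sum(ev),
                 eigenvalues = ev[seq_len(k)],
                 coordinates = coords),
            class = "atlas_embedding")
}

#' Project samples onto a frozen embedding
#'
#' Naive projection: center with the stored per-gene means and multiply by
#' the stored rotation.  (Drift-corrected projection of genuinely new samples
#' lives in [project_sample()].)
#'
#' @param object an `atlas_embedding`.
#' @param newdata normalized gene x sample matrix containing all HVGs.
#' @param ... unused.
#' @return sample x component coordinate matrix.
#' @export
predict.atlas_embedding <- function(object, newdata, ...) {
  missing <- setdiff(object$hvg_ids, rownames(newdata))
  if (length(missing))
    stop("HVG(s) missing from newdata: ", paste(missing, collapse = ", "))
  Xh <- t(newdata[object$hvg_ids, , drop = FALSE])
  sweep(Xh, 2L, object$centers) %*% object$rotation
}

#' @export
print.atlas_embedding <- function(x, ...) {
  cat("atlas_embedding:", length(x$hvg_ids), "HVGs,",
      ncol(x$rotation), "components over", nrow(x$coordinates), "samples\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an embedding to a directory of plain-text files
#'
#' Writes `hvg.tsv` (gene id + center), `rotation.tsv`, `coordinates.tsv`
#' and `meta.json`.
#'
#' @param embedding an `atlas_embedding`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_embedding <- function(embedding, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(gene_id = embedding$hvg_ids,
               center = unname(embedding$centers[embedding$hvg_ids])),
    file.path(dir, "hvg.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(embedding$rotation), embedding$rotation),
    file.path(dir, "rotation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(embedding$coordinates),
               embedding$coordinates),
    file.path(dir, "coordinates.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(explained_variance_fraction = embedding$explained_variance_fraction,
         eigenvalues = embedding$eigenvalues,
         n_components = ncol(embedding$rotation)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load an embedding serialized with [save_embedding()]
#'
#' @param dir directory written by [save_embedding()].
#' @return an `atlas_embedding`.
#' @export
load_embedding <- function(dir) {
  hvg <- utils::read.delim(file.path(dir, "hvg.tsv"), stringsAsFactors = FALSE)
  rot <- utils::read.delim(file.path(dir, "rotation.tsv"), stringsAsFactors = FALSE)
  coo <- utils::read.delim(file.path(dir, "coordinates.tsv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rotation <- as.matrix(rot[, -1L, drop = FALSE])
  rownames(rotation) <- rot[[1L]]
  coords <- as.matrix(coo[, -1L, drop = FALSE])
  rownames(coords) <- coo[[1L]]
  structure(list(hvg_ids = hvg$gene_id,
                 centers = stats::setNames(hvg$center, hvg$gene_id),
                 rotation = rotation,
                 explained_variance_fraction = meta$explained_variance_fraction,
                 eigenvalues = meta$eigenvalues,
                 coordinates = coords),
            class = "atlas_embedding")
}
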