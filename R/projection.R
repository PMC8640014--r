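# Projection of new bulk samples, single-cell pseudobulks and imputed single
# cells onto the frozen atlas.
#
# Adding a sample to the cohort perturbs the normalization and hence the
# recomputed PCA; the drift is approximately an affine distortion of the
# coordinate system.  Three elastic-net models (one per top component) are
# trained at runtime on the reference samples to predict the displacement
# between the frozen coordinates and the recomputed ones, and the prediction
# corrects the new sample's recomputed position.

# Signed permutation aligning recomputed components with the originals by
# greedy maximal-|correlation| matching.
align_components <- function(recomputed, original, min_cor = 0.8) {
  k <- ncol(original)
  C <- stats::cor(recomputed, original)
  perm <- integer(k); sgn <- numeric(k); used <- rep(FALSE, nrow(C))
  cors <- numeric(k)
  A <- abs(C)
  assigned <- integer(0)
  for (step in seq_len(k)) {
    A_masked <- A
    A_masked[used, ] <- -Inf
    if (length(assigned)) A_masked[, assigned] <- -Inf
    pick <- which(A_masked == max(A_masked), arr.ind = TRUE)[1L, ]
    i <- pick[1L]; j <- pick[2L]
    perm[j] <- i; sgn[j] <- sign(C[i, j]); cors[j] <- abs(C[i, j])
    used[i] <- TRUE
    assigned <- c(assigned, j)
  }
  if (any(cors < min_cor))
    stop("embedding incompatibility: component alignment correlation ",
         paste(sprintf("%.2f", cors), collapse = "/"),
         " below ", min_cor)
  list(perm = perm, sign = sgn, cor = cors)
}

apply_alignment <- function(coords, alignment) {
  out <- coords[, alignment$perm, drop = FALSE]
  out <- sweep(out, 2L, alignment$sign, "*")
  colnames(out) <- paste0("PC", seq_len(ncol(out)))
  out
}

# Fit one elastic-net drift model per component: response = original -
# recomputed coordinate over the reference samples, predictors = the
# recomputed top-k coordinates, mixing alpha, penalty by 5-fold CV with a
# fixed fold seed for determinism.
fit_drift_models <- function(original, recomputed, alpha = 0.5,
                             nfolds = 5L, cv_seed = 1L) {
  n <- nrow(original)
  set.seed(split_seed(cv_seed, "folds"))
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  lapply(seq_len(ncol(original)), function(k) {
    y <- original[, k] - recomputed[, k]
    if (stats::sd(y) < .Machine$double.eps^0.5)
      return(list(constant = mean(y)))   # degenerate zero-drift response
    glmnet::cv.glmnet(recomputed, y, alpha = alpha, foldid = foldid)
  })
}

predict_drift <- function(models, newx) {
  vapply(models, function(m) {
    if (!is.null(m$constant)) return(rep(m$constant, nrow(newx)))
    as.numeric(stats::predict(m, newx = newx, s = "lambda.min"))
  }, numeric(nrow(newx)))
}

#' Project one new sample onto the frozen atlas with drift correction
#'
#' The new sample's raw counts are appended to the reference counts, the
#' merged matrix is re-normalized, PCA is recomputed on the frozen HVG list,
#' the recomputed components are sign/permutation-aligned to the originals,
#' per-component elastic-net models of the reference samples' coordinate
#' drift are fitted, and the new sample's recomputed coordinate is corrected
#' by the predicted drift.  Samples are projected one at a time; the frozen
#' embedding and trajectory are never modified.
#'
#' @param new_counts named per-gene raw counts for one sample.  Up to
#'   `max_missing` of the embedding's HVGs may be absent; they are imputed at
#'   the recomputed center value.
#' @param reference_counts gene x sample raw counts of the reference cohort,
#'   or an `atlas` from [build_atlas()] (in which case `embedding`, `traj`
#'   and `batch_model` are taken from it).
#' @param embedding the frozen `atlas_embedding`.
#' @param traj optional `trajectory`; when given, pseudotime is assigned
#'   from the corrected PC1-PC2 coordinate.
#' @param batch_model optional `batch_model` used when the atlas was built;
#'   the merged matrix then undergoes the same correction, with the new
#'   sample treated as `new_batch` (default: the model's reference batch,
#'   i.e. PolyA-like, so no correction is applied to it).
#' @param new_batch batch label assigned to the new sample when a
#'   `batch_model` is supplied.
#' @param alpha elastic-net mixing parameter.
#' @param nfolds,cv_seed cross-validation folds and fixed fold seed.
#' @param max_missing tolerated fraction of missing HVGs (default 0.02).
#' @return list with `coordinates` (corrected, 1 x k), `raw_coordinates`
#'   (aligned recomputed, uncorrected), `pseudotime` (or `NA`), `alignment`
#'   and per-component chosen penalties.
#' @export
project_sample <- function(new_counts, reference_counts, embedding = NULL,
                           traj = NULL, batch_model = NULL, new_batch = NULL,
                           alpha = 0.5, nfolds = 5L,
                           cv_seed = 1L, max_missing = 0.02) {
  if (inherits(reference_counts, "atlas")) {
    atlas <- reference_counts
    reference_counts <- atlas$counts
    embedding <- embedding %||% atlas$embedding
    traj <- traj %||% atlas$trajectory
    batch_model <- batch_model %||% atlas$batch_model
  }
  if (is.null(embedding)) stop("an atlas_embedding is required")
  genes <- rownames(reference_counts)
  missing_hvg <- setdiff(embedding$hvg_ids, names(new_counts))
  if (length(missing_hvg) > max_missing * length(embedding$hvg_ids))
    stop(length(missing_hvg), " of ", length(embedding$hvg_ids),
         " HVGs missing from the new sample (tolerance ",
         round(100 * max_missing, 1), "%): ",
         paste(utils::head(missing_hvg, 5), collapse = ", "), " ...")
  aligned <- stats::setNames(rep(0, length(genes)), genes)
  common <- intersect(genes, names(new_counts))
  aligned[common] <- new_counts[common]

  merged <- cbind(reference_counts, `..new..` = aligned)
  norm <- vst(merged)
  values <- norm$values
  if (!is.null(batch_model)) {
    # reproduce the atlas harmonization on the merged matrix; the new sample
    # is corrected only if declared as a non-reference technology
    ref_batch <- batch_model$sample_batch[colnames(reference_counts)]
    batch <- c(unname(ref_batch), new_batch %||% batch_model$reference)
    values <- apply_batch_correction(values, batch_model, batch)
  }
  Vh <- values[embedding$hvg_ids, , drop = FALSE]

  pr <- stats::prcomp(t(Vh), center = TRUE, scale. = FALSE,
                      rank. = ncol(embedding$rotation))
  coords <- pr$x
  # impute missing HVGs at the recomputed center, i.e. zero contribution
  if (length(missing_hvg)) {
    centered_new <- Vh[, ncol(Vh)] - pr$center
    centered_new[missing_hvg] <- 0
    coords[nrow(coords), ] <- centered_new %*% pr$rotation
  }

  ref_ids <- colnames(reference_counts)
  orig <- embedding$coordinates[ref_ids, , drop = FALSE]
  recomp_ref <- coords[ref_ids, , drop = FALSE]
  alignment <- align_components(recomp_ref, orig)
  recomp_ref <- apply_alignment(recomp_ref, alignment)
  recomp_new <- apply_alignment(coords[nrow(coords), , drop = FALSE], alignment)

  models <- fit_drift_models(orig, recomp_ref, alpha = alpha,
                             nfolds = nfolds, cv_seed = cv_seed)
  corrected <- recomp_new + predict_drift(models, recomp_new)
  colnames(corrected) <- colnames(orig)

  pt <- NA_real_
  if (!is.null(traj))
    pt <- pseudotime(traj, corrected[, 1:2, drop = FALSE])$pseudotime

  list(coordinates = corrected,
       raw_coordinates = recomp_new,
       pseudotime = pt,
       alignment = alignment,
       lambda = vapply(models, function(m) m$lambda.min %||% NA_real_,
                       numeric(1)))
}

#' Pseudobulk aggregation of single cells
#'
#' Sums gene counts over all cells into one bulk-comparable meta-sample.
#'
#' @param sc gene x cell count matrix.
#' @return named per-gene count vector.
#' @export
pseudobulk <- function(sc) {
  if (ncol(sc) < 1L) stop("need at least one cell")
  rowSums(sc)
}

#' Markov-affinity diffusion imputation of single-cell expression
#'
#' Builds a kNN graph on cells (Euclidean distance in the cells' top
#' principal components), applies an adaptive Gaussian kernel whose per-cell
#' bandwidth is the distance to the `ceiling(k/3)`-th neighbor, symmetrizes
#' the affinities, row-normalizes to a Markov operator M, and returns
#' `values %*% t(M^t_diff)` — each cell's profile diffused over its
#' neighborhood, mitigating dropout zeros.
#'
#' @param values gene x cell matrix of normalized expression.
#' @param k neighbor count (default 15); must be below the cell count.
#' @param t_diff diffusion power (default 3); 0 returns the input.
#' @param n_pcs principal components used for the cell-cell distances.
#' @return imputed gene x cell matrix.
#' @export
impute_diffusion <- function(values, k = 15L, t_diff = 3L, n_pcs = 20L) {
  n <- ncol(values)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (", n, ")")
  if (t_diff == 0L) return(values)
  M <- diffusion_operator(values, k = k, n_pcs = n_pcs)
  Mp <- M
  if (t_diff > 1L) for (i in seq_len(t_diff - 1L)) Mp <- Mp %*% M
  out <- values %*% t(Mp)
  dimnames(out) <- dimnames(values)
  out
}

# Row-stochastic cell x cell Markov operator used by impute_diffusion().
diffusion_operator <- function(values, k = 15L, n_pcs = 20L) {
  n <- ncol(values)
  r <- min(n_pcs, n - 1L, nrow(values))
  pcs <- stats::prcomp(t(values), center = TRUE, scale. = FALSE, rank. = r)$x
  D <- as.matrix(stats::dist(pcs))
  A <- matrix(0, n, n)
  kb <- max(1L, ceiling(k / 3))
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    nn <- ord[ord != i][seq_len(k)]
    sigma <- D[i, nn[kb]]
    if (sigma <= 0) sigma <- .Machine$double.eps
    A[i, nn] <- exp(-(D[i, nn] / sigma)^2)
    A[i, i] <- 1
  }
  W <- (A + t(A)) / 2
  W / rowSums(W)
}

#' Project single cells or cell clusters onto the frozen atlas
#'
#' Per cluster: gene counts are pseudobulked per cluster and each meta-sample
#' is projected with [project_sample()].  Per cell: expression is diffusion-
#' imputed, each cell is rescaled to the median reference library size to
#' avoid size-factor pathologies on sparse cells, and projected individually.
#'
#' @param sc gene x cell raw count matrix.
#' @param reference_counts,embedding,traj frozen atlas inputs as in
#'   [project_sample()].
#' @param per `"cluster"` or `"cell"`.
#' @param clusters per-cell cluster labels (required when `per = "cluster"`).
#' @param k,t_diff diffusion-imputation parameters (per-cell mode).
#' @param ... further arguments to [project_sample()].
#' @return data.frame with `id`, corrected `PC1..PCk` and `pseudotime`.
#' @export
project_cells <- function(sc, reference_counts, embedding = NULL, traj = NULL,
                          per = c("cluster", "cell"), clusters = NULL,
                          k = 15L, t_diff = 3L, ...) {
  per <- match.arg(per)
  atlas <- NULL
  if (inherits(reference_counts, "atlas")) {
    atlas <- reference_counts
    reference_counts <- atlas$counts
  }
  if (per == "cluster") {
    if (is.null(clusters)) stop("cluster labels required when per = 'cluster'")
    profiles <- lapply(split(seq_len(ncol(sc)), clusters), function(idx) {
      if (!length(idx)) return(NULL)
      pseudobulk(sc[, idx, drop = FALSE])
    })
    empty <- vapply(profiles, is.null, logical(1))
    if (any(empty)) {
      warning("skipping empty cluster(s): ",
              paste(names(profiles)[empty], collapse = ", "))
      profiles <- profiles[!empty]
    }
  } else {
    tot <- colSums(sc)
    if (any(tot == 0)) stop("cell(s) with zero total counts cannot be projected")
    rel <- sweep(sc, 2L, tot, "/")
    imp <- impute_diffusion(rel, k = k, t_diff = t_diff)
    imp[imp < 0] <- 0
    target <- stats::median(colSums(reference_counts))
    profiles <- lapply(seq_len(ncol(sc)), function(i) imp[, i] * target)
    names(profiles) <- colnames(sc)
  }
  rows <- lapply(names(profiles), function(id) {
    pj <- project_sample(profiles[[id]], atlas %||% reference_counts,
                         embedding, traj = traj, ...)
    data.frame(id = id, pj$coordinates, pseudotime = pj$pseudotime,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
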