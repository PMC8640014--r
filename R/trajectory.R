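# Start-anchored principal curve through the PC1-PC2 cloud and arc-length
# pseudotime on a fixed reporting scale.
#
# The curve is fitted by alternating orthogonal projection onto the current
# polyline with scatterplot smoothing of each coordinate against arc length,
# initialized from a minimum-spanning-tree path through the stage centroids
# rooted at the start stage.

# ---- polyline geometry -----------------------------------------------------

# Remove consecutive duplicate vertices.
dedup_vertices <- function(V) {
  if (nrow(V) < 2L) return(V)
  keep <- c(TRUE, rowSums((V[-1L, , drop = FALSE] -
                             V[-nrow(V), , drop = FALSE])^2) > 0)
  V[keep, , drop = FALSE]
}

cumulative_arclength <- function(V) {
  seg <- sqrt(rowSums((V[-1L, , drop = FALSE] - V[-nrow(V), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# Orthogonal projection of points (n x d) onto polyline vertices (m x d).
# Returns per-point arc length at the projection, squared distance, and the
# projected coordinates.
project_polyline <- function(points, V) {
  V <- dedup_vertices(V)
  n <- nrow(points); m <- nrow(V)
  if (m == 1L) {
    d2 <- rowSums(sweep(points, 2L, V[1L, ])^2)
    return(list(lambda = rep(0, n), dist2 = d2,
                proj = matrix(V[1L, ], n, ncol(V), byrow = TRUE)))
  }
  cum <- cumulative_arclength(V)
  best_d2 <- rep(Inf, n)
  best_lam <- rep(0, n)
  best_proj <- matrix(0, n, ncol(V))
  for (j in seq_len(m - 1L)) {
    a <- V[j, ]; b <- V[j + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ta <- sweep(points, 2L, a)
    tt <- pmin(1, pmax(0, as.numeric(ta %*% ab) / len2))
    proj <- outer(tt, ab) + matrix(a, n, length(a), byrow = TRUE)
    d2 <- rowSums((points - proj)^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_lam[upd] <- cum[j] + tt[upd] * sqrt(len2)
      best_proj[upd, ] <- proj[upd, , drop = FALSE]
    }
  }
  list(lambda = best_lam, dist2 = best_d2, proj = best_proj)
}

# Minimum-spanning-tree path through k centroids rooted at `start`
# (Prim's algorithm; k is the number of stages, at most a handful).
# Returns the vertex order and whether the MST is a simple path.
mst_path_order <- function(centroids, start) {
  k <- nrow(centroids)
  if (k == 1L) return(list(order = 1L, is_path = TRUE))
  D <- as.matrix(stats::dist(centroids))
  in_tree <- rep(FALSE, k); in_tree[start] <- TRUE
  parent <- rep(NA_integer_, k)
  for (step in seq_len(k - 1L)) {
    Dsub <- D[in_tree, !in_tree, drop = FALSE]
    pick <- which(Dsub == min(Dsub), arr.ind = TRUE)[1L, ]
    from <- which(in_tree)[pick[1L]]
    to <- which(!in_tree)[pick[2L]]
    parent[to] <- from
    in_tree[to] <- TRUE
  }
  adj <- lapply(seq_len(k), function(i)
    c(which(parent == i), if (!is.na(parent[i])) parent[i]))
  degrees <- lengths(adj)
  is_path <- all(degrees <= 2L) && degrees[start] == 1L
  # depth-first order from the root; for a path this is the path order
  ord <- integer(0); stack <- start; seen <- rep(FALSE, k)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    ord <- c(ord, v)
    stack <- c(stack, setdiff(adj[[v]], which(seen)))
  }
  list(order = ord, is_path = is_path)
}

# ---- fitting ---------------------------------------------------------------

# Resample a polyline at given arc-length fractions.
resample_polyline <- function(V, fractions) {
  cum <- cumulative_arclength(V)
  x <- fractions * max(cum)
  cbind(stats::approx(cum, V[, 1], xout = x, ties = "ordered")$y,
        stats::approx(cum, V[, 2], xout = x, ties = "ordered")$y)
}

#' Fit a start-anchored principal-curve trajectory
#'
#' The curve is initialized as the minimum-spanning-tree path through the
#' stage centroids rooted at `start_stage` and refined by alternating
#' orthogonal projection with per-coordinate scatterplot smoothing against
#' arc length.  Each refined curve is shrunk toward the centroid backbone
#' (`shrink`): an unregularized principal curve bends its ends into dense
#' stage clusters to soak up noise variance orthogonal to the progression,
#' scrambling the sample ordering at the extremes, while the backbone pins
#' the curve to the stage-level geometry and the smoother adds within-path
#' curvature.
#'
#' @param coords sample x 2 coordinate matrix (PC1-PC2) with sample ids as
#'   rownames; extra columns are ignored.
#' @param stages per-sample stage labels aligned with `coords` rows.
#' @param start_stage stage whose cluster anchors arc length 0.
#' @param include optional sample ids (or logical vector) to fit on; use it
#'   to drop technical replicates so they do not overweight the curve.
#'   Default: all samples.
#' @param smoother_span span of the local-regression smoother applied to each
#'   coordinate against arc length, as a fraction of samples.  The smoother
#'   is non-robust (no residual reweighting), which makes the fit exactly
#'   equivariant under rigid motions of the coordinates.
#' @param shrink weight in `[0, 1]` of the stage-centroid backbone in each
#'   update (0 = free principal curve, 1 = backbone only; default 0.7).
#' @param n_vertices polyline vertices, evenly spaced in arc length.
#' @param scale_max reported pseudotime of the furthest fitted sample
#'   (default 250).
#' @param tol convergence tolerance: maximum vertex displacement between
#'   iterations relative to the data scale, and relative change of the total
#'   squared projection distance.
#' @param max_iter maximum projection/smoothing iterations.
#' @return list of class `trajectory`: polyline `curve_points`,
#'   `cumulative_arclength`, `scale_factor`, `start_stage`, `smoother_span`,
#'   and `convergence` (iterations, final criterion, converged flag,
#'   branch warning).
#' @export
fit_trajectory <- function(coords, stages, start_stage = "NORMAL",
                           include = NULL, smoother_span = 0.6,
                           shrink = 0.7, n_vertices = 100L,
                           scale_max = 250, tol = 1e-4, max_iter = 50L) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (length(stages) != nrow(coords)) stop("one stage label per sample required")
  stages <- as.character(stages)
  if (!is.null(include)) {
    keep <- if (is.logical(include)) include else rownames(coords) %in% include
    coords <- coords[keep, , drop = FALSE]
    stages <- stages[keep]
  }
  present <- unique(stages)
  if (length(present) < 2L) stop("need at least two distinct stages")
  if (!start_stage %in% present) stop("start_stage '", start_stage, "' absent")

  ## initialization: MST path through stage centroids rooted at start
  stage_levels <- unique(c(start_stage, present))
  centroids <- t(vapply(stage_levels,
                        function(s) colMeans(coords[stages == s, , drop = FALSE]),
                        numeric(2)))
  mst <- mst_path_order(centroids, start = 1L)
  path <- centroids[mst$order, , drop = FALSE]
  # extend both ends along their tangent to the data's projection extent, so
  # that extreme samples order along the tangent instead of clamping to the
  # first/last centroid
  if (nrow(path) >= 2L) {
    extend_end <- function(P, head_end) {
      if (head_end) { v <- P[1L, ]; d <- P[1L, ] - P[2L, ] }
      else { v <- P[nrow(P), ]; d <- P[nrow(P), ] - P[nrow(P) - 1L, ] }
      len <- sqrt(sum(d^2))
      if (len == 0) return(P)
      d <- d / len
      over <- max(0, max(sweep(coords, 2L, v) %*% d))
      if (over <= 0) return(P)
      if (head_end) rbind(v + over * d, P) else rbind(P, v + over * d)
    }
    path <- extend_end(path, TRUE)
    path <- extend_end(path, FALSE)
  }
  backbone <- resample_polyline(path, seq(0, 1, length.out = n_vertices))
  branch_warning <- !mst$is_path
  if (branch_warning)
    warning("stage-centroid spanning tree is not a simple path; ",
            "fitting a single lineage through its depth-first order")

  data_scale <- sqrt(mean(apply(coords, 2L, stats::var)))
  V <- backbone
  D_old <- Inf; D_best <- Inf; stall <- 0L; crit <- Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    pr <- project_polyline(coords, V)
    D_new <- sum(pr$dist2)
    ord <- order(pr$lambda)
    lam <- pr$lambda[ord]
    grid <- seq(min(lam), max(lam), length.out = n_vertices)
    smoothed <- vapply(1:2, function(d) {
      fit <- stats::lowess(lam, coords[ord, d], f = smoother_span, iter = 0L)
      stats::approx(fit$x, fit$y, xout = grid, ties = "ordered")$y
    }, numeric(n_vertices))
    V_new <- dedup_vertices((1 - shrink) * smoothed + shrink * backbone)
    move <- if (nrow(V_new) == nrow(V))
      max(sqrt(rowSums((V_new - V)^2))) / data_scale else Inf
    d_rel <- if (is.finite(D_old))
      abs(D_old - D_new) / max(D_old, .Machine$double.eps) else Inf
    # movement is judged against 10x the SSE tolerance: grid resampling
    # leaves a sub-0.1%-of-scale jitter even at the fixed point, so the fit
    # also stops once the SSE has not improved for five iterations
    crit <- min(move / 10, d_rel)
    stall <- if (D_new < D_best * (1 - tol)) 0L else stall + 1L
    D_best <- min(D_best, D_new)
    V <- V_new
    D_old <- D_new
    if (crit < tol || stall >= 5L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("trajectory did not converge in ", max_iter,
            " iterations (criterion ", signif(crit, 3), "); returning best iterate")

  ## orientation: the start-stage centroid must project near arc length 0
  start_centroid <- matrix(colMeans(coords[stages == start_stage, , drop = FALSE]),
                           nrow = 1L)
  total_len <- max(cumulative_arclength(V))
  if (project_polyline(start_centroid, V)$lambda > total_len / 2)
    V <- V[rev(seq_len(nrow(V))), , drop = FALSE]

  cum <- cumulative_arclength(V)
  fitted_lambda <- project_polyline(coords, V)$lambda
  max_ref <- max(fitted_lambda)
  if (max_ref <= 0) stop("degenerate trajectory: all samples project to the start")
  scale_factor <- scale_max / max_ref

  structure(list(curve_points = V,
                 cumulative_arclength = cum,
                 start_stage = start_stage,
                 scale_factor = scale_factor,
                 scale_max = scale_max,
                 max_reference_arclength = max_ref,
                 smoother_span = smoother_span,
                 convergence = list(iterations = it, criterion = crit,
                                    converged = converged,
                                    branch_warning = branch_warning)),
            class = "trajectory")
}

#' Assign pseudotime by projection onto a fitted trajectory
#'
#' Each point is projected orthogonally to the nearest point of the fitted
#' polyline; pseudotime is the scaled arc length at the projection, clamped
#' to `[0, scale_max]` (points beyond the curve ends clamp rather than
#' extrapolate).
#'
#' @param traj a fitted `trajectory`.
#' @param coords sample x 2 coordinate matrix with sample ids as rownames.
#' @return data.frame with `sample_id` and `pseudotime`.
#' @export
pseudotime <- function(traj, coords) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  pr <- project_polyline(coords, traj$curve_points)
  pt <- pmin(traj$scale_max, pmax(0, traj$scale_factor * pr$lambda))
  data.frame(sample_id = rownames(coords) %||% seq_len(nrow(coords)),
             pseudotime = pt, stringsAsFactors = FALSE)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", nrow(x$curve_points), "curve vertices, pseudotime scale [0,",
      x$scale_max, "]\n")
  cat("  start stage:", x$start_stage, "| converged:",
      x$convergence$converged, "in", x$convergence$iterations, "iterations\n")
  invisible(x)
}

#' Serialize a trajectory to JSON
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_trajectory <- function(traj, path) {
  jsonlite::write_json(unclass(traj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trajectory serialized with [save_trajectory()]
#'
#' @param path JSON path.
#' @return a `trajectory`.
#' @export
load_trajectory <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$curve_points <- if (is.list(x$curve_points))
    do.call(rbind, lapply(x$curve_points, unlist)) else as.matrix(x$curve_points)
  class(x) <- "trajectory"
  x
}
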