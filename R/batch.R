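# Reference-batch empirical-Bayes location/scale batch correction.
#
# Parametric variant of the canonical EB batch-adjustment model: genes are
# standardized with the reference batch's per-gene mean and pooled sd, each
# non-reference batch gets per-gene location (gamma) and scale (delta^2)
# estimates which are shrunk toward batch-level normal / inverse-gamma priors
# fitted by moments, and the coupled posterior updates are iterated to
# convergence.  The reference batch is returned untouched.

#' Fit a reference-batch location/scale batch model
#'
#' @param X normalized gene x sample matrix (a `norm_matrix$values` or any
#'   numeric matrix on a roughly Gaussian scale).
#' @param batch per-sample batch labels (length `ncol(X)`).
#' @param reference label of the reference batch (left unchanged).
#' @param tol relative tolerance of the coupled EB updates.
#' @param max_iter maximum EB iterations per batch.
#' @return list of class `batch_model` with per-gene reference mean and
#'   pooled sd, shrunken batch x gene location offsets (`gamma_star`) and
#'   scale factors (`delta2_star`), prior hyperparameters, and the per-sample
#'   batch assignment used at fit time.
#' @export
fit_reference_batch_model <- function(X, batch, reference,
                                      tol = 1e-6, max_iter = 100L) {
  if (length(batch) != ncol(X)) stop("one batch label per sample required")
  batch <- as.character(batch)
  if (!reference %in% batch) stop("reference batch '", reference, "' absent")
  tab <- table(batch)
  if (any(tab < 2L))
    stop("batch(es) with a single sample (scale inestimable): ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  batches <- c(reference, setdiff(names(tab), reference))
  G <- nrow(X)

  ref_cols <- which(batch == reference)
  n_ref <- length(ref_cols)
  grand_mean <- rowMeans(X[, ref_cols, drop = FALSE])
  # pooled variance on the reference batch (n divisor, canonical form)
  pooled_var <- rowSums((X[, ref_cols, drop = FALSE] - grand_mean)^2) / n_ref
  pooled_sd <- sqrt(pooled_var)
  # variance floor guards constant genes in the reference
  floor_sd <- 1e-8 * max(stats::sd(X), .Machine$double.eps)
  pooled_sd <- pmax(pooled_sd, floor_sd)

  Z <- (X - grand_mean) / pooled_sd

  gamma_star <- matrix(0, nrow = length(batches), ncol = G,
                       dimnames = list(batches, rownames(X)))
  delta2_star <- matrix(1, nrow = length(batches), ncol = G,
                        dimnames = list(batches, rownames(X)))
  priors <- list()
  iterations <- stats::setNames(integer(length(batches)), batches)

  for (b in setdiff(batches, reference)) {
    cols <- which(batch == b)
    n_b <- length(cols)
    Zb <- Z[, cols, drop = FALSE]
    g_hat <- rowMeans(Zb)
    d_hat <- rowSums((Zb - g_hat)^2) / (n_b - 1L)

    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m_d <- mean(d_hat); s2_d <- stats::var(d_hat)
    a_prior <- (2 * s2_d + m_d^2) / s2_d
    b_prior <- (m_d * s2_d + m_d^3) / s2_d

    g_old <- g_hat; d_old <- d_hat
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (t2 * n_b * g_hat + d_old * g_bar) / (t2 * n_b + d_old)
      sum2 <- rowSums((Zb - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (n_b / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < tol || it >= max_iter) break
    }
    gamma_star[b, ] <- g_old
    delta2_star[b, ] <- d_old
    priors[[b]] <- list(gamma_bar = g_bar, tau2 = t2,
                        a = a_prior, b = b_prior,
                        gamma_hat = g_hat, delta_hat = d_hat)
    iterations[b] <- it
  }

  structure(list(reference = reference, batches = batches,
                 grand_mean = grand_mean, pooled_sd = pooled_sd,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 priors = priors, iterations = iterations,
                 sample_batch = stats::setNames(batch, colnames(X))),
            class = "batch_model")
}

#' Apply a fitted reference-batch correction
#'
#' Non-reference samples are adjusted as
#' `((x - ref_mean - gamma* sd) / sqrt(delta2*)) * ref_sd + ref_mean`;
#' reference-batch samples are returned bit-for-bit unchanged.
#'
#' @param X normalized gene x sample matrix over the genes the model was
#'   fitted on.
#' @param model a `batch_model`.
#' @param batch per-sample batch labels; defaults to the fit-time assignment
#'   looked up by column name.
#' @return corrected matrix, same shape as `X`.
#' @export
apply_batch_correction <- function(X, model, batch = NULL) {
  if (is.null(batch)) {
    idx <- match(colnames(X), names(model$sample_batch))
    if (anyNA(idx))
      stop("no fit-time batch assignment for sample(s): ",
           paste(colnames(X)[is.na(idx)], collapse = ", "),
           "; supply `batch` explicitly")
    batch <- unname(model$sample_batch[idx])
  }
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen)) stop("unseen batch label(s): ", paste(unseen, collapse = ", "))
  if (!identical(rownames(X), names(model$grand_mean)))
    stop("model fitted on different genes than X")

  out <- X
  for (b in setdiff(unique(batch), model$reference)) {
    cols <- which(batch == b)
    Zb <- (X[, cols, drop = FALSE] - model$grand_mean) / model$pooled_sd
    Zb <- (Zb - model$gamma_star[b, ]) / sqrt(model$delta2_star[b, ])
    out[, cols] <- Zb * model$pooled_sd + model$grand_mean
  }
  out
}

#' @export
print.batch_model <- function(x, ...) {
  cat("batch_model: reference =", x$reference, "; batches:",
      paste(x$batches, collapse = ", "), "\n")
  for (b in setdiff(x$batches, x$reference))
    cat(sprintf("  %s: mean |gamma*| = %.3f, mean delta2* = %.3f (%d EB iterations)\n",
                b, mean(abs(x$gamma_star[b, ])), mean(x$delta2_star[b, ]),
                x$iterations[b]))
  invisible(x)
}
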