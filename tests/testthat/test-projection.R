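# Drift-corrected projection of new samples, pseudobulk aggregation and
# diffusion imputation.

atlas_fixture <- function(seed = 2, n = 100, genes = 300) {
  co <- small_cohort(seed = seed, n = n, genes = genes)
  list(cohort = co, atlas = build_atlas(co$counts, co$manifest, n_hvg = 250))
}

test_that("a reference-mean-like profile projects near the origin", {
  fx <- atlas_fixture()
  at <- fx$atlas
  # count profile whose normalized values sit at the embedding centers:
  # naive transform of that profile is exactly the origin
  center_full <- rowMeans(at$norm$values)
  profile <- 2^center_full - 1
  pj <- project_sample(profile, at)
  ref_sd <- apply(at$embedding$coordinates, 2, sd)
  expect_true(all(abs(pj$coordinates) <= 0.05 * ref_sd))
})

test_that("zero drift makes the correction a no-op", {
  # recomputed == original: the error models must predict (approximately) zero
  fx <- atlas_fixture(seed = 4)
  orig <- fx$atlas$embedding$coordinates
  models <- trajatlas:::fit_drift_models(orig, orig, alpha = 0.5, cv_seed = 1)
  newx <- matrix(c(5, -3, 1), 1, dimnames = list(NULL, colnames(orig)))
  pred <- trajatlas:::predict_drift(models, newx)
  expect_lt(max(abs(pred)), 1e-6)
})

test_that("corrected coordinates are deterministic and leave the atlas frozen", {
  fx <- atlas_fixture(seed = 5, n = 80)
  at <- fx$atlas
  new <- fx$cohort$counts[, 7] + 3
  before <- list(at$embedding$rotation, at$embedding$coordinates,
                 at$trajectory$curve_points)
  p1 <- project_sample(new, at, cv_seed = 11)
  p2 <- project_sample(new, at, cv_seed = 11)
  expect_identical(p1$coordinates, p2$coordinates)
  expect_identical(before,
                   list(at$embedding$rotation, at$embedding$coordinates,
                        at$trajectory$curve_points))
})

test_that("drift correction improves projections against a reference snapshot", {
  # atlas frozen on 100 samples; projecting each of 10 held-out samples
  # against the 90 remaining reference samples re-normalizes the merged
  # matrix and genuinely drifts the recomputed coordinates
  fx <- atlas_fixture(seed = 6, n = 100, genes = 300)
  at <- fx$atlas
  co <- fx$cohort
  held <- colnames(co$counts)[seq(2, 100, by = 10)]
  ref_ids <- setdiff(colnames(co$counts), held)
  ref <- co$counts[, ref_ids]
  emb_ref <- at$embedding
  emb_ref$coordinates <- emb_ref$coordinates[ref_ids, , drop = FALSE]
  err <- t(vapply(held, function(id) {
    pj <- project_sample(co$counts[, id], ref, emb_ref)
    truth <- at$embedding$coordinates[id, ]
    c(corrected = sqrt(sum((pj$coordinates - truth)^2)),
      raw = sqrt(sum((pj$raw_coordinates - truth)^2)))
  }, numeric(2)))
  expect_lte(median(err[, "corrected"]), median(err[, "raw"]) + 1e-9)
})

test_that("missing HVGs are tolerated up to the threshold and refused beyond", {
  fx <- atlas_fixture(seed = 7, n = 60)
  at <- fx$atlas
  new <- fx$cohort$counts[, 10]
  hvg <- at$embedding$hvg_ids
  ok <- project_sample(new[setdiff(names(new), hvg[1:4])], at)   # 4/250 = 1.6%
  expect_true(all(is.finite(ok$coordinates)))
  expect_error(project_sample(new[setdiff(names(new), hvg[1:10])], at),
               "missing from the new sample")
})

test_that("pseudobulk aggregation is additive", {
  sc <- toy_counts(rpois(40 * 10, 5), 40, 10)
  # n identical cells -> n * c
  same <- sc[, rep(1, 6)]
  expect_equal(pseudobulk(same), 6 * sc[, 1])
  # single cell -> itself
  expect_equal(pseudobulk(sc[, 3, drop = FALSE]), sc[, 3])
  # split halves sum to the full pseudobulk
  expect_equal(pseudobulk(sc[, 1:5]) + pseudobulk(sc[, 6:10]), pseudobulk(sc))
})

test_that("diffusion imputation is a Markov smoothing operator", {
  set.seed(8)
  vals <- matrix(rnorm(30 * 40, 5), 30, 40,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 sprintf("c%02d", 1:40)))
  # t = 0 is the identity
  expect_identical(impute_diffusion(vals, k = 10, t_diff = 0), vals)
  # row-stochasticity: a constant gene is unchanged
  vals["g01", ] <- 4.2
  out <- impute_diffusion(vals, k = 10, t_diff = 3)
  expect_equal(unname(out["g01", ]), rep(4.2, 40), tolerance = 1e-10)
  # operator rows sum to one
  M <- trajatlas:::diffusion_operator(vals, k = 10)
  expect_equal(unname(rowSums(M)), rep(1, 40), tolerance = 1e-10)
  expect_true(all(M >= 0))
  # matches the direct matrix-power oracle
  t3 <- M %*% M %*% M
  expect_equal(out, vals %*% t(t3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(impute_diffusion(vals, k = 40), "smaller than")
})

test_that("diffusion denoises within blobs without cross-blob leakage", {
  set.seed(9)
  n_per <- 40
  blob <- function(center) {
    matrix(rnorm(25 * n_per, center, 1), 25, n_per)
  }
  vals <- cbind(blob(10), blob(-10))     # two well-separated cell blobs
  # marker expressed in blob 1 only, weak relative to the blob geometry so
  # its dropout zeros do not split the neighborhood graph
  marker <- c(rep(4, n_per), rep(0, n_per))
  marker[sample.int(n_per, n_per / 2)] <- 0     # 50% dropout in blob 1
  vals <- rbind(vals, marker = marker)
  dimnames(vals) <- list(c(sprintf("g%02d", 1:25), "marker"),
                         sprintf("c%02d", seq_len(2 * n_per)))
  out <- impute_diffusion(vals, k = 10, t_diff = 3)
  in1 <- seq_len(n_per); in2 <- n_per + seq_len(n_per)
  expect_lt(var(out["marker", in1]), var(vals["marker", in1]))
  expect_lt(mean(out["marker", in2]), 0.05 * mean(out["marker", in1]))
})

test_that("cells generated from a bulk profile project near that bulk", {
  fx <- atlas_fixture(seed = 10, n = 80, genes = 250)
  at <- fx$atlas
  co <- fx$cohort
  # pick a well-progressed bulk so order along the trajectory is informative
  ptv <- setNames(at$pseudotime$pseudotime, at$pseudotime$sample_id)
  hi <- names(sort(ptv, decreasing = TRUE))[2]
  lo <- names(sort(ptv))[2]
  sc_hi <- generate_single_cells(co$counts[, hi], n_cells = 50, dropout = 0.3,
                                 seed = 1)
  bulk_pt <- project_sample(co$counts[, hi], at)$pseudotime

  # pseudobulk projection lands within 10% of scale of the bulk's projection
  pb_pt <- project_sample(pseudobulk(sc_hi), at)$pseudotime
  expect_lt(abs(pb_pt - bulk_pt), 0.1 * at$trajectory$scale_max)

  # per = cluster with one all-cell cluster equals the pseudobulk projection
  cl <- project_cells(sc_hi, at, per = "cluster",
                      clusters = rep("all", ncol(sc_hi)))
  expect_equal(cl$pseudotime, pb_pt)

  # cells from opposite trajectory ends keep their bulks' order per cell
  sc_lo <- generate_single_cells(co$counts[, lo], n_cells = 30, dropout = 0.3,
                                 seed = 2)
  sc_hi2 <- generate_single_cells(co$counts[, hi], n_cells = 30, dropout = 0.3,
                                  seed = 3)
  both <- cbind(sc_lo, sc_hi2)
  colnames(both) <- sprintf("cell%03d", seq_len(ncol(both)))
  pc <- project_cells(both, at, per = "cell", k = 10, t_diff = 3)
  expect_lt(median(pc$pseudotime[seq_len(30)]),
            median(pc$pseudotime[30 + seq_len(30)]))
})
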