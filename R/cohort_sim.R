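# Synthetic multi-study cohort generator.
#
# Emulates the latent structure the downstream atlas assumes: four ordered
# disease stages lying along a 1-D latent progression, dataset- and
# library-technology-specific batch effects on the log scale, technical
# replicate pairs sequenced with two technologies, monotone up/down gene
# programs, stage-enriched driver mutations/CNAs and a pseudotime-dependent
# survival hazard.  A ground-truth record accompanies every cohort so that
# recovery can be scored.

#' Configuration for the synthetic cohort generator
#'
#' @param n_samples number of base samples (technical replicate pairs add
#'   `n_replicate_pairs` further columns).
#' @param n_genes number of genes.
#' @param stage_fractions named non-negative proportions for
#'   NORMAL/PRIMARY/CRPC/NEPC, summing to 1.  Defaults follow the composition
#'   of a large published pan-cohort (174/714/316/19 of 1223).
#' @param n_datasets number of datasets (studies) samples are spread over.
#' @param frac_hcs proportion of base samples assigned the hybrid-capture
#'   (HCS) library technology; the rest are PolyA+.
#' @param n_replicate_pairs number of PolyA+/HCS technical duplicate pairs.
#' @param frac_up_genes,frac_down_genes proportions of genes monotonically
#'   increasing/decreasing with latent progression.
#' @param effect_size log-scale slope of the monotone programs.
#' @param frac_subtype_genes,subtype_effect proportion of genes and log-scale
#'   amplitude of a progression-orthogonal binary tumor-subtype program
#'   (emulating truncal-driver subtypes that dominate a higher principal
#'   component rather than the trajectory).
#' @param frac_stromal_genes,stromal_effect proportion of genes and log-scale
#'   amplitude of a continuous stromal-contamination gradient, a second
#'   structured axis orthogonal to progression.
#' @param batch_sd,tech_sd log-scale standard deviations of per-dataset and
#'   per-technology gene offsets.
#' @param dispersion negative-binomial dispersion (0 gives Poisson counts).
#' @param libsize_range min/max expected library size (counts per sample).
#' @param n_driver_mut,n_driver_cna numbers of progression-linked driver
#'   genes in the mutation and copy-number tables.
#' @param survival_beta log-hazard slope per unit latent progression.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 300L,
                          n_genes = 2000L,
                          stage_fractions = c(NORMAL = 174, PRIMARY = 714,
                                              CRPC = 316, NEPC = 19) / 1223,
                          n_datasets = 4L,
                          frac_hcs = 0.15,
                          n_replicate_pairs = 10L,
                          frac_up_genes = 0.2,
                          frac_down_genes = 0.2,
                          effect_size = 1.5,
                          frac_subtype_genes = 0.1,
                          subtype_effect = 1.2,
                          frac_stromal_genes = 0.1,
                          stromal_effect = 1.2,
                          batch_sd = 0.3,
                          tech_sd = 0.5,
                          dispersion = 0.15,
                          libsize_range = c(2e5, 1e6),
                          n_driver_mut = 10L,
                          n_driver_cna = 5L,
                          survival_beta = 2,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              stage_fractions = stage_fractions,
              n_datasets = as.integer(n_datasets), frac_hcs = frac_hcs,
              n_replicate_pairs = as.integer(n_replicate_pairs),
              frac_up_genes = frac_up_genes, frac_down_genes = frac_down_genes,
              effect_size = effect_size,
              frac_subtype_genes = frac_subtype_genes,
              subtype_effect = subtype_effect,
              frac_stromal_genes = frac_stromal_genes,
              stromal_effect = stromal_effect,
              batch_sd = batch_sd, tech_sd = tech_sd,
              dispersion = dispersion, libsize_range = as.numeric(libsize_range),
              n_driver_mut = as.integer(n_driver_mut),
              n_driver_cna = as.integer(n_driver_cna),
              survival_beta = survival_beta, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  sf <- cfg$stage_fractions
  if (length(sf) != 4L) stop("stage_fractions must have four entries")
  if (is.null(names(sf))) names(sf) <- STAGES
  if (!identical(sort(names(sf)), sort(STAGES)))
    stop("stage_fractions must be named NORMAL/PRIMARY/CRPC/NEPC")
  if (any(sf < 0)) stop("configuration error: negative stage fraction")
  if (abs(sum(sf) - 1) > 1e-12) stop("stage_fractions must sum to 1")
  counts <- c(cfg$n_samples, cfg$n_genes, cfg$n_datasets,
              cfg$n_replicate_pairs, cfg$n_driver_mut, cfg$n_driver_cna)
  if (any(counts < 0)) stop("configuration error: negative count field")
  if (cfg$frac_up_genes + cfg$frac_down_genes > 1)
    stop("frac_up_genes + frac_down_genes must not exceed 1")
  if (cfg$frac_subtype_genes < 0 || cfg$frac_stromal_genes < 0)
    stop("program gene fractions must be non-negative")
  if (cfg$frac_hcs < 0 || cfg$frac_hcs > 1) stop("frac_hcs must lie in [0,1]")
  if (cfg$dispersion < 0) stop("dispersion must be non-negative")
  if (length(cfg$libsize_range) != 2L || any(cfg$libsize_range <= 0) ||
      diff(cfg$libsize_range) < 0)
    stop("libsize_range must be an increasing pair of positive values")
  invisible(cfg)
}

# Stage-specific latent-progression intervals; stages overlap (tumors of
# adjacent stages intermix in PC space rather than separating discretely).
STAGE_INTERVALS <- list(NORMAL  = c(0.00, 0.25),
                        PRIMARY = c(0.10, 0.60),
                        CRPC    = c(0.45, 0.90),
                        NEPC    = c(0.80, 1.00))

# Deterministic apportionment of n samples across the four stages.
stage_counts_for <- function(fractions, n) {
  fr <- fractions[STAGES]
  cum <- round(cumsum(fr) * n)
  diff(c(0L, cum))
}

#' Generate a synthetic multi-study cohort
#'
#' Counts are drawn negative-binomially with mean
#' `libsize_s * exp(baseline_g + class_g * effect_size * t_s + batch + tech) / C`
#' where `t_s` is the latent progression of sample `s`, `class_g` is +1/-1/0
#' for UP/DOWN/NULL genes, batch and tech are dataset- and technology-specific
#' log offsets, and `C = sum_g exp(baseline_g)` is a fixed cohort-level
#' constant making `libsize_s` the approximate expected library size.
#' Technical replicate pairs share the latent sample (same `t_s`, baseline and
#' dataset offsets, patient, genotype, survival) and differ only in technology
#' offsets and sampling noise.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements `counts`
#'   (gene x sample integer matrix), `manifest` (data.frame with sample_id,
#'   patient_id, stage, dataset, library_tech, replicate_group,
#'   metastatic_site), `mutations` (0/1 gene x sample), `cna` (-2..2
#'   gene x sample), `survival` (sample_id, time, event) and `truth`
#'   (latent progression, gene classes, offsets, driver ids, survival and
#'   mutation model parameters).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_samples; G <- config$n_genes

  ## ---- latent structure -------------------------------------------------
  set.seed(split_seed(config$seed, "latent"))
  n_stage <- stage_counts_for(config$stage_fractions, n)
  stage <- rep(STAGES, times = n_stage)
  t_s <- unlist(lapply(seq_along(STAGES), function(k) {
    iv <- STAGE_INTERVALS[[STAGES[k]]]
    stats::runif(n_stage[k], iv[1], iv[2])
  }), use.names = FALSE)

  baseline <- stats::rnorm(G, mean = 2, sd = 1.5)
  n_up <- floor(config$frac_up_genes * G)
  n_dn <- floor(config$frac_down_genes * G)
  gene_class <- rep(c("UP", "DOWN", "NULL"), c(n_up, n_dn, G - n_up - n_dn))
  gene_class <- sample(gene_class)
  class_sign <- c(UP = 1, DOWN = -1, "NULL" = 0)[gene_class]

  ## progression-orthogonal structured axes: a binary tumor subtype and a
  ## continuous stromal-contamination gradient, each driving its own gene
  ## program (drawn among NULL genes where possible)
  draw_program <- function(frac, exclude) {
    size <- floor(frac * G)
    pool <- setdiff(which(gene_class == "NULL"), exclude)
    if (length(pool) < size) pool <- setdiff(seq_len(G), exclude)
    if (length(pool) < size) pool <- seq_len(G)
    idx <- sample(pool, size)
    load <- numeric(G)
    load[idx] <- sample(c(-1, 1), size, replace = TRUE)
    load
  }
  subtype_load <- draw_program(config$frac_subtype_genes, integer(0))
  stromal_load <- draw_program(config$frac_stromal_genes,
                               which(subtype_load != 0))
  subtype <- stats::rbinom(n, 1L, 0.5)
  stromal <- stats::runif(n)

  dataset <- paste0("DS", sample.int(config$n_datasets, n, replace = TRUE))
  n_hcs <- round(config$frac_hcs * n)
  tech <- rep("POLYA", n)
  tech[sample.int(n, n_hcs)] <- "HCS"

  batch_offsets <- matrix(stats::rnorm(G * config$n_datasets, 0, config$batch_sd),
                          nrow = G,
                          dimnames = list(NULL, paste0("DS", seq_len(config$n_datasets))))
  tech_offsets <- cbind(POLYA = rep(0, G),
                        TOTAL = rep(0, G),
                        HCS   = stats::rnorm(G, 0, config$tech_sd))
  libsize <- stats::runif(n, config$libsize_range[1], config$libsize_range[2])

  polya_idx <- which(tech == "POLYA")
  if (config$n_replicate_pairs > length(polya_idx))
    stop("configuration error: n_replicate_pairs exceeds PolyA+ samples (",
         length(polya_idx), " available)")
  rep_base <- if (config$n_replicate_pairs > 0)
    sort(sample(polya_idx, config$n_replicate_pairs)) else integer(0)

  gene_ids <- sprintf("G%05d", seq_len(G))
  sample_ids <- sprintf("S%04d", seq_len(n))
  patient_ids <- sprintf("P%04d", seq_len(n))

  ## replicate columns appended after base samples
  rep_ids <- if (length(rep_base)) paste0(sample_ids[rep_base], "_HCSrep") else character(0)
  all_ids <- c(sample_ids, rep_ids)
  col_src <- c(seq_len(n), rep_base)              # latent sample behind column
  col_tech <- c(tech, rep("HCS", length(rep_base)))
  rep_group <- rep(NA_character_, length(all_ids))
  if (length(rep_base)) {
    grp <- sprintf("RG%03d", seq_along(rep_base))
    rep_group[rep_base] <- grp
    rep_group[n + seq_along(rep_base)] <- grp
  }

  manifest <- data.frame(
    sample_id = all_ids,
    patient_id = patient_ids[col_src],
    stage = stage[col_src],
    dataset = dataset[col_src],
    library_tech = col_tech,
    replicate_group = rep_group,
    metastatic_site = NA_character_,
    stringsAsFactors = FALSE)

  ## ---- counts -----------------------------------------------------------
  set.seed(split_seed(config$seed, "counts"))
  C <- sum(exp(baseline))
  log_latent <- outer(class_sign * config$effect_size, t_s[col_src]) + baseline +
    outer(subtype_load * config$subtype_effect, subtype[col_src] - 0.5) +
    outer(stromal_load * config$stromal_effect, stromal[col_src] - 0.5)
  log_mu <- log_latent +
    batch_offsets[, dataset[col_src], drop = FALSE] +
    tech_offsets[, col_tech, drop = FALSE]
  mu <- exp(log_mu) * rep(libsize[col_src] / C, each = G)
  ncol_tot <- length(all_ids)
  if (config$dispersion > 0) {
    counts <- matrix(stats::rnbinom(G * ncol_tot, mu = mu,
                                    size = 1 / config$dispersion),
                     nrow = G)
  } else {
    counts <- matrix(stats::rpois(G * ncol_tot, lambda = mu), nrow = G)
  }
  dimnames(counts) <- list(gene_ids, all_ids)

  ## ---- genotype ---------------------------------------------------------
  set.seed(split_seed(config$seed, "genotype"))
  mut_logit_intercept <- -3; mut_logit_slope <- 2.5; passenger_rate <- 0.05
  n_mut_genes <- min(G, config$n_driver_mut * 4L)
  mut_genes <- sample(gene_ids, n_mut_genes)
  mut_drivers <- mut_genes[seq_len(config$n_driver_mut)]
  p_mut <- matrix(passenger_rate, nrow = n_mut_genes, ncol = n,
                  dimnames = list(mut_genes, sample_ids))
  p_mut[mut_drivers, ] <- rep(stats::plogis(mut_logit_intercept +
                                              mut_logit_slope * t_s),
                              each = length(mut_drivers))
  mutations <- matrix(stats::rbinom(length(p_mut), 1L, p_mut),
                      nrow = n_mut_genes, dimnames = dimnames(p_mut))

  n_cna_genes <- min(G, config$n_driver_cna * 2L)
  cna_pool <- setdiff(gene_ids, mut_genes)
  if (length(cna_pool) < n_cna_genes) cna_pool <- gene_ids
  cna_genes <- sample(cna_pool, n_cna_genes)
  cna_drivers <- cna_genes[seq_len(config$n_driver_cna)]
  cna_shift <- 1.5
  shift_sign <- stats::setNames(rep(0, n_cna_genes), cna_genes)
  shift_sign[cna_drivers] <- sample(c(-1, 1), config$n_driver_cna, replace = TRUE)
  latent_cna <- outer(shift_sign * cna_shift, t_s) +
    matrix(stats::rnorm(n_cna_genes * n), nrow = n_cna_genes)
  z <- (latent_cna - rowMeans(latent_cna)) /
    sqrt(pmax(row_vars(latent_cna), .Machine$double.eps))
  cna <- matrix(cut(z, breaks = c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
                    labels = FALSE) - 3L,
                nrow = n_cna_genes, dimnames = list(cna_genes, sample_ids))

  ## genotype is a property of the patient: replicate columns copy their base
  mutations <- mutations[, sample_ids[col_src], drop = FALSE]
  colnames(mutations) <- all_ids
  cna <- cna[, sample_ids[col_src], drop = FALSE]
  colnames(cna) <- all_ids

  ## ---- survival ---------------------------------------------------------
  set.seed(split_seed(config$seed, "survival"))
  base_hazard <- 0.05
  hazard <- base_hazard * exp(config$survival_beta * t_s)
  event_time <- stats::rexp(n, rate = hazard)
  censor_time <- stats::runif(n, 5, 50)
  surv <- data.frame(sample_id = sample_ids,
                     time = pmin(event_time, censor_time),
                     event = as.integer(event_time <= censor_time),
                     stringsAsFactors = FALSE)

  truth <- list(latent_progression = stats::setNames(t_s[col_src], all_ids),
                gene_class = stats::setNames(gene_class, gene_ids),
                subtype = stats::setNames(subtype[col_src], all_ids),
                stromal_fraction = stats::setNames(stromal[col_src], all_ids),
                subtype_loading = stats::setNames(subtype_load, gene_ids),
                stromal_loading = stats::setNames(stromal_load, gene_ids),
                batch_offsets = batch_offsets,
                tech_offsets = tech_offsets,
                driver_mut = mut_drivers,
                driver_cna = cna_drivers,
                cna_shift_sign = shift_sign,
                survival_params = list(base_hazard = base_hazard,
                                       beta = config$survival_beta),
                mutation_model = list(intercept = mut_logit_intercept,
                                      slope = mut_logit_slope,
                                      passenger_rate = passenger_rate),
                libsize = stats::setNames(libsize[col_src], all_ids))

  structure(list(counts = counts, manifest = manifest, mutations = mutations,
                 cna = cna, survival = surv, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", x$config$n_replicate_pairs, "replicate pairs )\n")
  print(table(x$manifest$stage)[STAGES])
  invisible(x)
}

#' Generate single cells around a bulk expression profile
#'
#' Each cell's counts are Poisson around `bulk_mean_profile / n_cells`,
#' thinned entry-wise by Bernoulli(1 - dropout) to emulate dropout.
#'
#' @param bulk_mean_profile named non-negative per-gene expected counts.
#' @param n_cells number of cells.
#' @param dropout dropout proportion in `[0, 1]`.
#' @param seed integer seed.
#' @return gene x cell integer count matrix.
#' @export
generate_single_cells <- function(bulk_mean_profile, n_cells, dropout = 0,
                                  seed = 1L) {
  if (any(bulk_mean_profile < 0) || anyNA(bulk_mean_profile))
    stop("bulk_mean_profile must be non-negative")
  if (dropout < 0 || dropout > 1) stop("dropout must lie in [0, 1]")
  if (n_cells < 1) stop("n_cells must be at least 1")
  G <- length(bulk_mean_profile)
  set.seed(split_seed(seed, "cells"))
  lam <- rep(bulk_mean_profile / n_cells, times = n_cells)
  cc <- matrix(stats::rpois(G * n_cells, lam), nrow = G)
  if (dropout > 0)
    cc <- cc * matrix(stats::rbinom(G * n_cells, 1L, 1 - dropout), nrow = G)
  dimnames(cc) <- list(names(bulk_mean_profile) %||% sprintf("G%05d", seq_len(G)),
                       sprintf("cell%04d", seq_len(n_cells)))
  cc
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Counts as gene x sample TSV (and optionally MTX triplet), manifest,
#' mutation, CNA and survival tables as TSV, ground truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param mtx also write the counts as a MatrixMarket triplet.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, mtx = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  if (mtx) write_counts(cohort$counts, file.path(dir, "counts.mtx"),
                        format = "mtx")
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_counts(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_counts(cohort$cna, file.path(dir, "cna.tsv"))
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$batch_offsets <- NULL; truth$tech_offsets <- NULL   # bulky matrices
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
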