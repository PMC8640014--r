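# End-to-end orchestration: simulate -> normalize -> correct-batch ->
# build-atlas -> fit-trajectory -> associate, as a single reproducible run
# with a machine-readable report.

#' Build a frozen atlas (normalization through pseudotime) from a cohort
#'
#' Runs the harmonization chain: shifted-log normalization, reference-batch
#' correction of the hybrid-capture technology against the PolyA+ reference,
#' high-variance gene selection on the PolyA+ training subset, the frozen
#' 3-component PCA embedding, the start-anchored principal-curve trajectory
#' (fitted without technical replicates so duplicated libraries do not
#' overweight the curve), and per-sample pseudotime.
#'
#' @param counts gene x sample raw count matrix.
#' @param manifest sample manifest (see [read_manifest()]).
#' @param reference_tech technology used as the untouched reference batch
#'   (default POLYA); technologies other than `correct_tech` are treated as
#'   reference-compatible.
#' @param correct_tech technology to correct (default HCS).
#' @param n_hvg number of high-variance genes (default 2000).
#' @param n_components embedding components (default 3).
#' @param start_stage trajectory anchor stage (default NORMAL).
#' @param smoother_span,scale_max trajectory parameters (see
#'   [fit_trajectory()]).
#' @param correct_batch set `FALSE` to skip batch correction (e.g. a
#'   single-technology cohort).
#' @return list of class `atlas` with `norm`, `batch_model` (or NULL),
#'   `corrected` (gene x sample matrix), `hvg_ids`, `embedding`,
#'   `trajectory`, `pseudotime` (data.frame over all samples) and
#'   `manifest`.
#' @export
build_atlas <- function(counts, manifest,
                        reference_tech = "POLYA", correct_tech = "HCS",
                        n_hvg = 2000L, n_components = 3L,
                        start_stage = "NORMAL", smoother_span = 0.6,
                        scale_max = 250, correct_batch = TRUE) {
  check_count_matrix(counts)
  mf <- manifest_for_samples(manifest, colnames(counts))
  norm <- normalize_counts(counts)

  corrected <- norm$values
  batch_model <- NULL
  if (correct_batch && any(mf$library_tech == correct_tech)) {
    # only the corrected technology forms a non-reference batch; everything
    # else is treated as reference-compatible
    batch <- ifelse(mf$library_tech == correct_tech, correct_tech,
                    reference_tech)
    batch_model <- fit_reference_batch_model(norm$values, batch,
                                             reference = reference_tech)
    corrected <- apply_batch_correction(norm$values, batch_model, batch)
  }

  training <- mf$sample_id[mf$library_tech == reference_tech]
  if (length(training) < 2L)
    stop("fewer than two ", reference_tech, " training samples for HVG selection")
  hvg_ids <- select_hvg(corrected, training, n_genes = n_hvg)
  embedding <- fit_embedding(corrected, hvg_ids, n_components = n_components)

  # drop technical replicates for the curve fit: keep the reference-technology
  # member of each replicate group
  rg <- mf$replicate_group
  drop <- !is.na(rg) & mf$library_tech != reference_tech
  dup_ref <- !is.na(rg) & mf$library_tech == reference_tech &
    duplicated(paste(rg, mf$library_tech))
  include <- mf$sample_id[!(drop | dup_ref)]

  traj <- fit_trajectory(embedding$coordinates[, 1:2, drop = FALSE],
                         stages = mf$stage, start_stage = start_stage,
                         include = include, smoother_span = smoother_span,
                         scale_max = scale_max)
  pt <- pseudotime(traj, embedding$coordinates[, 1:2, drop = FALSE])

  structure(list(counts = counts, norm = norm, batch_model = batch_model,
                 corrected = corrected, hvg_ids = hvg_ids,
                 embedding = embedding, trajectory = traj,
                 pseudotime = pt, manifest = mf,
                 trajectory_samples = include),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat("atlas:", nrow(x$corrected), "genes x", ncol(x$corrected), "samples;",
      length(x$hvg_ids), "HVGs;",
      if (is.null(x$batch_model)) "no batch correction" else "batch-corrected", "\n")
  print(x$trajectory)
  invisible(x)
}

#' Default pipeline configuration
#'
#' @param seed global seed propagated to every stochastic stage.
#' @param out_dir artifact directory.
#' @param cohort a [cohort_config()] for the simulate stage (its seed is
#'   overridden by `seed`).
#' @return nested configuration list for [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("trajatlas_run_"),
                               cohort = cohort_config(seed = seed)) {
  cohort$seed <- as.integer(seed)
  list(seed = as.integer(seed),
       out_dir = out_dir,
       simulate = list(enabled = TRUE, config = cohort),
       input = list(counts = NULL, manifest = NULL, mutations = NULL,
                    cna = NULL, survival = NULL),
       atlas = list(enabled = TRUE, reference_tech = "POLYA",
                    correct_tech = "HCS", n_hvg = 2000L, n_components = 3L,
                    start_stage = "NORMAL", smoother_span = 0.6,
                    scale_max = 250),
       associate = list(enabled = TRUE, genes = TRUE, mutations = TRUE,
                        cna = TRUE, survival = TRUE,
                        n_reps = 10L, keep_frac = 2/3, min_mutated = 6L,
                        n_tiers = 4L))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order (simulate or load inputs,
#' build the atlas, run the association analyses), writes every numeric
#' artifact under `config$out_dir`, and records a run report (per-stage
#' status, artifact paths and md5 checksums, seed) as `run_report.json`.
#' A failed stage aborts everything downstream.
#'
#' @param config configuration list from [default_run_config()].
#' @return list with `report`, plus the in-memory `cohort`, `atlas` and
#'   `associations` objects.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list(), artifacts = list())
  add_artifact <- function(name, path) {
    report$artifacts[[name]] <<- list(path = path,
                                      md5 = unname(tools::md5sum(path)))
  }

  ## ---- inputs -----------------------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    cohort <- generate_cohort(config$simulate$config)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    for (f in c("counts.tsv", "manifest.tsv", "mutations.tsv", "cna.tsv",
                "survival.tsv", "truth.json"))
      add_artifact(paste0("cohort/", f), file.path(out_dir, "cohort", f))
    counts <- cohort$counts; manifest <- cohort$manifest
    mutations <- cohort$mutations; cna <- cohort$cna; surv <- cohort$survival
    report$stages$simulate <- "ok"
  } else {
    cohort <- NULL
    if (is.null(config$input$counts) || is.null(config$input$manifest))
      stop("stage simulate disabled and no counts/manifest supplied; ",
           "enable simulate or set input$counts and input$manifest")
    counts <- read_counts(config$input$counts)
    manifest <- read_manifest(config$input$manifest)
    mutations <- if (!is.null(config$input$mutations))
      read_counts(config$input$mutations) else NULL
    cna <- if (!is.null(config$input$cna)) {
      m <- data.table::fread(config$input$cna, sep = "\t", data.table = FALSE)
      v <- as.matrix(m[, -1L]); rownames(v) <- m[[1L]]; v
    } else NULL
    surv <- if (!is.null(config$input$survival))
      utils::read.delim(config$input$survival, stringsAsFactors = FALSE) else NULL
    report$stages$simulate <- "skipped"
  }
  summary <- validate_manifest(manifest, counts)
  if (length(summary$errors))
    stop("stage normalize: manifest/counts mismatch: ", summary$errors[1])

  ## ---- atlas ------------------------------------------------------------
  if (!isTRUE(config$atlas$enabled))
    stop("stage fit-trajectory disabled; downstream stages need the atlas")
  ac <- config$atlas
  atlas <- build_atlas(counts, manifest,
                       reference_tech = ac$reference_tech,
                       correct_tech = ac$correct_tech, n_hvg = ac$n_hvg,
                       n_components = ac$n_components,
                       start_stage = ac$start_stage,
                       smoother_span = ac$smoother_span,
                       scale_max = ac$scale_max)
  save_embedding(atlas$embedding, file.path(out_dir, "embedding"))
  save_trajectory(atlas$trajectory, file.path(out_dir, "trajectory.json"))
  utils::write.table(atlas$pseudotime, file.path(out_dir, "pseudotime.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_artifact("embedding/coordinates.tsv",
               file.path(out_dir, "embedding", "coordinates.tsv"))
  add_artifact("trajectory.json", file.path(out_dir, "trajectory.json"))
  add_artifact("pseudotime.tsv", file.path(out_dir, "pseudotime.tsv"))
  report$stages$normalize <- "ok"
  report$stages$`correct-batch` <-
    if (is.null(atlas$batch_model)) "skipped" else "ok"
  report$stages$`build-atlas` <- "ok"
  report$stages$`fit-trajectory` <- "ok"

  ## ---- associations -----------------------------------------------------
  associations <- list()
  if (isTRUE(config$associate$enabled)) {
    sc <- config$associate
    if (is.null(atlas$pseudotime))
      stop("stage associate requires fit-trajectory output")
    ptv <- stats::setNames(atlas$pseudotime$pseudotime,
                           atlas$pseudotime$sample_id)
    if (isTRUE(sc$genes)) {
      associations$genes <- pseudotime_gene_correlation(
        atlas$corrected, ptv, n_reps = sc$n_reps, keep_frac = sc$keep_frac,
        seed = config$seed)
      utils::write.table(associations$genes,
                         file.path(out_dir, "assoc_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      add_artifact("assoc_genes.tsv", file.path(out_dir, "assoc_genes.tsv"))
    }
    mf <- atlas$manifest
    strata <- stats::setNames(
      ifelse(mf$stage %in% c("CRPC", "NEPC"), "CRPC_NEPC", "PRIMARY_NORMAL"),
      mf$sample_id)
    if (isTRUE(sc$mutations) && !is.null(mutations)) {
      associations$mutations <- tryCatch(
        mutation_association(mutations, ptv, min_mutated = sc$min_mutated,
                             strata = strata[colnames(mutations)]),
        error = function(e) { message("mutation screen: ", conditionMessage(e)); NULL })
      if (!is.null(associations$mutations)) {
        utils::write.table(associations$mutations,
                           file.path(out_dir, "assoc_mutations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        add_artifact("assoc_mutations.tsv",
                     file.path(out_dir, "assoc_mutations.tsv"))
      }
    }
    if (isTRUE(sc$cna) && !is.null(cna)) {
      associations$cna <- cna_association(cna, ptv,
                                          strata = strata[colnames(cna)])
      utils::write.table(associations$cna, file.path(out_dir, "assoc_cna.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      add_artifact("assoc_cna.tsv", file.path(out_dir, "assoc_cna.tsv"))
    }
    if (isTRUE(sc$survival) && !is.null(surv)) {
      met <- mf$sample_id[mf$stage %in% c("CRPC", "NEPC")]
      ss <- surv[surv$sample_id %in% met, , drop = FALSE]
      if (nrow(ss) >= sc$n_tiers && sum(ss$event) > 0) {
        tiers <- stratify_quartiles(
          ptv[ss$sample_id], n_tiers = sc$n_tiers,
          patient = stats::setNames(mf$patient_id, mf$sample_id)[ss$sample_id])
        groups <- stats::setNames(as.character(tiers$tier), tiers$sample_id)
        ss <- ss[ss$sample_id %in% names(groups), , drop = FALSE]
        associations$survival <- logrank_test(ss, groups)
        jsonlite::write_json(associations$survival,
                             file.path(out_dir, "assoc_survival.json"),
                             auto_unbox = TRUE, digits = NA)
        add_artifact("assoc_survival.json",
                     file.path(out_dir, "assoc_survival.json"))
      }
    }
    report$stages$associate <- "ok"
  } else {
    report$stages$associate <- "skipped"
  }

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, cohort = cohort, atlas = atlas,
                 associations = associations))
}
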