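# Reading and writing count matrices, manifests and gene sets.
#
# TSV dialect: tab-separated, UTF-8, header row, first column the gene id.
# MTX dialect: MatrixMarket coordinate format with companion row/column name
# files (one id per line), default `<stem>_genes.tsv` / `<stem>_samples.tsv`.

#' Read a gene x sample count matrix
#'
#' @param path file path (TSV or MTX).
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_file,samples_file companion name files for MTX input;
#'   default `<stem>_genes.tsv` and `<stem>_samples.tsv` next to `path`.
#' @return validated numeric matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        genes_file = NULL, samples_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE, check.names = FALSE)
    if (ncol(dt) < 2L) stop("format error: expected gene id column plus samples in ", path)
    gene_ids <- as.character(dt[[1L]])
    mat <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(mat))
      stop("format error: non-numeric count entries in ", path)
    rownames(mat) <- gene_ids
  } else {
    stem <- sub("\\.mtx$", "", path)
    genes_file <- genes_file %||% paste0(stem, "_genes.tsv")
    samples_file <- samples_file %||% paste0(stem, "_samples.tsv")
    m <- Matrix::readMM(path)
    gene_ids <- readLines(genes_file)
    sample_ids <- readLines(samples_file)
    if (nrow(m) != length(gene_ids) || ncol(m) != length(sample_ids))
      stop("format error: MTX dimensions disagree with name files for ", path)
    mat <- as.matrix(m)
    dimnames(mat) <- list(gene_ids, sample_ids)
  }
  check_count_matrix(mat)
  mat
}

#' Write a gene x sample matrix
#'
#' @param counts matrix with dimnames.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"` (coordinate integer plus name files).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry dimnames")
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(stem, "_genes.tsv"))
    writeLines(colnames(counts), paste0(stem, "_samples.tsv"))
  }
  invisible(path)
}

#' Read a sample manifest
#'
#' Required columns: sample_id, patient_id, stage, dataset, library_tech.
#' Optional: replicate_group, metastatic_site.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_manifest <- function(path) {
  mf <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  validate_manifest_frame(mf)
  mf
}

validate_manifest_frame <- function(mf) {
  req <- c("sample_id", "patient_id", "stage", "dataset", "library_tech")
  miss <- setdiff(req, names(mf))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  dup <- mf$sample_id[duplicated(mf$sample_id)]
  if (length(dup)) stop("duplicate sample id(s) in manifest: ",
                        paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(mf$stage), STAGES)
  if (length(bad)) stop("validation error: unknown stage label(s): ",
                        paste(bad, collapse = ", "))
  badt <- setdiff(unique(mf$library_tech), TECHS)
  if (length(badt)) stop("validation error: unknown library_tech label(s): ",
                         paste(badt, collapse = ", "))
  invisible(mf)
}

#' Summarize and cross-check a manifest against a count matrix
#'
#' @param manifest sample manifest data.frame.
#' @param counts optional count matrix; when supplied, samples missing from
#'   either side are reported in `$errors`.
#' @return list of class `cohort_summary`: `total`, `per_stage`,
#'   `per_dataset`, `n_replicates` (samples in a technical replicate group),
#'   `errors` (character vector of cross-check messages).
#' @export
validate_manifest <- function(manifest, counts = NULL) {
  if (nrow(manifest)) validate_manifest_frame(manifest)
  per_stage <- vapply(STAGES, function(s) sum(manifest$stage == s), integer(1))
  per_dataset <- if (nrow(manifest)) table(manifest$dataset) else table(character(0))
  n_rep <- if ("replicate_group" %in% names(manifest))
    sum(!is.na(manifest$replicate_group)) else 0L
  errors <- character(0)
  if (!is.null(counts)) {
    not_in_counts <- setdiff(manifest$sample_id, colnames(counts))
    not_in_manifest <- setdiff(colnames(counts), manifest$sample_id)
    errors <- c(
      if (length(not_in_counts))
        paste0("sample missing from counts: ", not_in_counts),
      if (length(not_in_manifest))
        paste0("sample missing from manifest: ", not_in_manifest))
  }
  structure(list(total = nrow(manifest), per_stage = per_stage,
                 per_dataset = per_dataset, n_replicates = n_rep,
                 errors = errors),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort:", x$total, "samples (", x$n_replicates, "in replicate groups )\n")
  print(x$per_stage)
  if (length(x$errors)) cat(length(x$errors), "cross-check error(s)\n")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene ids); descriptions in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("format error: GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}
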