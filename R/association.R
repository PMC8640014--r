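# Pseudotime-association analyses: resampled gene-pseudotime correlation,
# pre-ranked competitive gene-set testing, mutation and copy-number
# association, survival stratification with the log-rank test, and
# mRNA-protein fold-change concordance.
#
# Significance is reported as raw p, Benjamini-Hochberg q, and the field's
# -10*log10(q) scale on which the 0.05 threshold sits at 13.01.

as_pt_vector <- function(pt) {
  if (is.data.frame(pt)) stats::setNames(pt$pseudotime, pt$sample_id)
  else pt
}

assoc_frame <- function(feature_id, statistic, p_raw) {
  q <- stats::p.adjust(p_raw, method = "BH")
  data.frame(feature_id = feature_id, statistic = statistic, p_raw = p_raw,
             q_fdr = q, neg10log10_q = -10 * log10(q),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Significance on the -10*log10(FDR) scale
#'
#' @param q adjusted p value(s) in `(0, 1]`.
#' @return `-10 * log10(q)`; the conventional 0.05 threshold maps to 13.01.
#' @export
neglog_fdr <- function(q) {
  if (any(q <= 0) || any(q > 1)) stop("q must lie in (0, 1]")
  -10 * log10(q)
}

#' Resampled gene-pseudotime correlation screen
#'
#' For each of `n_reps` seeded random subsets of `ceiling(keep_frac * n)`
#' samples, the Pearson correlation between each gene's normalized expression
#' and pseudotime is computed; the reported statistic is the mean over
#' subsets (a leave-one-third-out scheme at the defaults, robustifying the
#' plain correlation against outliers).  p values come from the
#' t-distribution of the mean r at the full sample size, with BH FDR across
#' genes.
#'
#' @param X normalized gene x sample matrix.
#' @param pt pseudotime table (data.frame from [pseudotime()]) or named
#'   vector covering all columns of `X`.
#' @param n_reps number of random subsets (default 10).
#' @param keep_frac fraction of samples per subset (default 2/3);
#'   `keep_frac = 1` reduces to the plain full-sample correlation.
#' @param seed RNG seed for the subsets.
#' @return `AssociationResult` data.frame (feature_id, statistic, p_raw,
#'   q_fdr, neg10log10_q); constant genes are excluded and listed in the
#'   `"excluded"` attribute.
#' @export
pseudotime_gene_correlation <- function(X, pt, n_reps = 10L, keep_frac = 2/3,
                                        seed = 1L) {
  ptv <- as_pt_vector(pt)
  missing <- setdiff(colnames(X), names(ptv))
  if (length(missing))
    stop("pseudotime missing for sample(s): ", paste(missing, collapse = ", "))
  ptv <- ptv[colnames(X)]
  n <- ncol(X)
  if (n < 10L) stop("need at least 10 samples")
  constant <- row_vars(X) == 0
  excluded <- rownames(X)[constant]
  Xv <- X[!constant, , drop = FALSE]

  m <- ceiling(keep_frac * n)
  set.seed(seed)
  r_mat <- vapply(seq_len(n_reps), function(rep) {
    idx <- if (m >= n) seq_len(n) else sample.int(n, m)
    as.numeric(stats::cor(t(Xv[, idx, drop = FALSE]), ptv[idx]))
  }, numeric(nrow(Xv)))
  r_mean <- rowMeans(r_mat, na.rm = TRUE)

  # t-transform of the averaged r at the full sample size
  r_cl <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r_mean))
  tval <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  out <- assoc_frame(rownames(Xv), r_mean, p)
  attr(out, "excluded") <- excluded
  out
}

#' Pre-ranked competitive gene-set test
#'
#' Rank-based competitive test: for each set, the rank-sum of its members in
#' the supplied gene ranking is compared with its null expectation, with the
#' variance inflated by `1 + (m - 1) * rho` to account for inter-gene
#' correlation (m = set size), a two-sided normal p, and BH FDR over sets.
#'
#' @param ranked_stats named per-gene statistic (e.g. mean correlation to
#'   pseudotime); ranking is ascending, so positive z means the set sits at
#'   the top of the ranking.
#' @param gene_sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param rho assumed inter-gene correlation (default 0.01).
#' @param min_size sets with fewer overlapping members are skipped.
#' @return data.frame with set, n_genes, direction ("Up"/"Down"), z, p_raw,
#'   q_fdr, neg10log10_q.
#' @export
preranked_gene_set_test <- function(ranked_stats, gene_sets, rho = 0.01,
                                    min_size = 5L) {
  genes <- names(ranked_stats)
  if (is.null(genes)) stop("ranked_stats must be a named vector")
  N <- length(genes)
  ranks <- rank(ranked_stats)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], genes)
    m <- length(members)
    if (m == 0L) {
      warning("gene set '", nm, "' has no overlap with the ranking; skipped")
      return(NULL)
    }
    if (m < min_size || m == N) return(NULL)
    W <- sum(ranks[members])
    EW <- m * (N + 1) / 2
    VW <- m * (N - m) * (N + 1) / 12 * (1 + (m - 1) * rho)
    z <- (W - EW) / sqrt(VW)
    data.frame(set = nm, n_genes = m,
               direction = ifelse(z >= 0, "Up", "Down"),
               z = z, p_raw = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no gene set passed the size filter")
  rows$q_fdr <- stats::p.adjust(rows$p_raw, method = "BH")
  rows$neg10log10_q <- -10 * log10(rows$q_fdr)
  rows[order(rows$p_raw), , drop = FALSE]
}

#' Mutation-pseudotime association screen
#'
#' Per gene recurrently mutated in at least `min_mutated` samples (within
#' stratum), a two-tailed Wilcoxon rank-sum test compares the pseudotime of
#' mutant versus wild-type samples (normal approximation with tie
#' correction).  BH FDR is applied per stratum.  Genes mutated in all or no
#' samples of a stratum are excluded and reported.
#'
#' @param mut 0/1 gene x sample mutation matrix.
#' @param pt pseudotime table or named vector covering the samples.
#' @param min_mutated recurrence filter (default 6, i.e. more than five
#'   mutated individuals).
#' @param strata optional named per-sample grouping (e.g. primary vs
#'   metastatic); analyses run separately per stratum.
#' @return `AssociationResult` data.frame with an additional `stratum` and
#'   `n_mutated` column; statistic is the rank-sum W of the mutant group.
#'   Excluded genes per stratum in the `"excluded"` attribute.
#' @export
mutation_association <- function(mut, pt, min_mutated = 6L, strata = NULL) {
  ptv <- as_pt_vector(pt)
  missing <- setdiff(colnames(mut), names(ptv))
  if (length(missing))
    stop("pseudotime missing for sample(s): ", paste(missing, collapse = ", "))
  if (!all(mut %in% c(0L, 1L))) stop("mutation values must be 0/1")
  strata <- strata %||% stats::setNames(rep("all", ncol(mut)), colnames(mut))
  if (is.null(names(strata))) names(strata) <- colnames(mut)
  excluded <- list()
  out <- lapply(unique(strata), function(st) {
    ids <- colnames(mut)[strata[colnames(mut)] == st]
    M <- mut[, ids, drop = FALSE]
    ptx <- ptv[ids]
    n_mut <- rowSums(M)
    degenerate <- rownames(M)[n_mut >= min_mutated & n_mut == length(ids)]
    excluded[[st]] <<- degenerate
    test_genes <- rownames(M)[n_mut >= min_mutated & n_mut < length(ids)]
    if (!length(test_genes)) return(NULL)
    res <- lapply(test_genes, function(g) {
      mutant <- M[g, ] == 1
      if (stats::var(ptx) == 0)            # degenerate: no ordering information
        return(c(W = NA_real_, p = 1))
      w <- stats::wilcox.test(ptx[mutant], ptx[!mutant],
                              alternative = "two.sided",
                              exact = FALSE, correct = FALSE)
      c(W = unname(w$statistic), p = w$p.value)
    })
    res <- do.call(rbind, res)
    df <- assoc_frame(test_genes, res[, "W"], res[, "p"])
    df$stratum <- st
    df$n_mutated <- n_mut[test_genes]
    df
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no gene passes the recurrence filter (min_mutated = ",
                         min_mutated, ")")
  attr(out, "excluded") <- excluded
  out
}

#' Copy-number-pseudotime association
#'
#' Per gene, the Pearson correlation between the ordinal copy-number code
#' (-2 homozygous deletion .. 2 amplification) and pseudotime within each
#' stratum, with t-distribution p values and BH FDR.  Constant copy-number
#' vectors yield `NA` statistics (reported, not dropped silently).
#'
#' @param cna gene x sample matrix with values in -2..2.
#' @param pt pseudotime table or named vector.
#' @param genes optional whitelist of genes to test (e.g. recurrent prostate
#'   drivers); default all rows.
#' @param strata optional named per-sample grouping.
#' @return `AssociationResult` data.frame with `stratum` column.
#' @export
cna_association <- function(cna, pt, genes = NULL, strata = NULL) {
  if (!all(cna %in% -2:2)) stop("CNA values must lie in -2..2")
  ptv <- as_pt_vector(pt)
  genes <- genes %||% rownames(cna)
  genes <- intersect(genes, rownames(cna))
  strata <- strata %||% stats::setNames(rep("all", ncol(cna)), colnames(cna))
  if (is.null(names(strata))) names(strata) <- colnames(cna)
  out <- lapply(unique(strata), function(st) {
    ids <- colnames(cna)[strata[colnames(cna)] == st]
    ptx <- ptv[ids]
    res <- vapply(genes, function(g) {
      x <- cna[g, ids]
      if (stats::var(x) == 0 || stats::var(ptx) == 0)
        return(c(r = NA_real_, p = NA_real_))
      ct <- stats::cor.test(x, ptx, method = "pearson")
      c(r = unname(ct$estimate), p = ct$p.value)
    }, numeric(2))
    df <- assoc_frame(genes, res["r", ], res["p", ])
    df$stratum <- st
    df
  })
  do.call(rbind, out)
}

#' Stratify samples into pseudotime tiers (quartiles by default)
#'
#' Samples are sorted by ascending pseudotime (ties broken by sample id) and
#' split into `n_tiers` contiguous groups.  When the count is not divisible,
#' the remainder goes to the lower tiers, so group sizes differ by at most
#' one with the larger groups first (79 samples give 20/20/20/19).  When
#' `patient` is supplied, only the highest-pseudotime sample per patient is
#' kept before stratifying.
#'
#' @param pt pseudotime table or named vector.
#' @param n_tiers number of tiers (default 4: Q1..Q4).
#' @param patient optional named per-sample patient ids for deduplication.
#' @return data.frame with sample_id, pseudotime, tier (factor Q1..Qk).
#' @export
stratify_quartiles <- function(pt, n_tiers = 4L, patient = NULL) {
  ptv <- as_pt_vector(pt)
  if (is.null(names(ptv))) names(ptv) <- as.character(seq_along(ptv))
  if (!is.null(patient)) {
    patient <- patient[names(ptv)]
    keep <- unlist(lapply(split(names(ptv), patient), function(ids) {
      ids[order(-ptv[ids], ids)][1L]    # keep the higher-pseudotime sample
    }), use.names = FALSE)
    ptv <- ptv[names(ptv) %in% keep]
  }
  n <- length(ptv)
  if (n < n_tiers) stop("fewer samples (", n, ") than tiers (", n_tiers, ")")
  ord <- order(ptv, names(ptv))
  base <- n %/% n_tiers; rem <- n %% n_tiers
  sizes <- rep(base, n_tiers) + c(rep(1L, rem), rep(0L, n_tiers - rem))
  tier <- rep(paste0("Q", seq_len(n_tiers)), times = sizes)
  data.frame(sample_id = names(ptv)[ord],
             pseudotime = unname(ptv[ord]),
             tier = factor(tier, levels = paste0("Q", seq_len(n_tiers))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' k-group log-rank test
#'
#' Standard log-rank comparison of survival across tiers: at each distinct
#' event time, observed versus expected events per group under the
#' hypergeometric null, chi-square with k-1 degrees of freedom.  Groups
#' without events stay in the expected-event accounting.
#'
#' @param surv data.frame with sample_id, time (> 0), event (0/1).
#' @param groups named per-sample group labels (e.g. tiers from
#'   [stratify_quartiles()]).
#' @return list with `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(surv, groups) {
  if (any(surv$time <= 0)) stop("survival times must be positive")
  g <- groups[surv$sample_id]
  if (anyNA(g)) stop("group label missing for sample(s): ",
                     paste(surv$sample_id[is.na(g)], collapse = ", "))
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least two non-empty groups")
  if (sum(surv$event) == 0L) stop("no events; log-rank undefined")
  fit <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
  df <- length(fit$n) - 1L
  chi <- unname(fit$chisq)
  list(chi_square = chi, df = df, p = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Log2 fold change between two sample groups
#'
#' Difference of group means on the (already log-scale) normalized values,
#' per gene.
#'
#' @param X normalized gene x sample matrix.
#' @param samples_a,samples_b sample ids of the two groups (a minus b).
#' @return named per-gene log2 fold change.
#' @export
log2_fold_change <- function(X, samples_a, samples_b) {
  rowMeans(X[, samples_a, drop = FALSE]) - rowMeans(X[, samples_b, drop = FALSE])
}

#' Fold-change concordance between two modalities
#'
#' Pearson correlation between two per-gene log2 fold-change vectors (e.g.
#' mRNA and protein CRPC-vs-primary changes) over their gene intersection;
#' genes absent in either modality are dropped and counted.
#'
#' @param fc_a,fc_b named per-gene log2 fold changes.
#' @return list with `r`, `p`, `n_common`, `n_dropped`.
#' @export
fc_concordance <- function(fc_a, fc_b) {
  common <- intersect(names(fc_a), names(fc_b))
  if (length(common) < 3L)
    stop("fewer than 3 genes shared between the two modalities")
  ct <- stats::cor.test(fc_a[common], fc_b[common], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_common = length(common),
       n_dropped = length(fc_a) + length(fc_b) - 2L * length(common))
}
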