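# Shared fixtures, built in code at test time.

# Small all-PolyA cohort without replicate pairs: recomputed PCA stays
# comparable to the frozen one, which keeps projection tests fast and clean.
small_cohort <- function(seed = 2, n = 120, genes = 400, ...) {
  generate_cohort(cohort_config(
    n_samples = n, n_genes = genes, seed = seed,
    frac_hcs = 0, n_replicate_pairs = 0, ...))
}

# Deterministic toy count matrix with dimnames.
toy_counts <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# Manifest matching a count matrix, single stage/technology by default.
toy_manifest <- function(sample_ids, stage = "PRIMARY", tech = "POLYA",
                         dataset = "DS1") {
  data.frame(sample_id = sample_ids,
             patient_id = paste0("pat_", sample_ids, recycle0 = TRUE),
             stage = rep_len(stage, length(sample_ids)),
             dataset = rep_len(dataset, length(sample_ids)),
             library_tech = rep_len(tech, length(sample_ids)),
             replicate_group = rep(NA_character_, length(sample_ids)),
             metastatic_site = rep(NA_character_, length(sample_ids)),
             stringsAsFactors = FALSE)
}
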