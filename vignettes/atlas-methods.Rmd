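---
title: "Methods: building and querying a progression atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and querying a progression atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajatlas)
```

# Overview

trajatlas harmonizes bulk RNA-seq cohorts that span several studies, library
technologies and disease stages into a single frozen principal-component
atlas, orders samples along a start-anchored principal curve ("pseudotime",
reported on a 0–250 scale), places new bulk samples or single cells onto the
frozen atlas without refitting it, and screens genes, gene sets, somatic
mutations, copy-number calls and survival for association with pseudotime.
The intended application is staged tumor progression — normal tissue through
primary disease to castration-resistant and neuroendocrine prostate cancer —
but nothing in the machinery is tissue-specific.

This vignette explains each model, its assumptions, the tunable parameters,
the numerical choices, and what the synthetic cohorts used in the test suite
do and do not establish about real data.

# Normalization

`size_factors()` implements median-of-ratios library-size estimation: per
sample, the median over genes (restricted to genes with positive counts in
every sample) of the ratio between the sample's count and the gene's
geometric mean.  `vst()` then applies a shifted-log transform,
`log2(count / size_factor + 1)`.

A dispersion-trend variance-stabilizing transform is a common alternative;
the shifted log was chosen because it is fully specified, monotone,
library-size-free, and roughly variance-stabilizing for the count ranges the
atlas works with.  It is deliberately isolated behind the single `vst()`
operation so a different transform can be swapped in without touching any
downstream module.  One consequence worth knowing: the shifted log is
*exactly* invariant under re-normalization of the identical sample set, so
coordinate drift on projection (below) arises only when the merged cohort
actually differs from the frozen one.

Degenerate inputs: samples with all-zero counts, and cohorts without a
single everywhere-positive gene, are errors rather than silent NaNs.

# Reference-batch correction

Library technology (PolyA+ selection versus hybrid-capture sequencing, HCS)
shifts and rescales per-gene log expression.  `fit_reference_batch_model()`
implements the parametric empirical-Bayes location/scale model with a
designated *reference batch*: genes are standardized by the reference
batch's mean and pooled standard deviation; each other batch receives
per-gene location (γ) and scale (δ²) estimates that are shrunk toward
batch-level normal and inverse-gamma priors fitted by moments; the coupled
posterior updates are iterated to relative tolerance 1e-6 (at most 100
iterations).  `apply_batch_correction()` moves non-reference batches onto
the reference and returns reference samples bit-for-bit unchanged — the
property that lets the PolyA+ majority define the atlas scale.

Choices: only the parametric variant is implemented; per-gene reference
standard deviations are floored at `1e-8 * sd(X)` so constant genes cannot
blow up the standardization; no biological covariates enter the batch
design — biology is instead protected by selecting high-variance genes on
the PolyA+-only training subset (next section).  By default only HCS is
treated as a non-reference batch; total-RNA libraries are treated as
reference-compatible unless declared otherwise.  The model is fitted on all
samples with technology as the batch factor (fitting only on
replicate-anchored samples is possible by subsetting the input).

# The frozen embedding

`select_hvg()` ranks genes by variance across a *training subset* —
by default all PolyA+ samples — and keeps the top 2000 (ties broken
lexicographically by gene id so serialized atlases are reproducible).
Restricting the ranking to one technology prevents genes whose variance is
technology-driven from entering the embedding even after correction.
The default of 2000 genes follows the convention of scaling the usual
500-gene PCA default by the ~4x larger annotation universe the atlas
quantifies against.

`fit_embedding()` centers the selected genes (no unit scaling — variance
ranking already weights genes, and rescaling would undo it) and computes the
top three principal components by SVD.  Each component's sign is fixed so
its largest-magnitude loading is positive.  The embedding — HVG list,
centers, rotation, reference coordinates — is frozen and serializable
(`save_embedding()` / `load_embedding()`).

# The trajectory

`fit_trajectory()` fits a single-lineage principal curve through the PC1–PC2
cloud.  Initialization is the minimum-spanning-tree path through the stage
centroids rooted at the start stage (normal tissue), with both ends extended
along their tangents to the data's projection extent so extreme samples
order along the tangent instead of piling up at the first or last centroid.
A non-path MST raises a branch warning and the depth-first order is used.

The refinement loop alternates (i) orthogonal projection of all samples onto
the current polyline, (ii) smoothing each coordinate against arc length with
non-robust lowess (span 0.6 of the samples), evaluated on an even
100-vertex arc-length grid, and (iii) *shrinking the smoothed curve toward
the centroid backbone* with weight 0.7.  The shrinkage is the one genuinely
open design decision in this module and deserves its rationale: an
unregularized principal curve monotonically decreases the total squared
projection distance by bending its ends into the dense stage clusters,
soaking up noise variance orthogonal to the progression — the fitted curve
"flaps" and the sample ordering at the extremes degrades with every
iteration.  Anchoring each update to the stage-level geometry removes the
pathology while the smoother still captures within-path curvature such as
the arch that a 1-D expression gradient produces in PC space.  The
non-robust smoother (no residual reweighting) makes the whole fit exactly
equivariant under rotations and translations of the coordinates.

Convergence is declared when the curve stops moving (maximum vertex
displacement below 0.1% of the data scale), when the projection SSE changes
by less than 1e-4 relatively, or when the SSE has not improved for five
iterations (grid resampling leaves a sub-0.1% limit-cycle jitter even at the
fixed point); the cap is 50 iterations.

`pseudotime()` projects any point orthogonally onto the polyline and reports
`scale_factor * arc length`, where the scale factor maps the furthest fitted
reference sample to 250.  Points beyond the curve ends clamp to 0 or 250
rather than extrapolate.  Technical replicates should be excluded from the
fit (the `include` argument; `build_atlas()` does this automatically,
keeping the PolyA+ member of each replicate pair) so duplicated libraries do
not overweight the curve; they still *receive* pseudotime.

# Projecting new samples

Adding a sample to a cohort changes the per-gene geometric means and the PCA
centering, so a recomputed embedding disagrees slightly with the frozen one;
the displacement is approximately an affine distortion of the coordinate
system.  `project_sample()` therefore: merges the new sample's raw counts
with the reference counts; re-runs normalization and (if the atlas used one)
the frozen batch model on the merged matrix — the new sample itself is
treated as PolyA-like unless `new_batch` declares otherwise; recomputes the
PCA on the frozen HVG list; aligns recomputed components to the originals by
greedy maximal-|correlation| signed matching (an alignment correlation below
0.8 on any component is an error — the reference snapshot is then too
perturbed for a signed permutation to bridge); fits one elastic-net model
per component predicting the reference samples' coordinate error (original
minus recomputed) from their recomputed top-3 coordinates; and corrects the
new sample's recomputed coordinate by the predicted error.  Pseudotime
follows from the corrected PC1–PC2 position.

Elastic-net specifics: mixing parameter 0.5, penalty chosen by 5-fold
cross-validation with a fixed fold seed (so projections are bit-reproducible),
prediction at the CV-optimal penalty.  The three recomputed coordinates plus
an intercept are the feature set — affine drift needs nothing richer, and
the per-sample refit stays cheap.  A constant (zero-variance) drift response
short-circuits to its mean, since penalized regression is undefined there.
Up to 2% of HVGs may be missing from a new sample; they are imputed at the
recomputed center value.  Samples are projected one at a time, and the
frozen atlas objects are never mutated.

# Single cells

`pseudobulk()` sums gene counts over cells into one bulk-comparable
meta-sample.  `impute_diffusion()` mitigates dropout by Markov-affinity
diffusion: a kNN graph on cells (Euclidean distance in the cells' top 20
principal components), an adaptive Gaussian kernel whose per-cell bandwidth
is the distance to the `ceiling(k/3)`-th neighbor, symmetrization, row
normalization to a Markov operator M, and smoothing of expression by `M^t`
(defaults k = 15, t = 3; t = 0 is the identity, and row-stochasticity leaves
constant genes untouched).  `project_cells()` projects either cluster
pseudobulks (clusters are caller-supplied labels, not discovered here) or —
after imputation and rescaling of each cell to the median reference library
size, which prevents size-factor pathologies on sparse profiles — individual
cells.

# Association analyses

*Genes.*  `pseudotime_gene_correlation()` repeats a leave-one-third-out
Pearson correlation: 10 seeded random subsets of 2/3 of the samples, the
per-gene correlation in each, and the mean across subsets as the reported
statistic — more robust to outliers than a single full-sample correlation,
to which it reduces when `keep_frac = 1`.  The p value transforms the mean r
through the t-distribution at the full sample size; how to attach a p value
to an averaged correlation is genuinely underdetermined, and this choice is
simple, slightly conservative in the tails, and calibrated in the null
simulations of the test suite.  Benjamini–Hochberg FDR is applied across
genes and significance is reported as −10·log10(q), a scale on which the
0.05 threshold sits at 13.01.

*Gene sets.*  `preranked_gene_set_test()` is a rank-based competitive test:
the rank-sum of a set's members against its null expectation, with the
variance inflated by `1 + (m − 1)·rho` for inter-gene correlation
(rho = 0.01 by default, the conventional figure for this family of tests)
and a two-sided normal p.  With rho = 0 it reduces exactly to the classic
Wilcoxon rank-sum z.

*Mutations.*  `mutation_association()` compares mutant versus wild-type
pseudotime per gene with a two-tailed Wilcoxon rank-sum test, restricted to
genes mutated in at least 6 samples within the analysis stratum (primary and
CRPC/NEPC tumors are screened separately when strata are given).  The normal
approximation uses the tie correction but *not* the continuity correction:
on a balanced 12-sample fixture with complete separation the
continuity-corrected p (0.0051) overshoots the exact enumeration p (0.00216)
by more than a factor 2, while the uncorrected approximation stays within
it; for screens at these sample sizes the uncorrected version tracks the
exact test better.  Constant pseudotime yields p = 1 by convention.

*Copy number.*  `cna_association()` correlates the ordinal −2..2 code with
pseudotime per gene (Pearson, t-distribution p), intended for a small
whitelist of recurrently altered drivers; constant vectors report NA rather
than disappearing.

*Survival.*  `stratify_quartiles()` sorts by pseudotime (ties broken by
sample id) and splits into four contiguous tiers; when the count is not
divisible the remainder goes to the *lower* tiers, the unique rule that
yields 20/20/20/19 for 79 samples.  When a patient contributes several
samples only the highest-pseudotime one is kept.  `logrank_test()` is the
standard k-group log-rank (via the survival package) with k−1 degrees of
freedom; groups whose events are all censored stay in the expected-event
accounting.

*Cross-modality.*  `fc_concordance()` correlates two per-gene log2
fold-change vectors (e.g. mRNA and protein CRPC-versus-primary changes) over
their gene intersection, dropping and counting genes absent in either
modality.

# The synthetic cohort generator

`generate_cohort()` draws a multi-study cohort with known ground truth, so
every recovery claim in the test suite is checked against the generating
latent state.  Per sample, a latent progression t is drawn uniformly within
overlapping stage intervals ([0, 0.25] normal, [0.1, 0.6] primary,
[0.45, 0.9] CRPC, [0.8, 1] NEPC) — stages overlap in expression space
rather than separating discretely.  Counts are negative binomial with mean
`libsize_s · exp(baseline_g + class_g·effect·t_s + subtype and stromal
programs + dataset offset + technology offset) / C`, where baselines are
N(2, 1.5²) on the natural-log scale, C is the fixed cohort-level sum of
baseline intensities (so `libsize_range`, default 2e5–1e6, is the expected
sequencing depth), and dispersion defaults to 0.15.  20% of genes rise and
20% fall monotonically with slope `effect_size` (default 1.5).  Two further
structured axes are orthogonal to progression: a binary tumor-subtype
program and a continuous stromal-contamination gradient (10% of genes each,
log-amplitude 1.2).  They emulate the truncal-driver and stromal axes that
occupy the higher principal components of real pan-cohort data; without
them the synthetic PC2/PC3 subspace is noise-degenerate and per-component
alignment of a recomputed embedding is ill-posed, so the projection module
could not be exercised meaningfully.

Dataset and technology offsets are per-gene N(0, batch_sd²) and
N(0, tech_sd²) on the log scale; stage composition follows the 174/714/316/19
proportions of a large published pan-cohort; a configurable number of
technical replicate pairs shares the latent sample, dataset, patient,
genotype and survival between a PolyA+ and an HCS column.  Driver mutations
are Bernoulli with logit −3 + 2.5·t (passengers constant at 5%); copy-number
codes arise by thresholding a standardized latent Gaussian with mean shifted
by ±1.5·t for drivers at cuts (−1.5, −0.5, 0.5, 1.5); survival is
exponential with hazard 0.05·exp(β·t), β = 2, under uniform censoring.
One RNG stream per purpose (latent structure, counts, genotype, survival)
is derived deterministically from the seed, so enabling an extra output
never perturbs the others.  `generate_single_cells()` thins Poisson draws
around a bulk profile split over cells with entry-wise Bernoulli dropout.

What the generator does *not* emulate: isoform and length effects, gene-gene
correlation beyond the shared latent factors, realistic mutation spectra,
multi-lineage branching, doublets, or spatial structure.  Tests passing on
these cohorts demonstrate that the pipeline recovers the structure it
assumes — a dominant 1-D progression with technology batches — not that real
cohorts satisfy those assumptions.

# Problem sizes and reproducibility

The test suite and the acceptance script run the stochastic checks at the
cohort sizes the method is designed around, scaled for a desk run: recovery
of latent progression on five 300-sample, 2000-gene cohorts (Spearman ≥ 0.9
expected in at least 4 of 5); drift-corrected projection of 20 held-out
samples against a 180-of-200 reference snapshot on 500-gene cohorts; batch
recovery on 400 genes × 2 × 200 samples; null calibration on 2000 null
genes, 1000 random gene sets and 2000 label permutations.  Every stochastic
step in the package funnels through explicit seeds (cohort seed, subset
seed, CV fold seed), and the pipeline's `run_report.json` records artifact
checksums so a rerun at the same seed is verifiably identical.

# Known limitations

Single lineage only — branch detection is out of scope and a non-path stage
MST only warns.  The pseudotime scale is a convention (furthest reference
sample = 250), so pseudotimes are comparable within one atlas, not across
atlases.  The drift correction assumes the reference snapshot is a modest
perturbation of the frozen cohort; component alignment refuses (by design)
when a perturbation rotates the embedding beyond what a signed permutation
can express.  The shifted-log transform slightly compresses very low counts
relative to a dispersion-aware transform; swapping `vst()` is the supported
escape hatch.
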