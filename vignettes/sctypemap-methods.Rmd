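---
title: "Methods: whole-body single-cell expression mapping with sctypemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body single-cell expression mapping with sctypemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctypemap)
```

## Overview

`sctypemap` implements the analysis behind whole-body single-cell
expression atlases that integrate many per-tissue droplet scRNA-seq
datasets with matched bulk RNA-seq. The pipeline is *pseudo-bulk
centric*: instead of modelling individual cells, annotated cell
clusters are pooled into deep, bulk-like expression profiles, and all
gene-centric statistics are computed on those profiles. The stages
are:

1. per-cell quality control with per-tissue thresholds;
2. pooling of cells by cluster and normalization to nTPM;
3. exclusion of clusters with unreliable annotation;
4. aggregation of clusters into consensus cell types;
5. five-category specificity classification plus the tau score;
6. single-cell vs bulk concordance analyses;
7. deconvolution of bulk tissues against an enriched-gene signature.

A synthetic-data generator with planted, recorded ground truth stands
in for external accessions, so every stage is testable end to end.

## Quality control

For every cell we compute the number of detected genes (count > 0),
total UMI counts, and the percentage of counts on
mitochondrial-flagged and ribosomal-flagged genes, plus an externally
supplied doublet score. A cell is kept only if it passes **all**
thresholds; removal counts attribute each removed cell to every
criterion it fails, which keeps filter reports order-independent.
Percentages are computed on raw counts (the standard QC definition),
and filtering acts on cells only — genes are never dropped at this
stage, because the classifier is meant to operate on the full gene
universe (undetected genes become the `not_detected` category rather
than disappearing).

Defaults (`min_genes = 200`, `max_pct_mito = 20`,
`max_doublet_score = 0.25`, other bounds infinite) are
common-practice values for droplet data; organ-specific thresholds
are configuration (`qc_thresholds(overrides = ...)`), not code, since
real atlases tune them per dataset.

## Pseudo-bulk profiles and nTPM

Pooling sums UMI counts over all cells of a cluster. Pooled columns
are scaled to counts per million (no gene-length term — UMI data),
then adjusted by trimmed-mean-of-M-values (TMM) scaling factors:

nTPM(g, c) = CPM(g, c) / f(c),

with the factors f computed by `edgeR::calcNormFactors` (reference
column = upper quartile closest to the mean; doubly trimmed,
inverse-variance-weighted mean of M-values; geometric mean rescaled
to 1; genes zero in either column excluded). "Normalized TPM" in
atlas practice is exactly this TMM-adjusted CPM; the package adopts
the standard published trim fractions (M: 0.3, A: 0.05) and keeps
them as parameters. TMM is computed **within** each tissue's set of
clusters when a grouping is supplied (`ntpm(x, groups = ...)`),
matching the per-dataset processing of multi-source atlases; whether
to normalize within tissue or across all clusters jointly is a
genuinely open choice, and both are available.

nTPM column sums need not equal 1e6 once factors differ from 1; this
is a documented property, not an error. Within a column the gene
ranking is preserved (positive scaling).

Clusters graded `low` or `very_low` by the annotation curators are
excluded before any downstream statistic (`filter_reliability`);
retained factors are not recomputed.

## Consensus cell types

The consensus profile of a cell type is the **unweighted** arithmetic
mean of its contributing cluster profiles. Cell-count weighting was
deliberately rejected: a single very large cluster (e.g. one donor's
dominant cluster) would otherwise dominate the consensus of a
cell type observed in many tissues.

Similarity between profiles is summarised by Spearman's rho (average
ranks on ties; constant profiles yield missing values that are
reported, not silently imputed), and the consensus dendrogram is
agglomerative clustering of distance 1 − rho under the Ward-D2
criterion. Units are ordered lexicographically before clustering so
tied merges are reproducible; the tree exports to Newick.

Two display transforms mirror atlas user interfaces: per-gene
z-scores across cell types (constant rows become zeros and are
flagged), and the per-cell "% of max" transform

log2(read_count + 1) / log2(max(read_count) + 1) × 100,

binned as `<1%`, `<25%`, `<50%`, `<75%`, `>=75%`. An all-zero gene
maps every cell to 0% in the lowest bin.

## Specificity classification

Each gene's nTPM vector x over K cell types is assigned exactly one
of five categories, first match wins, with detection limit
`detection_limit = 1` nTPM and enrichment ratio `fold_threshold = 4`
(the atlas convention; the ratio is a parameter, not a constant):

1. **not detected** — max(x) < 1;
2. **cell type enriched** — the unique maximum is at least 4× the
   second-largest value;
3. **cell type group enriched** — the smallest group size g in
   2..`max_group_size` (default 10) whose top-g values (descending,
   ties broken by cell-type id) have mean ≥ 4× the largest remaining
   value, with every member detected;
4. **cell type enhanced** — some detected type is ≥ 4× the mean of
   all *other* types; all such types are reported;
5. **low cell type specificity** — otherwise.

Comparisons are multiplicative throughout, so a zero background never
divides. Three boundary decisions deserve note:

* an exact tie at the maximum falls through to the group rule — "a
  single cell type" is only unambiguous without ties;
* group members must each clear the detection limit (an undetected
  "group-enriched" member is biologically incoherent);
* the prefix search over the sorted vector is provably equivalent to
  exhaustive search over all subsets of size ≤ `max_group_size`
  (if any qualifying subset of size g exists, the top-g prefix
  qualifies); the test suite verifies this equivalence exhaustively
  on a small alphabet.

### Tau

tau = Σᵢ (1 − xᵢ/max(x)) / (K − 1) ranges from 0 (uniform
expression) to 1 (expression exclusive to one cell type) and is
undefined (missing) for genes below the detection limit everywhere.
Tau is computed on untransformed nTPM, matching the normalized-
expression form of the original definition; a `log2(x + 1)` variant
is available behind a flag since the literature varies on this point.

### Distribution categories

With d = #{types ≥ detection limit}: `not_detected` (d = 0),
`detected_in_single` (d = 1), `detected_in_some` (1 < d < K/3),
`detected_in_many` (K/3 ≤ d < K), `detected_in_all` (d = K). The
one-third boundary is the documented atlas convention and is kept
configurable through the parameter object.

## Single-cell vs bulk concordance

The same classifier applied to gene × tissue bulk nTPM yields
tissue-level categories, enabling a category crosstab over the shared
gene universe, Spearman concordance of tau, and a detectability
partition (both / single-cell only / bulk only / neither), with
bulk-only genes annotated by their maximum bulk expression and
single-cell-only genes by their distribution category.

Concordance between the continuous tau and the ordinal category
scheme uses the **polyserial correlation**, estimated by the two-step
(ad hoc) estimator: thresholds are normal quantiles of the cumulative
category proportions and

rho = r · s_y / Σₖ φ(τ̂ₖ),

with r the Pearson correlation of tau with the integer-coded
category and s_y the population (1/n) standard deviation. The
population form was chosen deliberately: with a binary ordinal the
estimator then reduces *exactly* to the textbook biserial
correlation, which the tests assert. Categories are ordered
low specificity < enhanced < group enriched < enriched; not-detected
genes are excluded (tau undefined). Full maximum likelihood was
rejected: the closed-form estimator is deterministic, adequate for a
concordance summary, and easy to validate against simulation.

The paired difference between single-cell and bulk tau uses a
one-sided Wilcoxon signed-rank test (zero differences dropped); a
paired nonparametric test is the natural choice for bounded,
non-normal scores.

## Deconvolution

The signature matrix restricts the consensus profile to genes
classified **enriched**; cell types without any enriched gene are
flagged unidentifiable. Bulk composition is estimated by dampened
weighted least squares (DWLS): starting from the nonnegative
least-squares solution projected to the simplex, iterate

* weights wⱼ = 1 / max((S p)ⱼ, ε)², ε = 1e−8 (floors zero-predicted
  genes);
* dampening: cap every weight at d × min positive weight — d = 1 is
  ordinary (uniform-weight) NNLS, large d approaches raw relative
  weighting;
* weighted NNLS, renormalize to the simplex; stop when max|Δp| <
  1e−6 or after 100 iterations (non-convergence is flagged, not
  fatal).

The dampening constant is selected from the grid 2⁰..2¹⁴ by 4-fold
cross-validation over signature genes, minimizing held-out *relative*
squared error. Two details matter: the held-out weights are uncapped
(1/prediction²), because a d-dependent error metric is not comparable
across the grid; and folds are stratified by each signature gene's
marker type so every fold retains markers of every cell type. The
fold assignment is deterministic given `fold_seed`. The bulk vector
is renormalized to the per-million scale before solving, as a scale
mismatch would otherwise bias the weights.

The inner nonnegative solver is a Lawson–Hanson active-set
implementation normalised by max|A| so its tolerances are scale-free
on per-million expression values; it is cross-checked against an
independent NNLS implementation in the tests.

Enriched-gene overlap between cell types and tissues is tested by the
hypergeometric upper tail P(X ≥ k), with Benjamini–Hochberg
correction across all pairs and significance reported at q < 0.05
(the standard choice where the procedure is otherwise unspecified).

## The synthetic-data generator

`sim_config()` defines the study conditions; `simulate_profiles()`,
`simulate_counts()` and `simulate_bulk()` realise them. Defaults: 2,000
genes, 12 cell types, 2 clusters per type (one per synthetic tissue),
300 cells per cluster; log-normal baseline gene means (meanlog
log 20, sdlog 1) with 10% per-type jitter; library sizes log-normal
(median 5,000 UMI, sdlog 0.35); gamma-Poisson counts with dispersion
0.4; 2% mitochondrial and 5% ribosomal genes with raised baselines so
cells carry realistic flagged-count fractions; 5% doublets (score 0.9
vs 0.05 baseline — planted, not estimated) and 5% high-mitochondrial
QC outliers; bulk noise multiplicative log-normal with sd 0.1. The
planted category counts default to the proportions reported for
whole-body atlases: 10% enriched, 14% group enriched, 54% enhanced,
6% not detected, remainder low specificity. These sizes keep a full
end-to-end run under ten seconds while leaving every category
populated enough for rate estimates.

Planting recipes (all scale-invariant, so they survive CPM/TMM):

* **enriched** — one target type (cycling over all types so each has
  markers) multiplied by `fold_factor` (default 8, i.e. twice the
  classifier ratio, leaving headroom for sampling noise);
* **group enriched** — a group of 2–4 types multiplied by
  `fold_factor` while the remaining types are divided by it. The
  suppression is deliberate: with only 12 cell types, a plain
  fold-8 group contrast produces tau values *below* what any
  enhanced gene can attain (an enhanced gene's tau is bounded below
  by 1 − 1/fold by construction), which would invert the qualitative
  tau ordering that real atlases show. Strongly bimodal profiles are
  also what real group-enriched genes (median tau ≈ 0.9, close to
  enriched) look like;
* **enhanced** — the non-target types follow a graded ramp
  (1.4×..0.6× the gene baseline, mean 1, 5% jitter) and the target is
  set to 1.1 × (fold_factor/2) × mean(rest). The ramp guarantees the
  profile lands in the *enhanced* region of a classifier whose ratio
  is fold_factor/2: the target clears the mean-of-others bound with
  10% margin but stays below the ratio times the second-largest
  value, and no prefix group qualifies. A naive "one type raised
  above the mean" recipe fails here — on a flat background such a
  spike is captured by the enriched or group rule instead;
* **not detected** — the whole row is scaled by 1e−4, placing
  expected nTPM well below 1 everywhere.

Doublets are extra cells whose expected profile averages two distinct
parent types, hosted inside a real cluster of the first parent. QC
outliers get a tenfold boost of mitochondrial relative expression
(renormalised), i.e. roughly 30–50% mitochondrial counts against a
3–9% baseline.

The generator does **not** emulate batch effects, ambient RNA
contamination, cell-cycle structure, donor variation, or any specific
accession's gene count. Passing tests on these data therefore
demonstrate the correctness of the computations and the
recoverability of planted signal under idealised droplet-like noise —
not robustness to the technical artefacts of real atlas integration.

A note on deconvolution difficulty: because planted enriched markers
retain a full baseline in the 11 other types (an 8:1 contrast), a
bulk mixture's background contributes substantially to every marker,
and with ~210 signature genes the attainable mean L1 error of
recovered proportions at 10% multiplicative bulk noise is about 0.05
even for an oracle-weighted estimator; real atlas signatures, whose
markers are closer to exclusive, are considerably easier.

## Numerical and design choices

* Detection boundary is closed: a gene at exactly 1 nTPM everywhere
  is detected (`low_specificity`), below 1 it is `not_detected`.
* Classifier ties at the maximum fall to the group rule; elevated
  type lists are returned sorted by id; dendrogram leaves are ordered
  by id before clustering.
* All simulator randomness flows through one seed in the
  configuration; internally each `simulate_*` call uses a fixed
  offset of that seed and restores the caller's RNG state, so runs
  are reproducible without global side effects.
* `dwls_solve` errors on rank-deficient signatures (naming the
  collinear types via QR pivoting) rather than returning an
  unidentifiable mixture.
* Pipeline outputs are byte-identical across reruns with identical
  inputs and seed; the run manifest deliberately omits timestamps.

## Problem sizes used by the test suite

Unit tests run on compact simulations (300 genes, 6 cell types, 50
cells per cluster); the end-to-end recovery and invariant checks use
the full default configuration (2,000 genes, 12 types, 7,200 single
cells plus doublets), 20 Dirichlet bulk mixtures for deconvolution,
and n = 20,000 for polyserial recovery. These sizes were chosen so
that the complete suite exercises every stage at meaningful scale in
well under a minute of compute per heavy test.

## Known limitations

* The enrichment ratio, group-size cap and detection limit are
  parameters with atlas-convention defaults; published resources do
  not always print their exact values, so cross-atlas comparisons
  should confirm the settings.
* TMM-within-tissue vs TMM-across-all-clusters is unresolved in the
  literature; results differ slightly between the two.
* Tau on raw vs log-transformed nTPM is a genuine fork; both are
  provided.
* DWLS assumes the bulk profile is a nonnegative combination of the
  signature profiles on a common per-million scale; strong platform
  effects between the single-cell reference and bulk data violate
  this and are out of scope here.
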