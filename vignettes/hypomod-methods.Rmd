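---
title: "Methods: models, parameters and design choices in hypomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in hypomod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hypomod)
```

`hypomod` is a tested re-implementation of a single-cell analysis chain that
links hypothalamic cell types to an intracerebroventricular growth-factor
treatment: quality control and clustering of UMI count matrices, iterative
reference label projection, pseudobulk negative-binomial differential
expression with a repeated-downsampling control, signed co-expression module
discovery with mixed-effects module–treatment association, principal-curve
spatial ("pseudoventricle") scoring, and enrichment statistics. This
vignette is the package's own account of the underlying models, the
parameters that matter, and the places where the design was genuinely open.

## The synthetic-data model

Every stage is tested against data from `simulate_dataset()`, whose
generative model deliberately matches the assumptions of the downstream
statistics.

Counts are negative binomial with mean `mu` and variance `mu + alpha *
mu^2`; the per-gene dispersion `alpha` is drawn from a gamma prior (shape 2,
rate 20, so a typical `alpha` of ~0.1). This is the same mean–dispersion
parameterization the DE engine fits, which is what makes parameter-recovery
tests meaningful. Per-cell library sizes are log-normal with a median of
~1800 UMIs — the depth regime of droplet experiments on fragile hypothalamic
tissue — and per-cell gene means are renormalized to the library size, so
the generator reproduces the *compositional* character of UMI data: when one
program rises, everything else falls slightly. Several design decisions
below exist because of that property.

The structured signal consists of:

- **Cell types with markers.** Marker genes are multiplicatively enriched
  (`marker_log2fc`, default 2) in their type. Marker baselines are drawn
  from a moderately expressed stratum (log-normal meanlog 1, sdlog 0.5)
  rather than the global baseline: canonical markers are robustly detected
  genes, and a marker whose baseline lands in the sparse tail would be
  uninformative no matter its fold enrichment.
- **Planted DE.** A configurable fraction of background genes receives a
  treated-vs-control log2 fold change in the affected cell types.
- **Modules.** Each module has a per-cell latent Gaussian factor
  `f = b_sample + effect * treated + N(0, 1)`; member genes add
  `loading * f` to their log2 mean. The per-sample intercept `b_sample`
  (sd 0.05) models replicate-level biological variation in tightly
  controlled inbred cohorts; the loading default of 1 (and 1.25 in the
  recovery fixtures) corresponds to strongly co-regulated programs with
  typical 2–4-fold swings, the regime of reactive-glia responses. Weaker
  loadings produce pairwise correlations (~0.25 at these depths) that no
  topological-overlap argument can separate from noise — a real limitation
  of module discovery at this sparsity, not of the implementation.
- **A spatial gradient.** One cell type may carry a latent position
  `t ~ U(0, 1)`; zone-marker genes add smooth log2 profiles of `t`
  (ramps, bumps). This emulates tanycyte zonation along the
  third-ventricle wall.
- **Flagged mito/ribo genes** with configurable expected UMI shares, so the
  QC fraction filters are exercisable.

What the generator does *not* emulate: ambient RNA, doublets, read-level
error, cell-cycle structure, and realistic gene–gene correlation beyond the
planted factors. Passing tests therefore demonstrate that the statistics do
what they claim under their own assumptions — calibrated nulls, recoverable
planted effects — not that any particular biological dataset satisfies
those assumptions.

## QC and clustering

The QC thresholds are the workflow's constants: 400–4000 detected genes per
cell, a combined mitochondrial+ribosomal UMI ceiling of 20% (single-cell) or
5% (single-nucleus), and a minimum of 10 (sc) or 5 (sn) cells per gene.
Two readings of the published filters were open:

- *Combined vs separate mito/ribo ceilings.* The phrasing
  ("mitochondrial and/or ribosomal") is ambiguous; the combined share is the
  default, with separate ceilings available via `max_mito_fraction` /
  `max_ribo_fraction`.
- *Filter order.* Cells are filtered before genes (gene detection counts are
  computed on the retained cells), matching the order in which the filters
  are described; the operation is idempotent either way for these data.

Normalization is `log1p(1e4 * count / total)` — a fully specified,
testable substitute for regression-based variance stabilization; every
downstream statistic consumes only a normalized matrix. Variable genes are
ranked by dispersion (variance/mean) z-scored within equal-occupancy mean
bins; the bin count shrinks for small gene sets so each bin keeps ~20 genes
(a z-score within a bin of planted genes is self-defeating). Covariates
(total UMIs, mito/ribo fraction) are regressed out per gene by OLS, residuals
scaled to unit variance and clipped at ±10. PCA is an exact SVD with the
largest-magnitude loading per component forced positive, so results are
bit-reproducible.

Clustering builds a k-nearest-neighbor graph (k = 20) in PC space, weights
edges by the Jaccard overlap of neighbor sets (pruned below 1/15), and
partitions by Louvain modularity under a fixed seed. The resolution default
is 0.1, the workflow's constant; note igraph's resolution scale is coarser
than the scale used by the reference single-cell toolkit, so type-level
recovery in the tests uses 0.3. Cells with silhouette width below zero are
removed; clusters in which any single sample contributes at least half the
cells (boundary inclusive — the published phrasing does not state
strictness) are flagged.

## Label projection

Anchor-based transfer is replaced by a fully specified projector: variable
genes and PCA are fit on the reference; query cells are normalized, scaled
with the *reference* means and standard deviations, per-cell centered, and
projected onto the reference loadings; the label is the majority among the
k = 30 nearest reference cells and the confidence is the vote fraction (a
multiple of 1/k). Cells are kept above a confidence threshold (0.75 for the
atlas passes, 0.50 for the tanycyte and oligodendrocyte analyses), and
references are applied iteratively, each removing its confidently labeled
cells.

Two implementation details matter in sparse data. First, the per-cell
centering: a population absent from a reference loses transcriptome mass to
its own (invisible) markers, so without centering it projects as a uniformly
depressed profile and inherits whichever reference type sits lower —
with unanimous votes. Second, a distance gate leaves query cells unassigned
when they sit farther from the reference than the reference's own
99th-percentile k-th-neighbor distance. Even so, per-cell noise dominates
cell-level distances at ~2000 UMIs, so out-of-reference cells are *reduced*
to ambiguous votes rather than eliminated; reference order genuinely
matters, and `iterative_projection` surfaces per-reference assignment
counts rather than hiding the sensitivity.

## The DE engine

Pseudobulk DE is a deliberate re-implementation of the standard
negative-binomial machinery rather than a wrapper: median-of-ratios size
factors (rescaled to geometric mean 1), per-gene method-of-moments
dispersion pooled within groups with a floor of 1e-8, an NB GLM with log
link fit by IRLS with `log(size factor)` offsets, a Wald test on the
treated-vs-control coefficient against a normal reference, and BH-FDR over
tested genes. The workflow's own contributions — pseudobulk aggregation and
the repeated-downsampling DEG distribution — need an engine whose
calibration is testable end to end; the suite verifies a type-I fraction in
[0.03, 0.08] at nominal 0.05 on 3-vs-3 null simulations and recovery of a
planted log2FC of 2 within ±0.3, and cross-checks coefficients and standard
errors against an independent GLM fit gene by gene. No dispersion shrinkage
is applied; at 6-vs-6 pseudobulk depth the method-of-moments estimate is
sufficient for calibration, and shrinkage would add an untestable knob.

Downsampling draws ten cells per cluster per sample (without replacement;
samples with fewer cells are excluded, clusters left with fewer than two
samples per arm are skipped with a warning), aggregates, tests, and counts
genes at FDR < 0.1, a hundred times per cluster. Gene-level correction
within an iteration is BH (the thresholds quoted with results are FDRs);
the cross-cluster abundance test uses Bonferroni, and both corrections are
reported rather than conflated.

## Module discovery

The network is signed: `a_ij = ((1 + cor_ij)/2)^power`. The soft power is
the lowest candidate in 1..30 whose scale-free fit reaches R² ≥ 0.8, where
the fit regresses `log10 p(k)` on `log10 k` over 10 equal-width connectivity
bins and only negative slopes qualify. Three admissibility constraints
implement the "discard over-connected powers" rule, whose published phrasing
is ambiguous: candidates are discarded when their mean connectivity reaches
the 95th percentile of the candidates' mean connectivities, when it exceeds
10% of the gene count (a network where the typical gene neighbors a tenth of
the genome is too dense to carve — without this, data with a dominant
treatment program select power 3–4 and the cut returns one giant module),
or when it falls below 1 (the network fragments and the topological overlap
denominator degenerates). If no admissible power reaches the target, the
best-fit admissible power is used with a warning.

Topological overlap is the standard
`TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with the
shared-neighbor sum excluding both endpoints; `1 − TOM` is the clustering
distance (average linkage below 3000 genes, complete above).

The published dynamic hybrid tree cut has many unstated internals, so the
cut here is a deterministic procedure that preserves the exposed knobs
(deepSplit granularity, minimum 15 genes, no post-hoc reassignment between
modules):

1. a static cut at the `q`-quantile of the full tree's merge heights
   (deepSplit 2 → q = 0.92, deepSplit 4 → q = 0.99) forces the highest
   joins apart;
2. branches are recursively re-cut while heterogeneous — the root join
   clears a height gap of `(1 − q)` times the spread of the dissimilarity
   (gaps must be scale-relative: the TOM scale compresses as the power
   grows), or the mean internal dissimilarity exceeds the cohesion bound
   0.97;
3. stable branches are trimmed: average linkage chains weakly attached,
   low-connectivity genes onto real modules below the unrelated plateau, and
   a jump of more than 0.1 × the dissimilarity spread in the sorted
   member-attachment profile detaches the stragglers for re-clustering;
4. a branch becomes a module only with ≥ 15 genes and mean internal
   dissimilarity ≤ 0.97 — unrelated genes sit near 1 on the TOM
   dissimilarity scale, so noise branches fail this bound and become grey.

Eigengenes are unit-norm first-PC cell embeddings of the standardized
member submatrix, sign-oriented against the module mean. Merging is
iterative: while any eigengene pair has dissimilarity `1 − cor ≤ 0.2`
(Pearson ≥ 0.8 — the boundary is exact and tested), the closest pair is
fused and eigengenes recomputed. kME is the gene–eigengene Pearson
correlation.

Module–treatment association is a Gaussian mixed model on per-cell
eigengene values — treatment (and batch, when more than one level is
present) fixed, a random intercept per sample — fit by REML via `lme4`,
with a Wald normal p-value and BH-FDR across modules. Per-cell observations
(rather than per-sample means) follow from the eigengene being a cell
embedding; the random intercept carries the animal-level dependence. A
normal reference rather than a degrees-of-freedom approximation is adequate
here because the calibration target is empirical (permutation-uniform
p-values under the study conditions, verified in the suite) and the
per-sample variance share is small; with few samples and large
between-sample variance the Wald reference would be anticonservative, which
is a documented limitation. The reporting rule is FDR < 0.05 *and*
|beta| > 0.005 on the unit-norm eigengene scale — at thousands of cells the
beta floor is what keeps compositional spillover from the responsive program
(which shifts every null eigengene slightly) out of the reported set.

## Pseudoventricle scoring

The principal curve is the Hastie–Stuetzle iteration: initialize at the
first principal component, then alternate projecting points onto the
current polyline (lambda = arc length of the foot) with smoothing each
coordinate against lambda by local linear regression (loess), until the
total squared projection distance changes by less than 0.1% or 50
iterations. The span default of 0.3 suits embeddings whose noise is small
against the trajectory (the tested regime: sigma at 5% of the extent);
noisy embeddings need a stiffer curve (the workflow script uses 0.75) or the
curve starts tracking off-axis variation — a known failure mode of
principal curves, surfaced in the convergence diagnostics rather than
hidden.

Lambda is oriented so the ventral anchor (a ventral-zone marker score)
sits at 0, and linearly rescaled to [0, 30]: the published analysis bins
"with a width of 1" on an unstated scale, and ~30 width-1 bins match the
figure resolution; the bin count is a parameter. Per bin, the treatment
effect on the per-cell scaled module expression (mean of z-scored member
genes) is tested with the same random-intercept mixed model, falling back
to a two-sample t-test when an arm retains a single sample (recorded per
bin); bins with fewer than 3 cells per group are reported untested and
excluded from the Bonferroni denominator. A module is flagged when at
least 5 consecutive tested bins are significant after adjustment; untested
bins break runs.

## Enrichment statistics

Over-representation is a plain upper-tail hypergeometric test with the
workflow's filters applied before correction: term size within [10, 300] in
the background, overlap ≥ 3. Adjustment is Bonferroni. The hierarchical GO
filtering and ordered-query machinery of the original web service are not
reproduced; ordered queries are approximated by nested top-k prefixes where
needed. The direction z-score is `(n_up − n_down)/sqrt(n_overlap)`, with
overlap genes in neither direction set counting only in the denominator.

Preranked GSEA uses the weighted running sum (hit increments ∝ |stat|,
uniform miss decrements), a gene-label permutation null of matched set
size (appropriate for preranked input; sample permutation is impossible
there), `NES = ES / mean(|null ES| of the same sign)`, and the add-one
two-sided empirical p `(1 + #(|null| ≥ |ES|)) / (n_perm + 1)`.

The RRHO map evaluates, for every threshold pair on a shared step grid, the
upper-tail hypergeometric p of the overlap of the two top lists — the same
kernel as the enrichment test, verified identical to 1e-12 — reported as
−log10 p with an optional Benjamini–Yekutieli grid. The one-sided
over-enrichment map is implemented; signed four-quadrant maps are out of
scope. Reactivity genesets follow the published construction: per condition,
genes with log2FC > 2 (FDR < 0.05 where applicable), day-1 genes shared
between the two injury models moved to a PAN set, and any gene left in two
condition sets removed from all, so condition sets are pairwise disjoint.

## Problem sizes, tolerances and degenerate inputs

The test suite and the analysis scripts run at desk scale by design:
simulations of 150–1200 genes and 1000–4000 cells, 12 samples (6 per arm,
the larger cohort design), 100 downsampling iterations, 20 seeded
replicates for the end-to-end module-chain recovery check, and 200
replicates for the mixed-model calibration. Closed-form quantities are
asserted to 1e-10–1e-12 against brute-force oracles; Monte-Carlo quantities
use bands derived from their sampling distributions. Degenerate inputs
fail loudly: zero-total cells, empty barcode files, dimension mismatches,
confounded designs, all-cells-removed QC, single-type references and
disjoint rank universes are all errors with named causes, and zero-variance
genes are handled explicitly (correlation 0, kME 0, inert in module
scores) with warnings.

## Known limitations

- The cohesion bound (0.97) that separates modules from noise branches is
  an absolute constant on the TOM-dissimilarity scale; very weak modules
  (pairwise correlation below ~0.3 at these depths) are not recoverable,
  and the bound was chosen for, and validated on, count data of this
  sparsity.
- Vote-fraction confidence cannot fully exclude out-of-reference
  populations (see the projection section); ordering references from most
  to least comprehensive is the practical mitigation.
- The NB engine does not shrink dispersions or fold changes; with fewer
  than 3 samples per arm its calibration degrades.
- The principal curve assumes an open, roughly 1-D trajectory; closed or
  branching topologies are out of scope.
- Abundance testing assumes per-animal counts are comparable (no
  compositional normalization across types).
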