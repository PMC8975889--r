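---
title: "Methods: arteriovenous identity analysis in emvec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arteriovenous identity analysis in emvec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emvec)
```

emvec analyzes arterial–venous identity in embryonic vascular endothelial
cell (VEC) single-cell RNA-seq data. This vignette documents the models and
procedures the package implements, the parameters that matter, the synthetic
data the test suite relies on, and the numerical choices made where the
design was genuinely open.

## Expression model and preprocessing

Counts are deduplicated UMI counts per gene per cell. Normalization is
transcripts-per-million followed by a shifted log:

$$\mathrm{norm}_{gc} = \ln\!\left(\frac{\mathrm{TPM}_{gc}}{s} + 1\right),
\qquad \mathrm{TPM}_{gc} = \frac{x_{gc}}{\sum_g x_{gc}} \times 10^6,$$

with $s = 10$ for well-based protocols (per-cell depths of order $10^5$) and
$s = 100$ for droplet protocols (depths of order $10^4$). The divisor keeps
the pseudo-counted scale near the actual transcript count, so one transcript
is not counted several times. We use the natural logarithm throughout; the
field's conventions vary between $\ln$ and $\log_2$ here, but every identity
call the package makes is provably invariant to that choice (see the affine
invariance property below), so the ambiguity only affects raw score values,
not conclusions.

Quality control retains cells with *strictly more than* `min_genes` detected
genes and `min_transcripts` total UMIs. Three presets mirror common
deep-well regimes: `well_default` (2000, 100000), `well_shallow`
(2000, 50000) and `well_minimal` (1000, 10000). The strict inequality is a
deliberate reading of "more than"; cells exactly at a threshold are
rejected.

## Arteriovenous feature score

The score uses 13 arterial markers (*Bmx, Cxcr4, Dll4, Efnb2, Epas1, Gja4,
Gja5, Hey1, Igfbp3, Mecom, Nrp1, Unc5b, Vegfc*) and 3 venous markers
(*Aplnr, Nr2f2, Nrp2*). Three steps, each across all cells:

1. min–max scale each marker's normalized expression to 0–10;
2. per cell, average the scaled arterial values and the scaled venous
   values separately;
3. min–max rescale each of the two averages to 0–10, giving $S_a$ and
   $S_v$.

A cell is *arterial* iff $S_a > \tau$ and $S_v \le \tau$ (default
$\tau = 5$), *venous* by symmetry, *double* if both exceed $\tau$, and
*neither* otherwise. Ties at the threshold are conservative
("neither"). Because min–max scaling removes any per-gene positive affine
transform, the classification is invariant to the normalization's log base
— this is tested as a property. Constant genes scale to all zeros and bias
neither side. Missing marker symbols (e.g. species differences) are dropped
with a warning rather than erroring; each side must retain at least one
gene.

Per-cluster summaries use the sample mean and covariance of $(S_a, S_v)$
and a coverage ellipse $(x-\mu)^\top\Sigma^{-1}(x-\mu) \le q$ with
$q = \chi^2_2(0.5)= -2\ln 0.5 \approx 1.386$ for the default 50% coverage.
Clusters with fewer than 3 cells or singular covariance are flagged
degenerate instead of erroring.

## Cell-cycle phase scores

Phase scoring uses the canonical core sets of 43 G1/S and 54 G2/M genes and
the binned-control module score: genes are ranked by mean expression and cut
into 25 equal-occupancy bins; for each signature gene, 50 control genes are
drawn from its bin (seeded); a cell's score is the mean signature expression
minus the mean control expression. A cell with both scores $\le 0$ is G1;
otherwise the larger score decides (S for G1/S, G2M for G2/M). The exact
control-sampling formula is a package decision — the construction is the
standard module score used across the field — and the seed is exposed so
assignments are reproducible.

## Differential expression

Two-sided two-sample Wilcoxon rank-sum on normalized values, normal
approximation with mid-ranks and tie-corrected variance, no continuity
correction. Genes enter the test only if detected (norm > 0) in at least
`min_pct = 0.25` of either group. P values are Benjamini–Hochberg adjusted
over tested genes; a gene is retained when its *linear* fold change (either
direction) is at least `fc_min = 2` and adjusted p ≤ 0.05. Linear fold
change is computed on de-logged means with $\varepsilon = 10^{-9}$
protection; the log-scale difference of means is reported alongside. The
choice of BH (the adjustment procedure is rarely printed in applied work)
and the linear-scale fold change are documented decisions.

Pattern genes across an arterial developmental continuum are categorized by
stage-wise contrasts at `fc_min = 1.5`: up-regulated mid vs early =
*arterial segregation*; up-regulated late vs mid = *arterial
strengthening*; genes passing both are assigned to segregation (the earlier
event) and flagged, since ordering is by category first. For heatmap
ordering a per-gene plexus-comparison p value can be attached.

Fisher's combination $X = -2\sum_i \ln p_i \sim \chi^2_{2k}$ merges
independent p values; $p = 0$ inputs are clamped to the smallest positive
double with a warning. Smoothing along an ordering is a centered moving
average over 20 adjacent cells, truncated at the ends.

## Supervised cluster refinement

For two molecularly close clusters the package fine-tunes labels in five
seeded steps: (i) a DEG screen between the input clusters defines the gene
space; (ii) hierarchical clustering on $1 -$ Pearson correlation (average
linkage) cut at the root gives the two-way first split; (iii) 10-fold
random-forest feature selection accumulates Gini importance across folds and
keeps genes above the mean importance; (iv) a forest over the feature genes
computes each cell's out-of-bag vote probability for its own label, cells
above 0.6 train a classifier that re-predicts the rest; (v) 100 runs of
10-fold cross validation record each cell's held-out vote probability, and
cells averaging below 0.55 are discarded as ambiguous (a 51%/49% vote is no
basis for an assignment). Forests use 500 trees, $\sqrt{p}$ features per
split and no depth limit — the canonical defaults.

"Internal vote probability" is not a standardized term; we read it as the
out-of-bag vote fraction in step (iv) and the held-out CV vote fraction in
step (v), and aggregate across runs by the arithmetic mean. The feature-set
cutoff (importance above the mean) and the average linkage are likewise
exposed decisions. If the DEG screen finds fewer than two genes the
procedure aborts with a warning and returns the input labels — clusters
with identical programs cannot be refined, only detected as such. All-cell
degenerate inputs (constant profiles) are caught before any forest is
grown.

## Principal-curve pseudo-order

Cells are embedded by *modified* PCA scores: after standard PCA on centered
normalized expression, each of the top two components is recomputed from
only its 60 largest-|loading| genes (other loadings zeroed). This damps
technical, low-loading genes. Whether the "top genes" should be weighted by
their loadings or summed with signs only is ambiguous in the field; the
loading-weighted form is the default and the signed sum is available via
`weighted = FALSE`. Gene selection is per component, not global. With
`n_top` at or above the gene count the scores equal standard PCA exactly
(up to component sign), which is tested.

The principal curve is fit by the classical projection/smoothing iteration:
initialize on the first principal axis, project points onto the current
polyline (arc length = $\lambda$), smooth each coordinate against $\lambda$
with a cubic smoothing spline, repeat until the mean squared projection
distance changes by less than `tol = 1e-4` (relative) or 50 iterations.
The smoother uses a *fixed* 5 degrees of freedom rather than GCV: with
data-driven smoothness the self-consistency iteration can collapse onto a
curve that interpolates the points (projection error near zero, objective
oscillating), which defeats the purpose of a one-dimensional summary. df=5
matches long-standing principal-curve practice; GCV remains available with
`df = NULL`. Under the fixed df the objective is non-increasing, which is
tested as a property.

Orientation is extrinsic: the curve has no intrinsic direction, so
`orient_pseudoorder()` flips $\lambda$ when an anchor population (e.g. the
earliest sampling stage) does not sit at the low end. The operation is
idempotent.

## Ligand–receptor interaction calling

Interactions between a mural-cell (MC) population and a VEC population are
called by deterministic thresholding: for a (ligand, receptor) pair and a
direction, a call requires the ligand's normalized expression to exceed the
threshold in strictly more than 50% of sender cells *and* the receptor's in
strictly more than 50% of receiver cells. Genes absent from a matrix count
as never expressed, since reference ligand–receptor tables exceed any one
dataset's gene space.

The threshold is the upper quartile of expression "of all genes in the
analyzed data". Which population of values that quartile is taken over is
not recoverable from typical method descriptions; the default here is the
75th percentile of per-gene mean normalized expression pooled over the
supplied datasets (the per-entry alternative is dominated by zeros in
sparse data), with `"entry"` and `"nonzero_entry"` conventions selectable
and any fixed value (such as a previously published 1.34) acceptable
directly. Quantiles use linear interpolation between order statistics
(R type 7). Raising the threshold or the fraction cutoff can only remove
calls — monotonicity is tested.

## Cross-species conservation

Symbols are mapped through a two-column homolog table; one-to-many
relations either keep all targets (default, flagged ambiguous) or the first.
A conserved cluster marker must be a retained DEG in species A whose
homolog is a retained DEG *in the same direction* in species B; records are
ranked by Fisher's combined p of the two raw p values. Conserved arterial
genes must be up-regulated in all four arterial-vs-venous comparisons (two
arterial populations × two species); ranking combines the four raw p
values ($\chi^2_8$). With "any homolog" semantics a gene can qualify
through multiple partners; the best-supported record per reference gene is
kept. The conserved-arterial output is by construction a subset of each
up-list after mapping — tested as exact containment.

Label transfer between species uses k-nearest-neighbour classification in a
shared embedding supplied by the caller (batch/species integration itself
is out of scope; any integrated space works, and tests use PCA of
concatenated synthetic data). k defaults to 15 — the neighbourhood size is
rarely printed in applied work and is exposed as a parameter. Ties are
broken toward the label with the smallest summed distance, making the
transfer deterministic and permutation-invariant.

## Synthetic data: what it emulates, and what it does not

All validation runs on synthetic data with known ground truth. Counts are
negative binomial (gamma–Poisson; `rnbinom` with size $1/\phi$,
$\phi = 0.2$ by default — typical biological overdispersion for deep UMI
data). Per-gene baseline abundances are log-normal (sdlog 1.5); library
sizes are log-normal around `library_size_mean` $= 10^5$ (sdlog 0.3), so
TPM normalization is exercised non-trivially. Cluster programs are log2
fold-changes applied multiplicatively; expected counts are renormalized per
cell so the planted library size is respected.

Named marker/program genes are given a controlled low off-state baseline
(2 expected UMIs by default): arteriovenous markers in real tissue are
near-silent outside their compartment, and the default eight-cluster spec
additionally mirrors the mutual repression of the two programs — arterial
clusters carry the arterial set at $+2$ log2FC and the venous set at $-2$,
the venous cluster the reverse, and immature clusters sit at $-1$ on all
markers. Without this structure the min–max score of a 3-gene venous
signature is dominated by mid-scale baseline noise, which no real VEC
dataset shows. Effect sizes are otherwise chosen for testability, not
biological fidelity: no published effect sizes exist for these cluster
programs.

Latent time is uniform per cell within designated clusters and acts through
per-gene logistic ramps ($\pm$ amplitude, random midpoints in 0.25–0.75,
width 0.1) — simple, monotone and recoverable. Cell-cycle structure boosts
the planted G1/S or G2/M set in cells assigned to those phases. Batches
apply mild per-gene log-normal effects. Deliberate label flips are uniform
at `flip_fraction`. Every generator is bit-reproducible given the spec and
seed, and the ground truth (true labels, latent times, identities, phases,
planted genes and pairs) is returned alongside — it is never consumed by
pipeline stages.

What the generator does *not* emulate: raw reads, UMI collisions, barcode
errors, doublets, ambient RNA, realistic gene–gene correlation structure,
or realistic marker co-regulation beyond the planted programs. Passing
tests therefore demonstrate the correctness and calibration of the
procedures under their stated assumptions, not their performance on any
real embryo dataset.

## Problem sizes used in validation

The shipped checks use 8 × 100 cells × 2000 genes for identity recovery,
1000 genes × 2 × 100 cells for null calibration, 200 cells × 300 genes
with 10% flips for refinement (full 100 × 10-fold CV), 200 cells × 500
genes × 50 modulated genes for pseudo-ordering, 2000-gene dataset pairs
with 10 planted + 10 decoy ligand–receptor pairs, and two 600-cell
three-cluster "species" with 50 planted conserved genes. These sizes keep
every planted effect comfortably recoverable while exercising all code
paths.

## Known limitations

- The refinement procedure is two-cluster only, as in the analysis it
  reproduces; multi-way refinement would need a different vote rule.
- The principal curve is fit in two dimensions (the top two modified PCs);
  branching topologies are out of scope.
- The interaction rule is a deterministic threshold; no permutation null or
  statistical score is attached.
- The DEG module covers the rank-sum path used for well-based data; the
  logistic-regression variant used for droplet confirmatory analyses is not
  implemented.
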