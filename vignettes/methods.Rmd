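---
title: "Methods: meta-clustering shared tumour cell states from multi-sample snRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-clustering shared tumour cell states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stateatlas` discovers transcriptional cell states shared across samples in
multi-sample single-nucleus RNA-seq, typically post-chemotherapy residual
tumours grown as patient-derived xenografts (PDX).  This vignette is the
package's own account of the method: the models and rules each stage
implements, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design decisions taken where
the method description left room.  No empirical claim is made here that the
test suite does not itself compute.

## Why meta-clustering

Pooling cells of several patients and clustering once mostly recovers
patients, not biology: per-sample batch structure dominates any joint
embedding.  The route taken here clusters **each sample separately** (and
each cell-cycle phase separately, to keep proliferation from masquerading as
a state), summarises each within-sample cluster by its mean expression
profile, and then clusters the *clusters* across samples.  States that recur
across samples merge into **meta clusters (MCs)**; batch effects, which are
shared by all clusters of a sample, cancel in the cross-sample comparison to
first order.

## Stage by stage

### Species assignment (barnyard input)

PDX nuclei are a human/mouse mixture aligned to a joint reference.  For each
sample, the human threshold `t_h` is the 10th percentile
(linear-interpolation, type-7 quantile — the default of mainstream numeric
stacks) of human UMI counts over nuclei with more human than mouse UMIs;
`t_m` symmetrically.  A nucleus is kept as human iff `human > t_h`,
`mouse < t_m` and `human > mouse`, with strict inequalities (literal reading
of "exceeding"/"below").  If one side is empty the corresponding threshold
degrades to 0 (human) or +Inf (mouse) with a warning, so the rule never
aborts.  Note a structural property: on perfectly clean data the rule
excludes about the bottom decile of true human nuclei — it is designed to
shave low-UMI debris, which clean synthetic data does not have.

### Quality control

Read- and UMI-count gates are the outermost local minima of a Gaussian
kernel density (Silverman bandwidth, 512-point grid) fitted on
`log10(x + 1)`, below and above the global mode; a side with no local
minimum passes through to the data extreme, and gate comparisons are
inclusive so pass-through keeps everything.  Cells must additionally have a
mitochondrial UMI fraction strictly below `mito_max = 0.05`
(`MT-`-prefixed symbols by default, configurable regex).  Genes detected in
fewer than 5 retained cells are dropped.  Doublets: given calls from two
external tools and an expected count `n_doublet`, the removal set is the
intersection of the calls; if the intersection exceeds `n_doublet`, only its
`n_doublet` highest-scoring cells (primary caller's score, ties broken by
barcode) are removed.  Ranking *within the intersection* (not over all
cells) is a deliberate choice: only jointly-called cells are credible
doublets.

### Normalisation and phase assignment

Counts are normalised to analytic negative-binomial Pearson residuals
`(x − μ)/sqrt(μ + μ²/θ)` with `μ = gene abundance × cell size factor` and
`θ = 100`, clipped at `sqrt(n_cells)`; four per-cell covariates
(mitochondrial fraction, RPL fraction, genes detected, total UMIs) are then
regressed out of every gene by least squares in one matrix operation.  This
is the closest language-neutral equivalent of regularised-NB
variance-stabilising transforms; exact parity with any particular tool is a
non-goal.  The 3,000 most variable genes by residual variance are flagged as
HVGs.  A `log1p(10⁴·x/total)` layer is kept for profile averaging and
differential expression.

Cell-cycle phase uses the standard two-programme scoring: each score is the
mean log-expression of the programme's genes minus that of
expression-matched controls (25 bins, 50 controls per gene — the
conventional defaults); a cell is S/G2M iff either score is positive, G1
otherwise.  S and G2M are deliberately *not* separated: downstream
clustering is stratified G1 vs S/G2M only.

### Within-sample clustering

PCA is run on the HVG residuals; the dimensionality is the first component
whose explained-variance percentage drops by less than 0.1 percentage
points to the next (falling back to the maximum examined, default 100, with
a warning).  A k-nearest-neighbour graph (Euclidean in PC space, `k = 20`,
self included) gives shared-nearest-neighbour weights as Jaccard overlaps of
neighbour lists, min-max scaled to [0, 1].  Louvain modularity communities
are computed at every resolution in the grid {0.01…0.1 by 0.01} ∪ {0.2…1 by
0.05}; among resolutions yielding 3–8 clusters the winner minimises a
**medoid-based Davies–Bouldin index** on distance `1 − scaled similarity`
(ties → lowest resolution; no feasible resolution → nearest cluster count,
with a warning).  Two choices deserve note:

* the similarity matrix is *inverted* (`1 − s`) before use as a distance —
  feeding a similarity directly into Davies–Bouldin would invert the
  index's meaning;
* medoids replace centroids so the index is exactly computable from a
  distance matrix; medoid ties break to the first index, and coincident
  medoids of distinct clusters make the pairwise term +Inf (worst).

The Davies–Bouldin optimum sometimes refines one true state into two
subclusters at small stratum sizes; this is accepted, because meta
clustering merges same-state subclusters.

### Meta clustering

HVGs variable in ≥ 3 samples form the shared gene set.  Every within-sample
cluster (per phase) with ≥ 3 cells is summarised by its mean log-normalised
expression over those genes; pairwise Spearman correlations (average-rank
ties; a constant profile correlates 0, with a warning) feed average-linkage
hierarchical clustering on `1 − ρ`, cut at height 0.25 so clusters merge
while ρ ≥ 0.75.  The full similarity matrix is used — including same-sample
pairs — because the hierarchical cut needs a complete distance and
same-sample subclusters may legitimately merge.  MCs are named `MC0…` by
decreasing total cell count.  The cutoff is interpreted on the similarity
scale (height `1 − 0.75`); a config toggle exists for the alternative
reading.

### Marker aggregation

Within each sample, the sample's cells of one MC form a subcluster; each
gene is tested one-vs-rest with a two-sided Wilcoxon rank-sum on
log-normalised expression (normal approximation with tie and continuity
correction — verified against `stats::wilcox.test` to 1e-10), with
Seurat-convention fold changes `log2((mean(expm1 x_in)+1)/(mean(expm1
x_out)+1))` and no thresholding at this stage.  Per gene and MC, p-values
are combined across contributing samples with Fisher's method
(`χ²_{2k} = −2 Σ ln p`, upper tail at `2k` df; k varies per gene when a gene
is absent from a sample).  Heat-shock (`HSP`), mitochondrial (`MT-`) and
`RPL` genes are excluded by symbol prefix (configurable — no explicit gene
lists exist).  BH-FDR is computed per MC; markers require FDR < 0.01 and
`log2FC > log2(1.25)` in ≥ 2 samples, are ranked by combined p, and the top
100 feed all downstream signature work.  An MC present in only one sample
gets an empty marker set with a warning (the ≥ 2-sample clause can never
hold).

### Signatures, enrichment, state assignment

* **Overlap coefficient** `|A∩B| / min(|A|,|B|)` for gene-set similarity.
* **Hypergeometric enrichment**: `P(X ≥ k)` for `k` of `n` markers hitting a
  set of size `K` in a universe of `N` (the filtered merged gene universe),
  sets restricted to 3–500 genes, BH-FDR over tested sets, significance
  requiring both overlap ≥ 3 and FDR < 0.05.
* **Per-cell gene-set score**: genes are ranked within each cell by
  decreasing expression; the score is the maximum positive plus maximum
  negative deviation of the set-vs-rest Kolmogorov–Smirnov walk (the
  max-deviation-difference convention).  The single-largest-excursion
  variant is right-skewed under the null; the difference form is symmetric
  around zero under exchangeability (its null median over cells is ~0, a
  property the tests check), bounded in [−1, 1], and monotone under raising
  set-gene expression.  GSVA internals are not re-derived; this scorer has
  the same directional semantics and is used consistently everywhere.  A
  mean-z alternative is provided.
* **State assignment**: each cell goes to the MC with the highest positive
  score, ties to the first MC in column order, `"unassigned"` iff all
  scores ≤ 0.
* **Pseudo-bulk recipes** (per MC × sample mean log-normalised expression):
  plain mean (residual-tumour-, prognostic-, CIN70-style sets), minus the
  sum of row-z-scored values (recombination proficiency: high repair-gene
  expression ⇒ low score; all four genes required), and first principal
  component with the sign anchored to correlate positively with the set
  mean (the p53-signature recipe; the sign convention is otherwise
  arbitrary).
* **Cosine co-expression** of two per-cell scores,
  `r = x·y / sqrt(x² + y²)`, implemented literally as printed (it is
  cosine-like but unnormalised per cell), then min-max scaled to [0, 1];
  `x = y = 0` gives raw 0 with a warning.

### Regulon specificity

Activity of a regulon (TF + targets) in a cell is the area under the
recovery curve of regulon genes within the top 5% of that cell's expression
ranks (ties broken randomly under a fixed seed), normalised by the maximal
achievable area — an AUCell-style statistic in [0, 1], invariant to monotone
transforms of expression.  Regulon inference itself (SCENIC etc.) is out of
scope; activity matrices can also be supplied directly.  A TF is specific to
an MC iff per-sample Wilcoxon target-vs-rest tests pass (p < 0.05 *and* mean
difference > 0.1) in ≥ 1 sample, the regulon is detected in ≥ 2 samples, the
pooled median activity is higher in the target MC, and the TF is a candidate
for *exactly one* MC.  The companion t-test on overlap coefficients between
a regulon and each MC's top-100 markers is implemented literally as
described even though testing a handful of bounded OC values with a t-test
is statistically unusual; its p is NA when fewer than 2 comparison values
exist or they are degenerate.

### Clinical validation

Patients are split at the median signature score (`low` iff score ≤ the 50%
quantile).  Survival association censors follow-up at 10 years and fits a
Cox proportional-hazards model of high vs low (delegated to the standard
`survival` routines), reporting HR, 95% CI and the Wald p; a continuous-score
mode is provided because hazard ratios are sometimes reported per unit of
score rather than per group.  Response association is a one-sided Wilcoxon
rank-sum in the stated direction (residual disease scoring higher, by
default), exact when both arms have < 50 patients and no ties, otherwise the
tie-corrected normal approximation.  Arm-level p-values combine by the
sample-size-weighted sum-of-z, `Z = Σ w z / sqrt(Σ w²)`, which reduces
exactly to unweighted Stouffer under equal weights.

### Variant and copy-number rules

A variant is retained iff it is splice-site or exonic with a known
functional consequence (configurable allow-list: frameshift, stop
gain/loss, missense, in-frame indel, start loss — synonymous SNVs always
excluded), has read depth ≥ 5, HIGH or MODERATE predicted impact, and is
either absent from the population database, rarer than 0.1%, or carries any
ClinVar annotation (any non-empty annotation passes; the accepted classes
are configurable because none are enumerated).  Copy-number segment log2
ratios are standardised by the within-sample SD (denominator n − 1; zero SD
⇒ all neutral, warning) and called gain/loss beyond ±3.

## The synthetic world

The generator's job is to produce data in which every rule above has a
planted right answer.  Counts are negative binomial — the standard
snRNA-seq noise model; the source analysis used real data and states no
generative model — with mean `L_c · w_gc / Σ_g w_gc`, where the weight
multiplies:

* a log-normal gene baseline (`sdlog = 0.5`);
* a per-sample per-gene log-normal batch factor (`sd = 0.2`), inducing the
  per-patient separation that motivates meta-clustering;
* the state programme: each planted state over-expresses its disjoint
  marker set by `2^log2_effect` (default 4 states × 150 markers at effect
  2 — marker-set sizes in the hundreds mirror the scale of real MC marker
  lists);
* a 2^2 cell-cycle programme over the standard S (43) and G2M (54) gene
  lists for the 30% of cells in S/G2M;
* a per-cell log-normal mitochondrial multiplier (target fraction 2.5%,
  log-sd 0.4 — a few percent of cells exceed the 5% QC bar).

Library sizes are log-normal (mean 4,000, log-sd 0.3); 2% of cells are
planted low-quality with libraries shrunk ×0.03 or inflated ×8.  The
gene universe (default 2,000 genes) reserves 20 `MT-`, 40 `RPL`, 20 `HSP`
genes so the exclusion and covariate rules have substrate.  Two calibration
facts shaped the defaults, worked out before acceptance runs: profiles are
compared by Spearman over all shared HVGs, so the baseline's rank agreement
sets a floor under *every* pairwise ρ — a moderate baseline spread
(`sdlog 0.5`) and a three-digit marker programme keep cross-state ρ well
below the 0.75 cutoff while same-state cross-sample ρ stays above it.

Barnyard mixtures draw singlets with 2% cross-species contamination (purity
≈ 98%, comfortably above the 95% contract) and append
`round(rate · n)` doublets that *sum* one human and one mouse singlet's
draws; a synthetic doublet score (cross-species balance) stands in for
external callers so the consensus rule is testable.  Clinical cohorts are
Gaussian expression matrices where the response effect shifts signature
genes in residual-disease patients by `effect` SD units, and the survival
effect multiplies the exponential hazard of the above-median signature
group by `exp(effect)` (so `effect = log 2` plants HR 2; `effect = 0` is
the null in both modes).

What the generator does **not** emulate — so a green test does not speak to
it: ambient RNA and debris (hence the species-rule caveat above), empty
droplets, batch effects that distort covariance rather than gene means,
doublets *within* a species, S-vs-G2M substructure, overlapping or
hierarchical states, and any real gene identity (the packaged signature GMT
ships synthetic placeholder lists, clearly labelled; only the four
recombination-proficiency genes are real).

## Numerical and testing choices

Determinism: every stochastic routine takes a seed and restores the
caller's RNG state; pipeline reruns with equal seeds are bit-identical, and
stage outputs are cached so deleting one stage file re-executes only it and
its dependants.  Formula implementations are checked against independent
oracles (numerical χ² tail integration, exhaustive hypergeometric
enumeration, brute-force Davies–Bouldin evaluation, textbook BH).  Null
calibrations use fixed-seed Monte Carlo with replicate counts chosen so the
Monte-Carlo noise is small against the margin being tested (e.g. 500
replicates for the 93% CI-coverage bound, whose true value here is ~94%).
Zero p-values are clamped to the smallest positive double before log or
probit transforms, always with a warning.

## Known limitations

* Exact parity with the original R tool-chain (SCTransform, Seurat's SNN,
  CIDER, GSVA, AUCell) is explicitly not attempted; contracts are
  behavioural.
* The Davies–Bouldin resolution search optimises cluster compactness on the
  SNN-derived distance, which can prefer refinements of large states;
  correctness is restored at the meta-cluster level.
* The hierarchical cut at a fixed similarity of 0.75 is an absolute
  threshold: its behaviour depends on the correlation floor set by shared
  baseline expression, which real datasets (and the generator) must keep
  below the cutoff for cross-state pairs.
* Bulk per-gene differential expression via moderated linear models, tumour
  purity regression, and survival-model internals are out of scope; the
  package delegates or omits them.
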