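---
title: "palatrix: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{palatrix: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
behind each stage, the tunable parameters that matter, what the synthetic
generator emulates (and deliberately does not), and the numerical choices
made where the design was genuinely open. Nothing stated here goes beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The analysis problem

A developing tissue is sampled at four embryonic stages. Each cell
contributes a paired measurement: RNA counts over genes and ATAC counts
over accessibility peaks, plus the underlying fragment records. The
questions the pipeline answers are the standard ones for such a design:

1. which cells are usable (joint QC);
2. which peaks act as enhancers of which genes (peak–gene linkage);
3. which transcription factors mark each population in *both* modalities;
4. how the populations flow into terminal lineages over real time
   (optimal-transport trajectories, fate probabilities, pseudotime,
   driver genes);
5. which TFs causally matter, judged by in silico knockout of an inferred
   gene-regulatory network.

## Quality control

Six per-cell metrics are computed: `nCount_RNA`, `nFeature_RNA`,
`percent.mt` (share of counts on contig `"chrM"`), `nCount_ATAC`,
`nucleosome_signal`, and `TSS.enrichment`. The fragment-based metrics are
defined as:

* nucleosome signal = (# fragments with length in [147, 294]) /
  max(1, # fragments with length < 147) — the mono- vs sub-nucleosomal
  ratio;
* TSS enrichment: fragments are aggregated over all annotated TSS into a
  profile; the mean per-base coverage in TSS ± 50 bp is divided by the
  mean coverage in the outermost flanks ([−1000, −901] ∪ [901, 1000] bp),
  with pseudocount 0.1 in the denominator. Aggregating the profile over
  TSS *before* forming the ratio makes the uniform-coverage identity
  (enrichment ≈ 1) hold at realistic depths; a per-TSS ratio would be
  dominated by the pseudocount.

Filtering keeps cells satisfying **all** strict bounds:
200 < nCount_RNA < 100,000; nFeature_RNA < 7,500; percent.mt < 20;
200 < nCount_ATAC < 100,000; nucleosome_signal < 2; TSS.enrichment > 1.
A missing fragments table flags the ATAC metrics as unavailable rather
than silently zero, and filtering is idempotent.

## Normalization and embeddings

RNA normalization is `log1p(count / cell_total × median(cell_totals))` —
deterministic, size-factor invariant, and sufficient for the downstream
statistics (Pearson correlations and Wilcoxon ranks), which is why a
regression-based normalization was not re-implemented. Highly variable
genes are the top 3,000 by standardized dispersion (dispersion z-scored
within 20 mean bins); PCA uses the centered HVG matrix (30 components).

ATAC uses latent semantic indexing: binarize, term frequency =
count/cell total, IDF = log(1 + n_cells/(1 + peak occurrence)), then SVD
of `log1p(TF × IDF × 1e4)`. The log scaling matters: without it the
first component's correlation with sequencing depth drops from |r| ≈ 0.99
to ≈ 0.6 on generated data, because the row normalization inside TF
already removes most depth signal. Component 1 is dropped from the
returned LSI precisely because it tracks depth; all component signs
follow the convention "largest-magnitude loading positive" so repeated
runs are comparable.

Clustering builds a symmetrized kNN graph (k = 20, Euclidean) and runs
Leiden modularity communities; the resolution is an explicit knob (1 by
default, which recovers the five terminal populations of the default
simulation; idealized well-separated blobs need lower values because
modularity splits large kNN communities).

## Peak–gene linkage

For every (gene, peak) pair on the same contig with
|peak midpoint − TSS| ≤ 5×10⁵ bp, the observed statistic is the Pearson
correlation r between normalized expression and peak counts across cells.
The null for each pair is empirical: the 200 peaks nearest to the tested
peak in standardized (GC content, overall accessibility, width) space
(ties broken by peak index) are correlated with the same gene, giving
μ₀ and σ₀; z = (r − μ₀)/σ₀ with a one-sided upper-tail normal p, BH over
all tested pairs, and links kept at r > 0, padj < 0.05. This
matched-background formulation absorbs covariate-driven artefacts
(GC-dependent accessibility, sparsity) without a parametric covariate
model, and it is distribution-free. One-sided testing reflects that
positive regulation is the target; the r > 0 filter is still applied
afterwards as an explicit rule. Constant gene or peak vectors are
reported as skipped rather than propagated as NaN. Correlations are
computed on the normalized layer (a flag away from raw counts) — per-cell
values directly, with no cell aggregation.

## Motifs, deviations and markers

JASPAR PFM text is parsed into probability matrices with
`(count + 0.25·pseudocount)/(colsum + pseudocount)` (pseudocount 1) and
natural-log odds against a uniform background. Scanning thresholds are
defined by a scan p-value (default 1e-4) through the exact distribution
of window scores under the background model (dynamic programming over
scores discretized at 1/1000 log-odds units), which makes thresholds
comparable across motif lengths; both strands are scanned and windows
containing non-ACGT letters never hit.

chromVAR-style deviations compare each cell's counts in a motif's peaks
with the expectation under cell-independent peak weights, z-scored
against 50 background peak sets matched on GC and accessibility deciles.
One replacement map (peak → matched peak) is drawn per background
iteration and shared by all motifs, so identical hit columns receive
identical backgrounds, and deviations are invariant to global depth
scaling.

Markers use one-vs-rest Wilcoxon rank-sum tests (normal approximation
with tie and continuity correction, vectorized; the standalone
`wilcox_rank_sum_test()` switches to the exact tail for small tie-free
samples). The effect size is the natural-log fold change of
pseudocounted mean de-logged expression (for expression layers) or the
difference of means (for deviation scores, which can be negative). A
dual-modality marker TF for a group must be RNA-enriched *and*
motif-deviation-enriched (both padj < 0.05, effect > 0); deviations
rather than peak-set enrichment drive the dual criterion because they
give a per-cell statistic on the same cells as the RNA test (a flag can
switch this). ORA is plain hypergeometric with set sizes restricted to
[5, 500] after intersection with the universe.

## Trajectories

Growth rates start from the proliferation program: the mean normalized
expression of the proliferation set, z-scored, mapped through `exp` —
bounded, positive, and refined by the transport iterations.

Between adjacent stages, cells are coupled by entropic unbalanced optimal
transport in the shared 30-PC RNA space (squared Euclidean cost;
ε = 0.05 × mean cost; source marginal ∝ growth^Δt with a KL penalty
λ = 1, target marginal uniform and hard). The solver works in the log
domain (potentials + log-sum-exp), which is stable for arbitrarily small
ε; convergence is declared when the relative potential update falls below
1e-8, and non-convergence is an error reporting the residual. After each
of three growth iterations the growth rates are re-estimated from each
cell's transported mass and the problem re-solved.

The global transition matrix stacks the row-normalized couplings; cells
of the last stage transition within a symmetric kNN connectivity kernel,
closing the chain. Macrostates approximate GPCCA: the dominant right
eigenvectors of the (closed) last-stage block are extended backward
through the stages via v = (Tv)/λ, and cells are clustered in that space
by seeded k-means (default 6 macrostates). The coarse-grained transition
matrix uses stationary-distribution weights, which concentrate on the
recurrent cells; macrostates whose coarse self-transition reaches 0.8 are
terminal. The threshold is calibrated to this hard-partition
approximation — observed values are ≥ 0.84 for true terminal states and
≈ 0.3 for progenitor states, so the margin is wide; soft-membership
implementations concentrate nearer 1, where a 0.95 cut is customary.
Fate probabilities solve (I − Q)F = R with the terminal macrostates'
cells absorbing; every row sums to 1 and terminal rows are indicators,
and the same quantities are cross-checked against 100,000-walk
Monte-Carlo endpoint frequencies in the tests.

Diffusion pseudotime builds the symmetrized kNN kernel on the RNA PCs,
takes the eigenvectors of the normalized kernel, and measures the
eigenvalue-weighted (λ/(1−λ)) diffusion distance to the root cell over
10 components, rescaled to [0, 1]. Disconnected graphs are an error
naming the components.

Driver genes correlate expression with a lineage's fate probability
(t-approximation p, BH); drivers satisfy ρ > 0.05 and padj < 0.05. For
stage-resolved profiles, cells above the lineage's 75th fate-probability
percentile (per lineage — the natural reading when lineages have
different fate scales) are ordered by pseudotime; driver expression is
smoothed by a centered rolling mean (window 5% of cells, minimum 11),
standardized, and grouped by seeded k-means (k = 3) into start/middle/end
by the tertile of each cluster's mean peak position. A quantile-cut
fallback (`method = "quantile"`) groups drivers by peak-position tertiles
instead; both appear in the literature this design follows and k-means is
the primary. On the default simulation the quantile cut resolves the
three planted phase programs more sharply than k-means, whose clusters
merge the start and middle programs because their plateau-shaped
profiles correlate strongly — worth knowing when the programs of
interest saturate rather than switch off. Stage-resolved motif enrichment uses each stage's linked
peaks as foreground against all peaks linked to any driver of the
lineage.

## In silico perturbation

Candidate regulators are motif-driven: TF → gene iff the TF's motif hits
a peak significantly linked to the gene or the gene's promoter peak
(promoters always eligible; a coaccessibility input with threshold 0.8
is the alternate mode). Edges are fit per cluster by ridge regression of
the target on its candidate TFs over 20 bootstrap bags (penalty by GCV on
a small grid), with the coefficient as the bag mean.

Two numerical choices here deserve emphasis:

* **Edge p-values** use the bag t-statistic with the *spread of bag
  coefficients* as its scale. Bootstrap bags share cells, so the naive
  standard error sd/√n_bags is anti-conservative and lets ~30% of
  permuted-target nulls through p < 0.001; with the sd scale the
  permutation leak is zero while strong dependences remain far below the
  threshold. Edges are kept at p < 0.001 and capped at 2,000 per cluster
  by |coefficient|.
* **kNN imputation** (`knn_smooth`, k = 30) is applied to the expression
  layer the GRN machinery operates on. At the single-cell level,
  within-cluster TF–target correlations of genuinely coupled genes are
  ~0.1 and honest inference finds almost nothing; after imputation they
  reach 0.7–0.85 in the relevant clusters while permuted targets are
  still fully filtered. This mirrors how the cited knockout-simulation
  tool preprocesses its input.

A knockout sets the TF to zero (shift −x per cell) and propagates the
shift three times through the cell's cluster GRN as linear signal flow,
clipping so no shifted value drops below zero; the KO coordinate is held.
The per-cell gene-space shift is projected onto a 2-D embedding by
correlating it with the expression differences to the 200 nearest
embedding neighbours (softmax temperature 0.05) — over the *full* gene
space: the zero coordinates anchor the pattern, and restricting to the
shifted genes alone degenerates the correlation because the shift is
nearly uniform there. The shift field and the developmental flow (the
finite-difference gradient of grid-smoothed pseudotime, 40 × 40 grid)
share geometry; the perturbation score is −Σ⟨shift, flow⟩ over the grid
boxes whose local cell majority belongs to the lineage, so positive
scores mean development is reversed.

Score specificity is judged against degree-matched random pseudo-TFs: a
random gene is assigned the real TF's out-degree with random targets,
its coefficients are re-fit by the same bagging machinery, and the same
scoring path is applied; the 95th percentile of 20 such scores is the
bar. The perturbation stage operates on a two-lineage subsystem
(progenitors plus two sister branches, with the embedding and clustering
recomputed on the subset) — more than two arms cannot be resolved in a
single 2-D field, and the motivating analysis likewise focused on two
trajectories.

## The synthetic generator

The generator plants exactly the statistical structure the pipeline
assumes, under conditions chosen once:

* four sampling stages with overlapping latent-time windows covering
  s ∈ [0, 1]; branch point at s = 0.3; five branches with equal weights
  and two lineage TFs each (an early and a late one);
* eight target genes per TF, each with two enhancer peaks whose activity
  is a logistic (floor 0.15, span 0.8, slope 6) of a phase-specific
  drive: a Gaussian rise (width 0.22) to a phase center (start 0.5,
  middle 0.7, end 0.9) that decays only to a 0.5 plateau — activated
  programs stay partially on, which keeps the expression manifold
  monotone along each branch while leaving distinct peak positions for
  stage grouping;
* RNA counts are negative binomial (θ = 10) around depth × baseline ×
  (1 + w·Σ enhancer activity), with the strong planted link weight
  w = 5; ATAC counts are Poisson truncated at 5 around depth × peak
  scale × activity, with enhancer count scale 1.5 so enhancer
  accessibility overlaps the background peaks' range (otherwise
  covariate-matched background sampling would be degenerate);
* global proliferation (declining, 40 genes) and maturation (rising,
  40 genes) programs at amplitude 3 encode latent time the way broad
  developmental programs do in real tissue; multipotent cells get
  elevated true growth via the proliferation term and per-branch growth
  multipliers;
* a ~8 Mb synthetic genome of ~100 contigs carries every peak with a
  GC gradient (targets 0.25–0.75); each lineage TF's PWM consensus is
  embedded in all of its targets' enhancers; a handful of decoy PWMs
  mapped to housekeeping genes is included but never planted;
* fragments are generated one per ATAC count inside the counted peak,
  with sub-nucleosomal/mononucleosomal mixture lengths (70%/30%,
  ~80/~200 bp), so the fragment-based QC metrics are exercised; 10%
  junk barcodes with tiny depth, inflated mitochondrial share and
  mono-only fragments are appended and must fail QC.

Gene placement enforces that no two same-branch genes share a contig, so
no candidate window contains an enhancer of a co-regulated gene — planted
links are the only true positives among the ~30,000 candidate pairs.
Proliferation/maturation genes avoid target-bearing contigs for the same
reason.

What the generator does **not** emulate: doublets, batch effects,
replicate structure within stages (replicates affected only batch QC in
the motivating study), read-level fragments (no BAM), spliced/unspliced
layers, trans-contig regulation, silencers, and dispersion/depth
distributions fitted to any real dataset (θ and the depth lognormals are
conventional choices, documented, not fitted). Passing the recovery
tests therefore shows the pipeline is correct *given its model
assumptions*; it does not certify performance on real tissue, where
covariate structure, contamination and unmodeled variation are richer.

## Problem sizes and determinism

The default study conditions are 2,000 cells (500 per stage), 1,000
genes and 3,000 peaks — small enough that the full pipeline (simulation
through knockout scoring) completes in a few minutes on one CPU, yet
large enough that the planted structure is comfortably recoverable
(observed: link recall ≈ 0.95 at precision ≈ 0.92; per-branch pseudotime
Spearman 0.93–0.95; terminal macrostates 1:1 onto the five branches;
driver and dual-marker recall 1.0; progenitor fate antagonism ≈ −0.3).
Unit tests run a 320-cell, 200-gene, 640-peak configuration of the same
generator. Every stochastic operation takes a seed and restores the
caller's RNG state; identical (config, seed) reproduce the generator's
outputs bit-identically.

## Known limitations

* The GPCCA approximation is a hard partition of an eigenvector space;
  its coarse diagonal scale differs from soft-membership implementations
  (hence the 0.8 terminal threshold). The absorption probabilities
  themselves are exact given the terminal sets and are anchored to a
  Monte-Carlo oracle in the tests.
* The bagged-ridge p-value is a stability statistic, not a sampling
  p-value; it is calibrated empirically against permuted targets.
* Perturbation scores have implementation-defined absolute scale; only
  signs and orderings (own branch vs sister branch vs random pseudo-TFs)
  are interpreted.
* The linkage test's background matching assumes enough peaks share each
  tested peak's covariate neighbourhood; with very few peaks the null
  degenerates (the package requires at least a handful of matchable
  peaks and reports skipped pairs).
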