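# palatrix

Paired single-cell multiome (scRNA + scATAC) analysis of a branching
developmental system, from raw count matrices to in silico
transcription-factor knockouts — with a synthetic multiome generator that
plants the regulatory structure the analysis is supposed to find, so every
stage of the pipeline can be tested against ground truth without any
external download.

The scientific setting is a developing tissue sampled at four embryonic
stages in which a multipotent progenitor population differentiates into
several terminal lineages (the motivating system is the embryonic
secondary palate, where anterior and posterior mesenchymal lineages are
driven by antagonistic transcription factors and their enhancers). The
package is aimed at computational biologists who want a compact, fully
testable re-implementation of that workflow.

## What the package computes

| Stage | Model / statistic |
|---|---|
| QC | nCount/nFeature/percent.mt, fragment-based nucleosome signal and TSS enrichment; joint strict filters (200 < nCount < 100,000, nFeature < 7,500, %mt < 20, nucleosome signal < 2, TSS enrichment > 1) |
| Embeddings | median-scaled log normalization, PCA on 3,000 HVGs; ATAC LSI = SVD of log1p(TF x IDF x 1e4) with component 1 dropped (it tracks depth); Leiden clustering; gene-activity scores |
| Peak–gene links | Pearson r between normalized expression and peak counts for all pairs with \|peak midpoint − TSS\| ≤ 5×10⁵ bp; null mean/sd from the 200 background peaks nearest in standardized (GC, accessibility, width) space; z = (r − μ₀)/σ₀, one-sided p, BH; links kept at r > 0, padj < 0.05 |
| Motifs | JASPAR PFM parsing, log-odds scanning of both strands at a scan p-value threshold (exact DP score distribution), chromVAR-style deviations z-scored against 50 GC/accessibility-matched background peak sets |
| Markers | one-vs-rest Wilcoxon rank-sum (tie- and continuity-corrected; exact tail for small tie-free samples), BH per group; dual-modality marker TFs = RNA-enriched **and** motif-deviation-enriched; hypergeometric motif enrichment and generic ORA (set sizes 5–500) |
| Trajectory | entropic unbalanced Sinkhorn couplings between adjacent stages (cost = squared Euclidean in 30 RNA PCs, growth-adjusted source marginal, 3 growth re-estimation rounds); layered transition matrix closed by a kNN kernel in the last stage; GPCCA-style macrostates, terminal states by stationary-weighted coarse self-transition; absorption fate probabilities from (I − Q)F = R; diffusion pseudotime; drivers (ρ > 0.05, padj < 0.05); start/middle/end stage groups (k-means on smoothed profiles) with stage-resolved motif enrichment |
| Perturbation | motif-prior candidate edges (TF motif in a linked or promoter peak), bagged ridge GRN per cluster on kNN-imputed expression (p < 0.001, ≤ 2,000 edges per cluster by \|coef\|); knockout = TF set to 0, 3 linear propagation rounds; embedding-shift vector field (n_neighbors = 200, sigma_corr = 0.05); developmental flow = gradient of grid-smoothed pseudotime; perturbation score = −Σ⟨shift, flow⟩ over a lineage's grid territory |
| Validation | ChIP TSS-proximity rates (±5 kb) with replicate t test + pooled Fisher; interval-overlap and gene-set Fisher tests (Haldane–Anscombe odds ratios); composition summaries with half-up rounding |

## Worked example

```r
library(palatrix)

cfg <- sim_config(cells_per_stage = rep(150, 4))   # 600 cells, defaults else
sim <- simulate_multiome(cfg, seed = 42)
dataset <- normalize_rna(filter_cells(sim$dataset))
dataset
#> MultiomeDataset: 600 cells x 1000 genes (RNA), 3000 peaks (ATAC)
#>   fragments: 444863 rows
#>   contigs: 100  layers: lognorm

links <- link_test(dataset, candidate_pairs(dataset$genes, dataset$peaks))
sig <- filter_links(links)
round(sig$summary, 3)
#> n_links n_genes     min  median    mean     max
#>  95.000  67.000   1.000   1.000   1.418   2.000

head(sig$links[order(sig$links$padj), c("gene_id", "peak_id", "r", "z", "padj")], 3)
#>      gene_id           peak_id     r    z     padj
#> 381  Tg3.1.1  chr3:13100-13600 0.292 5.88 5.17e-05
#> 2221 Tg5.2.2 chr12:30400-30900 0.314 5.79 5.17e-05
#> 2371 Tg4.2.3 chr13:19100-19600 0.254 5.57 1.31e-04
```

The significant links are almost all planted enhancer–gene pairs
(precision 0.92 here); at this reduced cell count roughly half of the
planted links are recovered, while the default 2,000-cell configuration
reaches ≈ 0.95 recall at ≈ 0.92 precision. The `r` column is the observed
expression–accessibility correlation, `z` its distance from the
background-matched null, and `padj` the BH-adjusted one-sided p-value.
Downstream, `run_trajectory()` produces fate probabilities and pseudotime,
and `run_perturbation()` + `knockout_score()` quantify how strongly an in
silico TF knockout reverses the developmental flow of each lineage.

## The methods vignette

`vignettes/palatrix-methods.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
choices made where the design was genuinely open.
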