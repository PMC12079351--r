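# stellaniche

Statistical toolkit for dissecting **pancreatic stellate cell (PSC)
heterogeneity** in pancreatic ductal adenocarcinoma (PDAC) and relating it
to chromatin accessibility, spatial organisation, and patient survival.
It is aimed at computational biologists who have cluster-annotated
single-cell data, condition-level bulk RNA/ATAC data, spatial spot data
with a reference signature matrix, or cohort survival tables — and who
want the downstream association statistics, not another clustering tool.

## What it computes

- **Tissue enrichment (Ro/e).** For each (cluster, tissue) pair, the
  ratio of observed to chi-square expected cell counts,
  `Ro/e = n_ct / (n_c. n_.t / n)`. A cluster with `Ro/e > 1` in tumor
  tissue is called tumor-associated (TPSC), otherwise common (CPSC).
- **Cluster markers** by each-vs-rest Wilcoxon rank-sum tests on
  log-normalized counts (`min.pct = 0.2`, `logFC >= 0.25`, Bonferroni).
- **Gene-signature scores** as the mean per-gene z-score of
  log-normalized expression over a gene set, per cell.
- **Shannon expression diversity** `H = -Σ p_g ln p_g` over pooled gene
  proportions, per group and per cell.
- **Bulk differential expression** via the negative-binomial Wald test
  (DESeq2 workflow), with the DEG rule `|log2FC| > 1` and `p < 0.05`.
- **ATAC differential peaks** between two condition-level peak tables by
  normalized signal ratio (fold change ≥ 3, condition-exclusive peaks
  count as differential), nearest-TSS annotation with promoter /
  UTR / exon / intron / intergenic categories.
- **Co-regulated peaks:** differential peaks annotated to differentially
  expressed genes with consistent direction (`coUp`, `coDown`).
- **Motif-set enrichment** by the upper-tail hypergeometric test with BH
  adjustment.
- **Spot deconvolution** by non-negative least squares against reference
  signatures, PSC spot assignment by the `> 10%` total + argmax rule,
  region-stratified abundance tests (Mal / Bdy / nMal), pairwise Pearson
  co-localization, and NMF niche factorization (k = 6 default).
- **Survival association:** maximally selected rank-statistic cutpoint
  (the score split maximizing the standardized log-rank statistic
  `|O - E| / sqrt(V)`), log-rank test, Cox proportional-hazards HR with
  95% CI, and a per-feature screen.

A synthetic-data module (`generateSingleCell`, `generateBulkPair`,
`generateAtacPeaks`, `generateSpatial`, `generateSurvival`, ...)
generates every input with planted ground truth, so the full pipeline is
testable end to end without external downloads. `runPipeline(demoConfig())`
chains all stages from one config and writes a JSON run report with a
planted-truth recovery summary.

## Worked example

```r
library(stellaniche)

## single-cell: planted tumor enrichment, recovered by Ro/e
sc <- generateSingleCell(nCells = 3000, enrichmentFactor = 3, seed = 1)
rt <- roeEnrichment(SummarizedExperiment::colData(sc$counts))
rt
#> RoeTable: 7 clusters x 2 tissues, 3000 cells
#> Ro/e ratios:
#>            normal tumor
#> CCL19_PSC   0.522 1.454
#> CPSC1       0.554 1.424
#> CPSC2       1.613 0.417
#> CPSC3       0.590 1.390
#> MYH11_PSC   0.511 1.465
#> PLXDC1_PSC  1.561 0.467
#> THBS4_PSC   1.487 0.537
#> chi-square p: 2.1e-153

classifyPrevalence(rt, "tumor")
#>          CCL19_PSC              CPSC1              CPSC2              CPSC3
#> "tumor-associated" "tumor-associated"           "common" "tumor-associated"
#>          MYH11_PSC         PLXDC1_PSC          THBS4_PSC
#> "tumor-associated"           "common"           "common"

## survival: planted hazard ratio 3 at the score median
sv <- generateSurvival(nPatients = 400, trueHr = 3, cutQuantile = 0.5,
                       seed = 1)
maxstatCutpoint(sv$survival)
#> CutpointResult: cut = 0.4776, |Z| = 9.126, groups 204/196
#>   HR 2.865 [2.266, 3.621], Cox p = 1.35e-18; log-rank p = 7.14e-20
#>   (inflated by cutpoint selection)
```

The Ro/e table recovers the planted design: four subclusters enriched in
tumor tissue (ratios ~1.4), three in normal. The survival cutpoint lands
at the planted median (0.478 on a Uniform(0,1) score) and the Cox HR of
2.87 [2.27, 3.62] covers the planted hazard ratio of 3. The reported
log-rank p is flagged because the cutpoint search makes the naive
p-value anti-conservative.

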