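---
title: "Methods: PSC heterogeneity, multi-omic integration and spatial niches"
author: "stellaniche authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSC heterogeneity, multi-omic integration and spatial niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`stellaniche`, the assumptions behind them, the defaults and why they
were chosen, and what the synthetic-data generators do and do not
emulate. The package addresses a recurring analysis pattern in pancreatic
cancer stroma biology: pancreatic stellate cells (PSCs) activate from a
quiescent, lipid-storing state into myofibroblast-like states in the
tumor microenvironment, and the questions are (i) which PSC subclusters
are tumor-enriched, (ii) how activation rewires expression and chromatin
together, (iii) where subclusters sit in tissue space and with whom, and
(iv) whether their abundance carries prognostic information.

## Tissue enrichment: the Ro/e ratio

For a cluster-by-tissue contingency table of cell counts, the expected
count under independence is the chi-square expectation
$E_{ct} = n_{c\cdot}\,n_{\cdot t}/n$, and the enrichment ratio is
$R_{O/E} = n_{ct}/E_{ct}$. A cluster is called enriched in a tissue when
the ratio strictly exceeds 1 (`classifyPrevalence`); the boundary value
1 is classified as common, a deliberate strict-inequality convention.
Undefined ratios (zero expectation) are reported as missing, and the
chi-square test p-value for the whole table is reported alongside for
reference, since the ratio itself carries no significance calibration.

A structural property worth knowing: because enrichment inflates the
margins too, with only two tissues the ratio is bounded above by
$2f/(f+1) < 2$ for any planted enrichment factor $f$. Ratios of ~1.4–1.6
in a two-tissue design therefore reflect strong enrichment; recovery is
judged by `Ro/e > 1`, not by the ratio approaching $f$.

## Markers, signatures, diversity

`findMarkers` log-normalizes counts (counts-per-10k then `log1p` — the
scale factor is a convention; results are rank-based and insensitive to
it), pre-filters genes by within-cluster detection (`min.pct = 0.2`) and
each-vs-rest log2 fold change (expm1-mean with pseudocount 1,
threshold 0.25), tests with the two-sided Wilcoxon rank-sum test, and
adjusts by Bonferroni over all genes in the matrix — the conventional,
conservative choice for marker lists.

`signatureScore` interprets "mean scaled expression" as: z-score each
gene of the set across all observations of the supplied matrix, then
average over the set's genes present. Zero-variance genes contribute 0
rather than NaN so scores stay finite; absent genes are dropped and the
count of genes actually used is recorded. Because scaling is internal to
the supplied matrix, scores are comparable only within one matrix.

`expressionDiversity` computes the Shannon index
$H=-\sum_g p_g \ln p_g$ (natural log) on gene proportions, either pooled
over a group or per cell; both variants are exposed because
distributional comparisons of diversity are typically drawn per cell
while group summaries are pooled. $H$ is non-negative and bounded by the
log of the number of expressed genes.

## Bulk differential expression and the DEG rule

`differentialExpressionBulk` delegates to the standard DESeq2 negative
binomial workflow: median-of-ratios size factors, dispersion estimation
shrunk toward a fitted mean–dispersion trend, and the Wald test, with
Benjamini–Hochberg adjustment reported. The DEG flag applies
`|log2FC| > 1` (a 2-fold change) together with the **raw** p-value
`< 0.05`. Using raw p for the flag while also reporting adjusted p is
intentional and recorded in the result's attributes: the flag reproduces
a widely used published filter, and the adjusted p column lets users
apply the stricter criterion. All-zero genes are excluded from testing
and listed. Independent filtering and Cook's-distance filtering are
disabled so every expressed gene receives a p-value, which keeps the
null calibration of the raw-p filter interpretable.

## ATAC differential peaks, annotation, co-regulation

Peak calling from reads is out of scope; the input boundary is a
condition-level peak table (intervals plus a signal column). Between two
conditions, overlapping peaks (≥ 1 bp) are merged to their union
interval and compared by the ratio of signals after scaling both tables
to equal totals, with a pseudocount of 1. The retention threshold, fold
change ≥ 3, is applied symmetrically as the differential criterion; a
peak present in only one condition is condition-exclusive and counts as
differential in that direction. Overlaps within a single input table are
merged first (signals summed) with a warning. This makes the operation
exactly antisymmetric: swapping inputs swaps up and down calls.

`annotatePeakRegions` assigns each peak to the gene with the nearest TSS
from the peak midpoint (midpoint of the 0-based half-open interval;
coordinate convention is BED throughout, with 1-based annotation input
converted on read). Ties go to the lexicographically smaller gene id so
results are deterministic. The category is promoter when the midpoint
lies within [−1000, +100] bp of the TSS, strand-aware — windows are a
documented convention, since category vocabularies rarely state them —
otherwise 5′-UTR, 3′-UTR, exon, intron by containment in the assigned
gene, else intergenic.

`integrateCoRegulation` defines a co-regulated peak as a differential
peak annotated to a differentially expressed gene with the same
direction of change. Up-peaks on up-DEGs form `coUp`; down-peaks on
down-DEGs form `coDown`; discordant and neutral pairs are excluded and
unannotated peaks are skipped and counted. Disjointness and direction
consistency are enforced by the class validity check.

`motifEnrichment` tests each motif by the upper-tail hypergeometric
probability of at least the observed foreground hit count when drawing
the foreground from the pooled universe, with BH adjustment across
motifs. With zero observed hits the upper-tail probability is 1 by the
"at least observed" convention. Motif occurrences are inputs; scanning
and discovery are out of scope.

## Spatial deconvolution and niches

`deconvolve` is a deliberate linear stand-in for probabilistic
deconvolution: per spot, a non-negative least-squares fit of the spot's
expression to the reference profiles on shared genes, both normalized to
equal totals, with coefficients rescaled to proportions and the residual
norm reported. It is deterministic, exactly testable on constructed
mixtures, and scale-invariant in the spot's library size. Posterior
uncertainty and spot-level detection effects of Bayesian models are not
reproduced; point estimates are used downstream. A rank-deficient
reference is refused with the collinear profiles named.

`assignPscSpots` applies the assignment rule for PSC-carrying spots: a
spot is assigned iff the summed PSC-subcluster abundance strictly
exceeds 10%, labelled by the argmax subcluster; argmax ties are broken
lexicographically and flagged. `regionAbundance` stratifies one cell
type's abundance by region label (malignant core `Mal`, tumor boundary
`Bdy`, non-malignant `nMal` — labels are inputs) and compares region
pairs by Wilcoxon rank-sum with BH over the three pairs.
`colocalization` is the pairwise Pearson correlation of per-spot
proportions; zero-variance types yield missing entries rather than
zeros. By default all spots enter the correlation; restricting to
PSC-assigned spots is possible by subsetting the abundance matrix first.

`nmfNiches` factorizes the spot-by-type abundance matrix with
multiplicative-update NMF under squared error, `k = 6` by default —
small enough to keep factors interpretable as recurring cellular
neighborhoods, large enough to separate the major compartments. The
initialization is seeded uniform-random scaled by the matrix mean;
iteration stops at 500 updates or a relative objective change below
1e-6, the objective is checked to be non-increasing, and factors are
sorted by total loading for stable ordering.

## Survival association

`logrankTest` computes the two-group log-rank statistic from first
principles on the pooled event-time grid — observed events, summed
expectations, and the hypergeometric variance with the tie correction —
so the identity `statistic = (O−E)²/V` holds by construction. The
package's tests cross-check it against an independent implementation.

`maxstatCutpoint` evaluates the standardized statistic `|O−E|/√V` at
every candidate cutpoint of a continuous score between its 10% and 90%
quantiles (both groups at least 5 patients) and returns the maximizer.
Two caveats are built into the result object: the dichotomy depends on
the score only through ranks (any monotone transform gives the same
split), and the log-rank p-value reported at the selected cutpoint
ignores the search and is therefore anti-conservative — the result
carries a permanent `pInflated` flag instead of a small-sample
correction, which keeps the reported quantity identical to the common
published practice while labelling its bias.

`coxHR` fits a univariate Cox proportional-hazards model (Efron tie
handling, Newton iterations capped at 50) via the survival package and
reports the hazard ratio with a Wald 95% CI. Diverging coefficients are
reported as suspected complete separation rather than returned.
`survivalScreen` runs maxstat + Cox per feature, flags significance at
Cox p < 0.05, orders by hazard ratio, and marks failing features instead
of aborting the screen.

## The synthetic-data generators

The generators emulate the statistical structure of the study designs
the methods target, with planted ground truth recorded in a
`SyntheticTruth` object; with a fixed seed every generator is
bit-reproducible.

- `generateSingleCell`: cells drawn from a cluster-by-tissue joint
  distribution in which each cluster's planted tissue carries
  `enrichmentFactor` times the weight of the others (factor 1 is exactly
  null); counts are negative binomial with log-normal gene means and
  boosted cluster markers; a few `MT-` genes support QC. The default
  seven subclusters over tumor/normal with round-robin planting yield
  four tumor-enriched and three normal-enriched clusters, mirroring the
  TPSC/CPSC split.
- `generateBulkPair`: triplicate quiescent-vs-activated NB counts
  (dispersion 0.05 by default, a typical sorted-bulk value), a planted
  DEG fraction split evenly between directions, library sizes varying
  0.5–2×.
- `generateAtacPeaks`: paired condition-level peak tables sharing
  intervals; planted co-regulated peaks sit in promoter windows of
  planted DEGs with a 5-fold signal change in the matching direction.
  Planted peaks follow the DEG table's direction split so equal-total
  normalization preserves their folds; the remainder cycles through
  neutral, discordant, and intergenic distractors.
- `generateSpatial`: Dirichlet-style abundances on a spot grid; niche
  members get low-variance gammas multiplied by a shared log-normal
  factor, so the shared factor dominates their across-spot spread and
  their truth correlation is high; the first niche's factor is
  concentrated in the Bdy band of a concentric Mal/Bdy/nMal geometry.
  Spot expression mixes column-normalized reference profiles (each
  type's profile as a transcript distribution) times a library size,
  plus zero-truncated Gaussian noise; because deconvolution normalizes
  the same way, the noise-free case is exactly recoverable.
- `generateSurvival`: Uniform(0,1) score, exponential event times with
  the hazard multiplied by the true HR above the planted score quantile,
  and independent exponential censoring calibrated by solving the
  competing-exponentials censoring probability for the target rate.

What the generators do **not** emulate: read-level sequencing artefacts,
doublets, batch effects, spatial autocorrelation beyond the planted
niche factors and region bands, non-proportional hazards, and informative
censoring. Passing recovery tests on these generators therefore
demonstrates correctness of the statistics under their stated models,
not robustness to every artefact of real data.

## Numerical conventions and problem sizes

Degenerate inputs fail loudly and specifically: a single tissue for
Ro/e, an all-identical score for maxstat, a rank-deficient reference for
deconvolution, a niche naming an unknown cell type. Ties are always
broken deterministically (lexicographic ids). Coordinates are BED
0-based half-open on disk and GRanges 1-based in memory. The test-suite
and acceptance-script simulations use modest problem sizes — thousands
of cells, 1–2k genes, a few hundred spots or patients, and 10–20
replicate seeds per calibration — chosen so the whole suite runs in a
few minutes while keeping Monte Carlo noise well inside the asserted
margins.

## Known limitations

- The NNLS deconvolution ignores spot-level detection variation and
  returns point estimates; abundances for closely collinear cell types
  will trade off against each other.
- The maxstat p-value is intentionally uncorrected (flagged instead);
  for formal inference a permutation or improved-Bonferroni correction
  would be required.
- Marker testing loops `wilcox.test` per candidate gene and is meant for
  cluster-scale matrices, not genome-wide scans across hundreds of
  clusters.
- The DEG flag's raw-p criterion is anti-conservative by construction;
  the BH-adjusted column should be preferred when controlling FDR
  matters more than matching the published filter.
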