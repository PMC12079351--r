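## Central S4 containers. Count matrices travel as SummarizedExperiment
## (assay "counts" or "expression", colData = observation metadata,
## rowData$mito = mitochondrial flag); peak tables travel as GRanges with
## signal/direction/annotation metadata columns.

#' Planted ground truth attached to synthetic datasets
#'
#' Each generator records what it planted so downstream recovery can be
#' checked without external data: which cluster is enriched in which
#' tissue, the true DEG table, co-regulated peak assignments, co-localized
#' niche sets, and the survival effect.
#'
#' @slot enrichedClusters named character; cluster -> tissue it is enriched in
#' @slot degTable data.frame with columns `gene`, `trueLog2fc`, `direction`
#' @slot coregPeaks data.frame with columns `peak`, `direction`, `gene`
#' @slot nicheSets list of character vectors of co-localized cell types
#' @slot survivalEffect named numeric: `hr`, `cutQuantile`
#' @slot seed integer seed the dataset was generated from
#' @export
setClass("SyntheticTruth",
  representation(
    enrichedClusters = "character",
    degTable         = "data.frame",
    coregPeaks       = "data.frame",
    nicheSets        = "list",
    survivalEffect   = "numeric",
    seed             = "integer"
  ),
  prototype(
    enrichedClusters = character(),
    degTable         = data.frame(),
    coregPeaks       = data.frame(),
    nicheSets        = list(),
    survivalEffect   = numeric(),
    seed             = NA_integer_
  )
)

#' Observed/expected tissue-enrichment table (Ro/e)
#'
#' Cluster-by-tissue contingency of cell counts with chi-square expected
#' counts, the observed/expected ratio, and per-cluster prevalence labels.
#' A ratio above 1 marks a (cluster, tissue) pair as enriched.
#'
#' @slot observed cluster x tissue matrix of cell counts
#' @slot expected cluster x tissue matrix of chi-square expected counts
#' @slot roe observed/expected ratio, `NA` where expected is zero
#' @slot prevalence named character; cluster -> tissue of maximal Ro/e
#' @slot chisqP chi-square test p-value for the whole table
#' @export
setClass("RoeTable",
  representation(
    observed   = "matrix",
    expected   = "matrix",
    roe        = "matrix",
    prevalence = "character",
    chisqP     = "numeric"
  )
)

setValidity("RoeTable", function(object) {
  msg <- character()
  if (!all(dim(object@observed) == dim(object@expected)) ||
      !all(dim(object@observed) == dim(object@roe)))
    msg <- c(msg, "observed, expected and roe must share dimensions")
  if (any(abs(rowSums(object@expected) - rowSums(object@observed)) > 1e-9))
    msg <- c(msg, "expected row sums must equal observed row sums")
  if (any(abs(colSums(object@expected) - colSums(object@observed)) > 1e-9))
    msg <- c(msg, "expected column sums must equal observed column sums")
  pos <- object@expected > 0
  if (any(pos) &&
      any(abs(object@roe[pos] - object@observed[pos] / object@expected[pos]) >
            1e-9, na.rm = TRUE))
    msg <- c(msg, "roe must equal observed/expected where expected > 0")
  if (length(msg)) msg else TRUE
})

#' Per-spot (or per-sample) cell-type abundance matrix
#'
#' Rows are spatial spots or bulk samples, columns are cell types; entries
#' are non-negative proportions summing to at most 1 per row. Spots may
#' carry coordinates and a region label (`Mal`, `Bdy`, `nMal`).
#'
#' @slot abundance spots x cell-types numeric matrix
#' @slot coords spots x 2 coordinate matrix (may have zero rows)
#' @slot region character region label per spot (may be empty)
#' @export
setClass("AbundanceMatrix",
  representation(
    abundance = "matrix",
    coords    = "matrix",
    region    = "character"
  ),
  prototype(coords = matrix(numeric(), 0, 2), region = character())
)

setValidity("AbundanceMatrix", function(object) {
  msg <- character()
  if (any(object@abundance < 0))
    msg <- c(msg, "abundances must be non-negative")
  if (any(rowSums(object@abundance) > 1 + 1e-6))
    msg <- c(msg, "per-spot abundances must sum to at most 1")
  if (nrow(object@coords) > 0 && nrow(object@coords) != nrow(object@abundance))
    msg <- c(msg, "coords must have one row per spot")
  if (length(object@region) > 0 &&
      length(object@region) != nrow(object@abundance))
    msg <- c(msg, "region must have one label per spot")
  if (length(msg)) msg else TRUE
})

#' Co-regulated peak sets from RNA/ATAC integration
#'
#' Differential open-chromatin peaks annotated to differentially expressed
#' genes with consistent direction of change: `coUp` holds up-peaks on
#' up-DEGs, `coDown` down-peaks on down-DEGs.
#'
#' @slot coUp character peak ids co-upregulated with their gene
#' @slot coDown character peak ids co-downregulated with their gene
#' @slot mapping data.frame with columns `peak`, `peakDirection`, `gene`,
#'   `geneDirection` for every co-regulated peak
#' @export
setClass("CoRegulatedSet",
  representation(
    coUp    = "character",
    coDown  = "character",
    mapping = "data.frame"
  )
)

setValidity("CoRegulatedSet", function(object) {
  msg <- character()
  if (length(intersect(object@coUp, object@coDown)))
    msg <- c(msg, "coUp and coDown must be disjoint")
  if (nrow(object@mapping) &&
      !all(object@mapping$peakDirection == object@mapping$geneDirection))
    msg <- c(msg, "peak direction must match gene DEG direction")
  if (length(msg)) msg else TRUE
})

#' Non-negative niche factors from NMF of an abundance matrix
#'
#' @slot spotLoadings spots x k non-negative loading matrix
#' @slot typeWeights k x cell-types non-negative weight matrix
#' @slot reconError relative Frobenius reconstruction error
#' @slot objective squared-error objective trace across iterations
#' @export
setClass("NicheFactors",
  representation(
    spotLoadings = "matrix",
    typeWeights  = "matrix",
    reconError   = "numeric",
    objective    = "numeric"
  )
)

setValidity("NicheFactors", function(object) {
  msg <- character()
  if (any(object@spotLoadings < 0) || any(object@typeWeights < 0))
    msg <- c(msg, "factors must be non-negative")
  if (ncol(object@spotLoadings) != nrow(object@typeWeights))
    msg <- c(msg, "loading and weight factor counts must agree")
  if (length(msg)) msg else TRUE
})

#' Maximally selected rank-statistic cutpoint result
#'
#' The score cutpoint maximizing the standardized two-group log-rank
#' statistic, the naive log-rank p at that cutpoint (inflated by the
#' selection, hence flagged), and the Cox hazard ratio of the dichotomy.
#'
#' @slot cutpoint selected score threshold (high group: score > cutpoint)
#' @slot statistic maximal standardized log-rank statistic |Z|
#' @slot groupSizes integer sizes of the low/high groups
#' @slot logrankP naive log-rank p-value at the selected cutpoint
#' @slot pInflated always `TRUE`: the p-value ignores the cutpoint search
#' @slot hr Cox hazard ratio (high vs low)
#' @slot ciLower,ciUpper Wald 95 percent confidence bounds for the HR
#' @slot coxP Cox Wald p-value
#' @export
setClass("CutpointResult",
  representation(
    cutpoint   = "numeric",
    statistic  = "numeric",
    groupSizes = "integer",
    logrankP   = "numeric",
    pInflated  = "logical",
    hr         = "numeric",
    ciLower    = "numeric",
    ciUpper    = "numeric",
    coxP       = "numeric"
  )
)

setValidity("CutpointResult", function(object) {
  msg <- character()
  if (length(object@statistic) && object@statistic < 0)
    msg <- c(msg, "statistic must be non-negative")
  if (length(object@groupSizes) != 2L || any(object@groupSizes < 1L))
    msg <- c(msg, "both score groups must be non-empty")
  if (length(msg)) msg else TRUE
})

## ---- accessors ------------------------------------------------------------

#' @describeIn RoeTable-class observed cell counts
#' @param object a `RoeTable`
#' @export
setGeneric("observedCounts", function(object) standardGeneric("observedCounts"))
#' @export
setMethod("observedCounts", "RoeTable", function(object) object@observed)

#' @describeIn RoeTable-class chi-square expected counts
#' @export
setGeneric("expectedCounts", function(object) standardGeneric("expectedCounts"))
#' @export
setMethod("expectedCounts", "RoeTable", function(object) object@expected)

#' @describeIn RoeTable-class observed/expected ratio matrix
#' @export
setGeneric("roe", function(object) standardGeneric("roe"))
#' @export
setMethod("roe", "RoeTable", function(object) object@roe)

#' @describeIn RoeTable-class per-cluster prevalence labels
#' @export
setGeneric("prevalence", function(object) standardGeneric("prevalence"))
#' @export
setMethod("prevalence", "RoeTable", function(object) object@prevalence)

#' @describeIn AbundanceMatrix-class abundance matrix (spots x types)
#' @param object an `AbundanceMatrix`
#' @export
setGeneric("abundance", function(object) standardGeneric("abundance"))
#' @export
setMethod("abundance", "AbundanceMatrix", function(object) object@abundance)

#' @describeIn AbundanceMatrix-class spot coordinates
#' @export
setGeneric("spotCoords", function(object) standardGeneric("spotCoords"))
#' @export
setMethod("spotCoords", "AbundanceMatrix", function(object) object@coords)

#' @describeIn AbundanceMatrix-class spot region labels
#' @export
setGeneric("spotRegions", function(object) standardGeneric("spotRegions"))
#' @export
setMethod("spotRegions", "AbundanceMatrix", function(object) object@region)

#' @describeIn CoRegulatedSet-class co-upregulated peak ids
#' @param object a `CoRegulatedSet`
#' @export
setGeneric("coUpPeaks", function(object) standardGeneric("coUpPeaks"))
#' @export
setMethod("coUpPeaks", "CoRegulatedSet", function(object) object@coUp)

#' @describeIn CoRegulatedSet-class co-downregulated peak ids
#' @export
setGeneric("coDownPeaks", function(object) standardGeneric("coDownPeaks"))
#' @export
setMethod("coDownPeaks", "CoRegulatedSet", function(object) object@coDown)

#' @describeIn CoRegulatedSet-class peak-to-gene mapping table
#' @export
setGeneric("peakGeneMap", function(object) standardGeneric("peakGeneMap"))
#' @export
setMethod("peakGeneMap", "CoRegulatedSet", function(object) object@mapping)

#' @describeIn CutpointResult-class selected cutpoint
#' @param object a `CutpointResult`
#' @export
setGeneric("cutpoint", function(object) standardGeneric("cutpoint"))
#' @export
setMethod("cutpoint", "CutpointResult", function(object) object@cutpoint)

#' @describeIn CutpointResult-class Cox hazard ratio of the dichotomy
#' @export
setGeneric("hazardRatio", function(object) standardGeneric("hazardRatio"))
#' @export
setMethod("hazardRatio", "CutpointResult", function(object) object@hr)

## ---- show methods ---------------------------------------------------------

setMethod("show", "RoeTable", function(object) {
  cat("RoeTable:", nrow(object@observed), "clusters x",
      ncol(object@observed), "tissues,",
      sum(object@observed), "cells\n")
  cat("Ro/e ratios:\n")
  print(round(object@roe, 3))
  cat("chi-square p:", format(object@chisqP, digits = 3), "\n")
})

setMethod("show", "AbundanceMatrix", function(object) {
  cat("AbundanceMatrix:", nrow(object@abundance), "spots x",
      ncol(object@abundance), "cell types\n")
  if (length(object@region))
    print(table(object@region))
})

setMethod("show", "CoRegulatedSet", function(object) {
  cat("CoRegulatedSet:", length(object@coUp), "co-up,",
      length(object@coDown), "co-down peaks over",
      length(unique(object@mapping$gene)), "genes\n")
})

setMethod("show", "NicheFactors", function(object) {
  cat("NicheFactors:", ncol(object@spotLoadings), "factors,",
      nrow(object@spotLoadings), "spots x",
      ncol(object@typeWeights), "cell types; relative error",
      format(object@reconError, digits = 4), "\n")
})

setMethod("show", "CutpointResult", function(object) {
  cat(sprintf(
    "CutpointResult: cut = %.4g, |Z| = %.3f, groups %d/%d\n",
    object@cutpoint, object@statistic,
    object@groupSizes[1], object@groupSizes[2]))
  cat(sprintf("  HR %.3f [%.3f, %.3f], Cox p = %.3g; log-rank p = %.3g %s\n",
    object@hr, object@ciLower, object@ciUpper, object@coxP,
    object@logrankP,
    if (isTRUE(object@pInflated)) "(inflated by cutpoint selection)" else ""))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth (seed", object@seed, "):",
      length(object@enrichedClusters), "enriched clusters,",
      nrow(object@degTable), "planted DEGs,",
      nrow(object@coregPeaks), "co-regulated peaks,",
      length(object@nicheSets), "niche sets\n")
})
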