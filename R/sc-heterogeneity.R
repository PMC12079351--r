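## Single-cell stage: QC filtering, cluster markers, Ro/e tissue
## enrichment, signature scoring, and Shannon expression diversity.

#' Filter cells by QC thresholds
#'
#' Keeps cells with detected genes in `[minGenes, maxGenes]`, total UMI in
#' `[minUmi, maxUmi]`, and mitochondrial count fraction at most `maxMito`.
#' The defaults are the standard thresholds for droplet data (300-6000
#' genes, 500-50000 UMI, 15 percent mitochondrial). The gene set is left
#' unchanged; counts removed per criterion are logged in
#' `metadata(result)$qcLog`.
#'
#' @param se SummarizedExperiment with assay `counts` and a logical
#'   `rowData(se)$mito` flag
#' @param minGenes,maxGenes detected-gene bounds
#' @param minUmi,maxUmi UMI-count bounds
#' @param maxMito maximal mitochondrial fraction
#' @return filtered SummarizedExperiment (warning, not error, when no cell
#'   survives)
#' @export
qcFilterCells <- function(se, minGenes = 300, maxGenes = 6000,
                          minUmi = 500, maxUmi = 50000, maxMito = 0.15) {
  stopifnot(is(se, "SummarizedExperiment"))
  mito <- rowData(se)$mito
  if (is.null(mito)) stop("rowData(se)$mito flag is required for QC")
  counts <- .assayMatrix(se)
  detected <- colSums(counts > 0)
  umi <- colSums(counts)
  mitoFrac <- ifelse(umi > 0, colSums(counts[mito, , drop = FALSE]) / umi, 1)

  passGenes <- detected >= minGenes & detected <= maxGenes
  passUmi <- umi >= minUmi & umi <= maxUmi
  passMito <- mitoFrac <= maxMito
  keep <- passGenes & passUmi & passMito
  if (!any(keep)) warning("no cell passed QC")

  out <- se[, keep]
  metadata(out)$qcLog <- list(
    input = ncol(se), kept = sum(keep),
    failedGenes = sum(!passGenes), failedUmi = sum(!passUmi),
    failedMito = sum(!passMito))
  out
}

#' Cluster marker genes by each-vs-rest Wilcoxon rank-sum test
#'
#' Expression is log-normalized internally (counts-per-10k, `log1p`). For
#' each cluster, genes expressed in at least `minPct` of the cluster's
#' cells and with log2 fold change at least `logfcThreshold` (each-vs-rest
#' expm1-mean with pseudocount 1) are tested with a two-sided Wilcoxon
#' rank-sum test; p-values are Bonferroni-adjusted over all genes in the
#' matrix. Clusters with fewer than 3 cells are skipped with a warning.
#'
#' @param se SummarizedExperiment with assay `counts` and a cluster column
#'   in `colData`
#' @param clusterCol name of the colData column holding cluster labels
#' @param minPct minimal within-cluster detection fraction
#' @param logfcThreshold minimal log2 fold change to test
#' @param onlyPos keep positive markers only
#' @return data.frame with cluster, gene, log2fc, pctIn, pctOut, p, pAdj,
#'   ordered by cluster then p
#' @export
findMarkers <- function(se, clusterCol = "cluster", minPct = 0.2,
                        logfcThreshold = 0.25, onlyPos = TRUE) {
  counts <- .assayMatrix(se)
  meta <- .obsMeta(se)
  if (!clusterCol %in% names(meta)) stop("no column '", clusterCol, "'")
  cl <- as.character(meta[[clusterCol]])
  if (length(unique(cl)) < 2) stop("need at least 2 clusters")
  ln <- logNormalizeCounts(counts)
  nGenesTotal <- nrow(counts)

  res <- list()
  for (k in sort(unique(cl))) {
    inIdx <- which(cl == k)
    outIdx <- which(cl != k)
    if (length(inIdx) < 3) {
      warning("cluster '", k, "' has fewer than 3 cells; skipped")
      next
    }
    pctIn <- rowMeans(counts[, inIdx, drop = FALSE] > 0)
    pctOut <- rowMeans(counts[, outIdx, drop = FALSE] > 0)
    meanIn <- rowMeans(expm1(ln[, inIdx, drop = FALSE]))
    meanOut <- rowMeans(expm1(ln[, outIdx, drop = FALSE]))
    lfc <- log2((meanIn + 1) / (meanOut + 1))
    cand <- which(pctIn >= minPct &
                    (if (onlyPos) lfc >= logfcThreshold
                     else abs(lfc) >= logfcThreshold))
    if (!length(cand)) next
    p <- vapply(cand, function(g)
      suppressWarnings(wilcox.test(ln[g, inIdx], ln[g, outIdx])$p.value),
      numeric(1))
    res[[k]] <- data.frame(
      cluster = k, gene = rownames(counts)[cand],
      log2fc = lfc[cand], pctIn = pctIn[cand], pctOut = pctOut[cand],
      p = p, pAdj = pmin(1, p * nGenesTotal),
      stringsAsFactors = FALSE, row.names = NULL)
    res[[k]] <- res[[k]][order(res[[k]]$p), ]
  }
  if (!length(res))
    return(data.frame(cluster = character(), gene = character(),
                      log2fc = numeric(), pctIn = numeric(),
                      pctOut = numeric(), p = numeric(), pAdj = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tissue enrichment by the observed-to-expected cell-count ratio (Ro/e)
#'
#' Cross-tabulates cluster against tissue and divides observed counts by
#' chi-square expected counts (row total x column total / grand total). A
#' ratio above 1 marks enrichment of the cluster in that tissue. The
#' chi-square test p-value for the whole table is reported alongside.
#'
#' @param obsMeta data.frame (or SummarizedExperiment whose colData) with
#'   columns `cluster` and `tissue`
#' @return a [RoeTable-class]
#' @export
roeEnrichment <- function(obsMeta) {
  meta <- .obsMeta(obsMeta)
  if (!all(c("cluster", "tissue") %in% names(meta)))
    stop("obsMeta needs 'cluster' and 'tissue' columns")
  tissues <- unique(as.character(meta$tissue))
  if (length(tissues) < 2)
    stop("enrichment is undefined with a single tissue")
  observed <- unclass(table(cluster = as.character(meta$cluster),
                            tissue = as.character(meta$tissue)))
  observed <- matrix(as.numeric(observed), nrow(observed), ncol(observed),
                     dimnames = dimnames(observed))
  expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  roeMat <- ifelse(expected > 0, observed / expected, NA_real_)
  prev <- apply(roeMat, 1, function(r) colnames(observed)[which.max(r)])
  chisqP <- suppressWarnings(chisq.test(observed)$p.value)
  new("RoeTable", observed = observed, expected = expected, roe = roeMat,
      prevalence = prev, chisqP = chisqP)
}

#' Classify clusters as tumor-associated or common from an Ro/e table
#'
#' A cluster is tumor-associated iff its Ro/e in the tumor tissue strictly
#' exceeds 1, otherwise common. Missing Ro/e entries yield `unclassified`
#' with a warning.
#'
#' @param roeTable a [RoeTable-class]
#' @param tumorLabel the tissue treated as tumor
#' @return named character vector: cluster -> `tumor-associated`, `common`
#'   or `unclassified`
#' @export
classifyPrevalence <- function(roeTable, tumorLabel = "tumor") {
  stopifnot(is(roeTable, "RoeTable"))
  roeMat <- roe(roeTable)
  if (!tumorLabel %in% colnames(roeMat))
    stop("tissue '", tumorLabel, "' not present in the Ro/e table")
  v <- roeMat[, tumorLabel]
  out <- ifelse(is.na(v), "unclassified",
                ifelse(v > 1, "tumor-associated", "common"))
  if (any(is.na(v)))
    warning("clusters with undefined Ro/e left unclassified: ",
            paste(names(v)[is.na(v)], collapse = ", "))
  setNames(out, rownames(roeMat))
}

#' Gene-signature score as mean scaled expression
#'
#' Log-normalizes the matrix, z-scores each gene across all observations,
#' and averages the z-scores over the genes of the set present in the
#' matrix. Zero-variance genes contribute 0; absent genes are dropped.
#'
#' @param se SummarizedExperiment (or counts matrix)
#' @param geneSet character vector of gene ids
#' @param geneSetId label used in messages and attributes
#' @return named numeric vector of per-observation scores with attributes
#'   `geneSetId` and `nGenesUsed`
#' @export
signatureScore <- function(se, geneSet, geneSetId = "signature") {
  counts <- .assayMatrix(se)
  genes <- intersect(geneSet, rownames(counts))
  if (!length(genes))
    stop("no gene of set '", geneSetId, "' is present in the matrix")
  ln <- logNormalizeCounts(counts)[genes, , drop = FALSE]
  mu <- rowMeans(ln)
  sdv <- apply(ln, 1, sd)
  z <- (ln - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  score <- colMeans(z)
  if (any(!is.finite(score))) stop("non-finite signature scores")
  attr(score, "geneSetId") <- geneSetId
  attr(score, "nGenesUsed") <- length(genes)
  score
}

#' Shannon diversity of gene expression
#'
#' For each group, gene proportions are pooled counts over the group
#' divided by the group total, and `H = -sum(p * log(p))` over expressed
#' genes (natural log). The same formula applied to single cells gives the
#' per-cell variant used for box-plot comparisons.
#'
#' @param se SummarizedExperiment (or counts matrix)
#' @param groups factor/character of group labels per observation
#' @return list with `perGroup` (named numeric H per group, `NA` for
#'   all-zero groups, with a warning) and `perCell` (H per observation)
#' @export
expressionDiversity <- function(se, groups) {
  counts <- .assayMatrix(se)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("groups must have one label per observation")
  shannon <- function(x) {
    tot <- sum(x)
    if (tot == 0) return(NA_real_)
    p <- x[x > 0] / tot
    -sum(p * log(p))
  }
  perGroup <- vapply(split(seq_along(groups), groups), function(idx)
    shannon(rowSums(counts[, idx, drop = FALSE])), numeric(1))
  if (anyNA(perGroup))
    warning("groups with all-zero counts: ",
            paste(names(perGroup)[is.na(perGroup)], collapse = ", "))
  perCell <- apply(counts, 2, shannon)
  list(perGroup = perGroup, perCell = perCell)
}
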