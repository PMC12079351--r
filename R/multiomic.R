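## Multi-omic stage: bulk NB differential expression, ATAC differential
## peaks, nearest-TSS annotation, co-regulated peak integration, and
## hypergeometric motif-set enrichment.

#' Bulk RNA-seq differential expression (negative-binomial Wald test)
#'
#' Wraps the standard DESeq2 workflow (median-of-ratios size factors,
#' trend-shrunk dispersion estimates, Wald test, Benjamini-Hochberg
#' adjustment) and applies the DEG rule used throughout this package:
#' |log2 fold change| > 1 (a 2-fold change) and raw p < 0.05. The
#' adjusted p-value is reported alongside; the flag deliberately uses the
#' raw p, and that choice is recorded in the result's attributes.
#'
#' @param se SummarizedExperiment with assay `counts` and colData
#'   `condition` (or a counts matrix plus `condition`)
#' @param condition optional condition vector overriding colData
#' @param contrast character(2): numerator and denominator condition
#'   levels; defaults to the second level vs the first
#' @param lfcCut DEG log2 fold-change threshold (strict >)
#' @param pCut DEG raw p-value threshold
#' @return data.frame per tested gene: gene, baseMean, log2FoldChange,
#'   pvalue, padj, deg, direction; all-zero genes are excluded and listed
#'   in `attr(result, "excludedGenes")`; `attr(result, "degRule")`
#'   documents the filter
#' @export
differentialExpressionBulk <- function(se, condition = NULL,
                                       contrast = NULL,
                                       lfcCut = 1, pCut = 0.05) {
  counts <- .assayMatrix(se)
  if (is.null(condition)) {
    meta <- .obsMeta(se)
    if (!"condition" %in% names(meta))
      stop("colData needs a 'condition' column (or pass `condition`)")
    condition <- meta$condition
  }
  # keep the input order: the second condition encountered is the numerator
  condition <- factor(condition, levels = unique(as.character(condition)))
  if (nlevels(condition) != 2) stop("exactly two conditions are required")
  if (min(table(condition)) < 2)
    stop("need at least 2 replicates per condition")
  if (is.null(contrast))
    contrast <- c(levels(condition)[2], levels(condition)[1])

  allZero <- rownames(counts)[rowSums(counts) == 0]
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  storage.mode(counts) <- "integer"

  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = counts,
    colData = data.frame(condition = condition),
    design = ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds, contrast = c("condition", contrast),
                         independentFiltering = FALSE, cooksCutoff = FALSE)

  out <- data.frame(
    gene = rownames(res),
    baseMean = res$baseMean,
    log2FoldChange = res$log2FoldChange,
    pvalue = res$pvalue,
    padj = res$padj,
    stringsAsFactors = FALSE, row.names = NULL)
  out$deg <- !is.na(out$pvalue) & abs(out$log2FoldChange) > lfcCut &
    out$pvalue < pCut
  out$direction <- ifelse(!out$deg, "none",
                          ifelse(out$log2FoldChange > 0, "up", "down"))
  attr(out, "excludedGenes") <- allZero
  attr(out, "degRule") <- sprintf(
    "|log2FC| > %g and raw p < %g (BH-adjusted p reported, not used for the flag)",
    lfcCut, pCut)
  out
}

## Merge overlapping intervals within one table, summing signal.
.mergeWithin <- function(gr, label) {
  red <- reduce(gr, ignore.strand = TRUE)
  if (length(red) == length(gr)) return(gr)
  warning("overlapping peaks within ", label, " merged (",
          length(gr), " -> ", length(red), ")")
  hits <- findOverlaps(red, gr)
  sig <- tapply(mcols(gr)$signal[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), sum)
  mcols(red)$signal <- as.numeric(sig[as.character(seq_along(red))])
  nm <- tapply(names(gr)[S4Vectors::subjectHits(hits)],
               S4Vectors::queryHits(hits), function(x) x[1])
  names(red) <- as.character(nm[as.character(seq_along(red))])
  red
}

#' Call differential peaks between two condition-level peak tables
#'
#' Peaks overlapping by at least 1 bp between the two conditions are
#' merged to their union interval and compared by the ratio of normalized
#' signals (each table scaled to the same total, pseudocount 1). A merged
#' peak is `up` when signal(a)/signal(b) meets `fcMin` or the peak is
#' a-exclusive, `down` symmetrically, else `unchanged`. Overlapping peaks
#' within one input are merged first with a warning.
#'
#' @param a,b GRanges with mcols `signal` and peak-id names
#' @param fcMin fold-change threshold (default 3, the retention threshold
#'   applied to peak signal)
#' @return GRanges of merged intervals with mcols `signalA`, `signalB`
#'   (normalized), `foldChange`, `direction`, `exclusive`
#' @export
callDifferentialPeaks <- function(a, b, fcMin = 3) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  if (is.null(names(a))) names(a) <- sprintf("peakA_%05d", seq_along(a))
  if (is.null(names(b))) names(b) <- sprintf("peakB_%05d", seq_along(b))
  a <- .mergeWithin(a, "the first table")
  b <- .mergeWithin(b, "the second table")

  target <- (sum(mcols(a)$signal) + sum(mcols(b)$signal)) / 2
  sigA <- mcols(a)$signal * target / sum(mcols(a)$signal)
  sigB <- mcols(b)$signal * target / sum(mcols(b)$signal)

  merged <- reduce(c(granges(a), granges(b)), ignore.strand = TRUE)
  hitsA <- findOverlaps(merged, a)
  hitsB <- findOverlaps(merged, b)
  sA <- sB <- numeric(length(merged))
  tA <- tapply(sigA[S4Vectors::subjectHits(hitsA)],
               S4Vectors::queryHits(hitsA), sum)
  sA[as.integer(names(tA))] <- tA
  tB <- tapply(sigB[S4Vectors::subjectHits(hitsB)],
               S4Vectors::queryHits(hitsB), sum)
  sB[as.integer(names(tB))] <- tB
  presentA <- seq_along(merged) %in% S4Vectors::queryHits(hitsA)
  presentB <- seq_along(merged) %in% S4Vectors::queryHits(hitsB)

  # carry a stable peak id: first overlapping a-peak name, else b-peak name
  nm <- character(length(merged))
  nmA <- tapply(names(a)[S4Vectors::subjectHits(hitsA)],
                S4Vectors::queryHits(hitsA), function(x) x[1])
  nm[as.integer(names(nmA))] <- nmA
  nmB <- tapply(names(b)[S4Vectors::subjectHits(hitsB)],
                S4Vectors::queryHits(hitsB), function(x) x[1])
  empty <- nm == ""
  nm[empty] <- nmB[as.character(which(empty))]

  ratio <- (sA + 1) / (sB + 1)
  direction <- ifelse(!presentB, "up",
                ifelse(!presentA, "down",
                 ifelse(ratio >= fcMin, "up",
                  ifelse(ratio <= 1 / fcMin, "down", "unchanged"))))
  mcols(merged)$signalA <- sA
  mcols(merged)$signalB <- sB
  mcols(merged)$foldChange <- pmax(ratio, 1 / ratio)
  mcols(merged)$direction <- direction
  mcols(merged)$exclusive <- !(presentA & presentB)
  names(merged) <- nm
  merged
}

#' Annotate peaks with their nearest-TSS gene and a genomic category
#'
#' Each peak is assigned to the gene whose TSS is closest to the peak
#' midpoint (ties broken toward the lexicographically smaller gene id).
#' The category is `promoter` when the midpoint lies within [-1000, +100]
#' of the TSS (strand-aware), else 5'-UTR / 3'-UTR / exon / intron by
#' containment in the assigned gene, else `intergenic`. Peaks on
#' chromosomes absent from the annotation are left unannotated and
#' counted in `metadata(result)$nUnannotated`.
#'
#' @param peaks GRanges (1-based, as read from BED via standard importers)
#' @param annotation data.frame in the [generateTssTable()] layout
#'   (1-based closed coordinates)
#' @param promoterWindow numeric(2): bp window around the TSS treated as
#'   promoter, default c(-1000, 100)
#' @return `peaks` with added mcols `gene`, `category`, `distToTss`
#' @export
annotatePeakRegions <- function(peaks, annotation,
                                promoterWindow = c(-1000, 100)) {
  stopifnot(is(peaks, "GRanges"))
  need <- c("gene", "chrom", "strand", "tss", "txStart", "txEnd")
  if (!all(need %in% names(annotation)))
    stop("annotation lacks columns: ",
         paste(setdiff(need, names(annotation)), collapse = ", "))

  mid0 <- floor((start(peaks) - 1 + end(peaks)) / 2)  # 0-based midpoint
  chr <- as.character(seqnames(peaks))
  gene <- rep(NA_character_, length(peaks))
  category <- rep(NA_character_, length(peaks))
  dist <- rep(NA_real_, length(peaks))

  for (ch in unique(chr)) {
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    idx <- which(chr == ch)
    if (!nrow(ann)) next
    tss0 <- ann$tss - 1L
    ord <- order(ann$gene)  # lexicographic tie-break: scan in gene-id order
    ann <- ann[ord, , drop = FALSE]; tss0 <- tss0[ord]
    d <- abs(outer(mid0[idx], tss0, "-"))
    best <- apply(d, 1, which.min)  # first minimum = smallest gene id
    gene[idx] <- ann$gene[best]
    dist[idx] <- d[cbind(seq_along(idx), best)]

    g <- ann[best, , drop = FALSE]
    rel <- ifelse(g$strand == "+", mid0[idx] - tss0[best],
                  tss0[best] - mid0[idx])
    pos1 <- mid0[idx] + 1L  # 1-based position for containment checks
    inIv <- function(s, e) !is.na(s) & pos1 >= s & pos1 <= e
    inExon <- mapply(function(p, ss, ee) {
      s <- as.integer(strsplit(ss, ",")[[1]])
      e <- as.integer(strsplit(ee, ",")[[1]])
      any(p >= s & p <= e)
    }, pos1, g$exonStarts, g$exonEnds)
    category[idx] <- ifelse(
      rel >= promoterWindow[1] & rel <= promoterWindow[2], "promoter",
      ifelse(inIv(g$utr5Start, g$utr5End), "5UTR",
       ifelse(inIv(g$utr3Start, g$utr3End), "3UTR",
        ifelse(inExon, "exon",
         ifelse(inIv(g$txStart, g$txEnd), "intron", "intergenic")))))
  }
  nUn <- sum(is.na(gene))
  mcols(peaks)$gene <- gene
  mcols(peaks)$category <- category
  mcols(peaks)$distToTss <- dist
  metadata(peaks)$nUnannotated <- nUn
  peaks
}

#' Integrate differential peaks with differential genes into co-regulated sets
#'
#' A peak is co-regulated when it is annotated to a differentially
#' expressed gene and changes in the same direction: up-peaks on up-DEGs
#' form `coUp`, down-peaks on down-DEGs form `coDown`; discordant and
#' neutral pairs are excluded. Unannotated peaks are skipped and counted.
#'
#' @param dePeaks annotated differential peaks (GRanges with mcols
#'   `direction` and `gene`, from [callDifferentialPeaks()] then
#'   [annotatePeakRegions()])
#' @param degs DEG table from [differentialExpressionBulk()]
#' @return a [CoRegulatedSet-class]; skipped-peak counts in
#'   `metadata(peakGeneMap(result))` are recorded as attributes
#' @export
integrateCoRegulation <- function(dePeaks, degs) {
  stopifnot(is(dePeaks, "GRanges"))
  if (is.null(mcols(dePeaks)$gene) || is.null(mcols(dePeaks)$direction))
    stop("dePeaks must carry 'gene' and 'direction' metadata columns")
  degUp <- degs$gene[degs$deg & degs$direction == "up"]
  degDown <- degs$gene[degs$deg & degs$direction == "down"]

  pk <- data.frame(peak = names(dePeaks),
                   peakDirection = mcols(dePeaks)$direction,
                   gene = mcols(dePeaks)$gene,
                   stringsAsFactors = FALSE)
  nSkipped <- sum(is.na(pk$gene))
  pk <- pk[!is.na(pk$gene), , drop = FALSE]

  up <- pk$peakDirection == "up" & pk$gene %in% degUp
  down <- pk$peakDirection == "down" & pk$gene %in% degDown
  mapping <- rbind(
    data.frame(pk[up, , drop = FALSE],
               geneDirection = rep("up", sum(up)),
               stringsAsFactors = FALSE),
    data.frame(pk[down, , drop = FALSE],
               geneDirection = rep("down", sum(down)),
               stringsAsFactors = FALSE))
  rownames(mapping) <- NULL
  attr(mapping, "nUnannotatedSkipped") <- nSkipped
  new("CoRegulatedSet", coUp = pk$peak[up], coDown = pk$peak[down],
      mapping = mapping)
}

#' Motif-set enrichment by the hypergeometric test
#'
#' For each motif, the upper-tail hypergeometric probability of observing
#' at least the foreground's hit count when drawing the foreground from
#' the pooled universe, with BH adjustment across motifs. Fold enrichment
#' is the foreground hit rate over the universe hit rate. Motifs with
#' zero universe hits get p = 1 and fold 0, flagged.
#'
#' @param foreground character peak ids
#' @param background character peak ids; disjoint from the foreground
#'   unless `backgroundIsUniverse = TRUE`, in which case it must be a
#'   superset of the foreground
#' @param occurrences logical peaks x motifs matrix covering all peaks
#' @param backgroundIsUniverse treat `background` as the whole universe
#' @return data.frame per motif: motif, fgHits, universeHits,
#'   foldEnrichment, p, pAdj, zeroUniverse
#' @export
motifEnrichment <- function(foreground, background, occurrences,
                            backgroundIsUniverse = FALSE) {
  occurrences <- as.matrix(occurrences) > 0
  if (!all(foreground %in% rownames(occurrences)))
    stop("foreground peaks missing from the occurrence matrix")
  if (!all(background %in% rownames(occurrences)))
    stop("background peaks missing from the occurrence matrix")
  if (backgroundIsUniverse) {
    if (!all(foreground %in% background))
      stop("with backgroundIsUniverse the background must contain the foreground")
    universe <- unique(background)
  } else {
    if (length(intersect(foreground, background)))
      stop("foreground and background overlap; set backgroundIsUniverse ",
           "if the background is meant as a superset")
    universe <- unique(c(foreground, background))
  }
  foreground <- unique(foreground)
  n <- length(foreground)
  N <- length(universe)

  k <- colSums(occurrences[foreground, , drop = FALSE])
  K <- colSums(occurrences[universe, , drop = FALSE])
  p <- ifelse(K == 0, 1, phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  fold <- ifelse(K == 0, 0, (k / n) / (K / N))
  data.frame(
    motif = colnames(occurrences),
    fgHits = as.integer(k), universeHits = as.integer(K),
    foldEnrichment = fold, p = p, pAdj = p.adjust(p, "BH"),
    zeroUniverse = K == 0,
    stringsAsFactors = FALSE, row.names = NULL)
}
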