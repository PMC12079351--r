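## Synthetic-data generators. Every input the pipeline consumes can be
## produced here with planted ground truth (a SyntheticTruth object), so
## each downstream stage is testable without external accessions. All
## generators are deterministic given (parameters, seed).

#' Generate a single-cell count matrix with planted tissue enrichment
#'
#' Cells are assigned (cluster, tissue) labels from a joint distribution in
#' which each cluster's planted tissue carries `enrichmentFactor` times the
#' weight of the others; with factor 1 the design is exactly null. Counts
#' are negative-binomial with log-normal gene means and cluster-specific
#' marker genes elevated. A handful of `MT-` genes carry the mitochondrial
#' flag used by QC.
#'
#' Clusters are planted round-robin across tissues: with the default seven
#' PSC subclusters and two tissues, four clusters are tumor-enriched and
#' three normal-enriched, mirroring the TPSC/CPSC split.
#'
#' @param nCells number of cells (must be at least 10 x clusters x tissues)
#' @param clusters character vector of cluster names
#' @param tissues character vector of tissue names (at least 2)
#' @param enrichmentFactor multiplicative weight of each cluster's planted
#'   tissue; 1 means no enrichment
#' @param seed integer seed
#' @param nGenes number of genes (5 of them mitochondrial)
#' @param markersPerCluster marker genes elevated per cluster
#' @param markerBoost fold elevation of marker genes in their cluster
#' @param dispersion NB dispersion of counts
#' @param samplesPerTissue donor samples per tissue
#' @return list with `counts` (a [SummarizedExperiment::SummarizedExperiment]
#'   with colData cluster/tissue/sample and rowData `mito`) and `truth`
#'   (a [SyntheticTruth-class])
#' @export
generateSingleCell <- function(nCells = 5000,
                               clusters = c("CCL19_PSC", "PLXDC1_PSC",
                                            "MYH11_PSC", "THBS4_PSC",
                                            "CPSC1", "CPSC2", "CPSC3"),
                               tissues = c("tumor", "normal"),
                               enrichmentFactor = 3,
                               seed = 1L,
                               nGenes = 100,
                               markersPerCluster = 5,
                               markerBoost = 4,
                               dispersion = 0.5,
                               samplesPerTissue = 3) {
  nClust <- length(clusters)
  nTis <- length(tissues)
  if (nClust < 1 || nTis < 2) stop("need at least 1 cluster and 2 tissues")
  if (nCells < 10 * nClust * nTis)
    stop("nCells must be at least 10 x clusters x tissues")
  .checkScalar(enrichmentFactor, "enrichmentFactor", 0, strictLower = TRUE)
  set.seed(as.integer(seed))

  # round-robin planted enrichment: cluster i -> tissue ((i-1) mod nTis) + 1
  enriched <- setNames(tissues[(seq_len(nClust) - 1L) %% nTis + 1L], clusters)

  w <- matrix(1, nClust, nTis, dimnames = list(clusters, tissues))
  for (cl in clusters) w[cl, enriched[cl]] <- enrichmentFactor
  p <- as.vector(w) / sum(w)
  pick <- sample.int(nClust * nTis, nCells, replace = TRUE, prob = p)
  cellCluster <- clusters[(pick - 1L) %% nClust + 1L]
  cellTissue <- tissues[(pick - 1L) %/% nClust + 1L]

  tab <- table(factor(cellCluster, clusters), factor(cellTissue, tissues))
  if (any(tab == 0))
    stop("enrichment too extreme: some cluster has no cells in some tissue; ",
         "increase nCells or reduce enrichmentFactor")

  sampleIds <- paste0(rep(tissues, each = samplesPerTissue), "_s",
                      rep(seq_len(samplesPerTissue), nTis))
  cellSample <- vapply(cellTissue, function(t)
    sample(sampleIds[startsWith(sampleIds, t)], 1L), character(1))

  nMito <- min(5L, nGenes)
  geneIds <- c(paste0("MT-", seq_len(nMito)),
               sprintf("gene_%03d", seq_len(nGenes - nMito)))
  mito <- startsWith(geneIds, "MT-")
  baseMu <- rlnorm(nGenes, meanlog = 0, sdlog = 1)

  # marker blocks: non-mito genes assigned consecutively per cluster
  markerIdx <- vector("list", nClust)
  avail <- which(!mito)
  for (i in seq_len(nClust)) {
    take <- avail[seq_len(min(markersPerCluster, length(avail)))]
    markerIdx[[i]] <- take
    avail <- setdiff(avail, take)
    if (!length(avail)) avail <- which(!mito)  # recycle on tiny matrices
  }

  mu <- matrix(baseMu, nGenes, nCells)
  clIdx <- match(cellCluster, clusters)
  for (i in seq_len(nClust)) {
    cols <- which(clIdx == i)
    if (length(cols)) mu[markerIdx[[i]], cols] <-
        mu[markerIdx[[i]], cols] * markerBoost
  }
  counts <- matrix(rnbinom(nGenes * nCells, mu = mu, size = 1 / dispersion),
                   nGenes, nCells,
                   dimnames = list(geneIds,
                                   sprintf("cell_%05d", seq_len(nCells))))

  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(cluster = cellCluster, tissue = cellTissue,
                        sample = cellSample,
                        row.names = colnames(counts)),
    rowData = DataFrame(mito = mito, row.names = geneIds))
  truth <- new("SyntheticTruth", enrichedClusters = enriched,
               seed = as.integer(seed))
  list(counts = se, truth = truth)
}

#' Generate a two-condition bulk RNA-seq count matrix with planted DEGs
#'
#' Negative-binomial counts for a quiescent-vs-activated contrast with
#' `nReps` replicates per condition (triplicates by default, the design of
#' the FACS-sorted PSC bulk experiment). A fraction `fracDeg` of genes
#' carries a true |log2 fold change| of `effectLog2fc`, split evenly
#' between up and down; library sizes vary 0.5-2 fold.
#'
#' @param nGenes number of genes (0 allowed: empty matrix, empty truth)
#' @param nReps replicates per condition (at least 2)
#' @param fracDeg fraction of genes planted as differential
#' @param effectLog2fc absolute true log2 fold change of planted DEGs
#' @param dispersion NB dispersion (> 0)
#' @param seed integer seed
#' @param baseMeanLog mean of the log-normal gene-mean distribution
#' @return list with `counts` (SummarizedExperiment, colData `condition`)
#'   and `truth` (SyntheticTruth with `degTable`); "up" means higher in
#'   the activated condition
#' @export
generateBulkPair <- function(nGenes = 2000, nReps = 3, fracDeg = 0.1,
                             effectLog2fc = 2, dispersion = 0.05,
                             seed = 1L, baseMeanLog = log(100)) {
  if (nReps < 2) stop("nReps must be at least 2")
  .checkScalar(dispersion, "dispersion", 0, strictLower = TRUE)
  .checkScalar(fracDeg, "fracDeg", 0, 1)
  set.seed(as.integer(seed))

  conds <- rep(c("quiescent", "activated"), each = nReps)
  sampleIds <- paste0(conds, "_r", rep(seq_len(nReps), 2L))
  if (nGenes == 0) {
    counts <- matrix(integer(), 0, 2L * nReps,
                     dimnames = list(character(), sampleIds))
    se <- SummarizedExperiment(
      assays = list(counts = counts),
      colData = DataFrame(condition = conds, row.names = sampleIds))
    return(list(counts = se,
                truth = new("SyntheticTruth", seed = as.integer(seed))))
  }

  geneIds <- sprintf("gene_%05d", seq_len(nGenes))
  baseMu <- rlnorm(nGenes, meanlog = baseMeanLog, sdlog = 1.2)
  nDeg <- round(fracDeg * nGenes)
  degIdx <- if (nDeg > 0) sample.int(nGenes, nDeg) else integer()
  nUp <- ceiling(nDeg / 2)
  upIdx <- degIdx[seq_len(nUp)]
  downIdx <- setdiff(degIdx, upIdx)
  trueLfc <- numeric(nGenes)
  trueLfc[upIdx] <- effectLog2fc
  trueLfc[downIdx] <- -effectLog2fc

  lib <- runif(2L * nReps, 0.5, 2)
  mu <- outer(baseMu, rep(1, 2L * nReps))
  act <- conds == "activated"
  mu[, act] <- mu[, act] * 2^trueLfc
  mu <- sweep(mu, 2, lib, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nGenes, 2L * nReps,
                   dimnames = list(geneIds, sampleIds))

  degTable <- data.frame(
    gene = geneIds[degIdx],
    trueLog2fc = trueLfc[degIdx],
    direction = ifelse(trueLfc[degIdx] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(condition = conds, row.names = sampleIds))
  list(counts = se,
       truth = new("SyntheticTruth", degTable = degTable,
                   seed = as.integer(seed)))
}

#' Build a toy gene annotation table (GTF-lite) for a set of genes
#'
#' Genes are laid out on two chromosomes with 10 kb spacing and alternating
#' strands; each gene has a 2 kb body with two exons, a 5'-UTR and a 3'-UTR
#' of 100 bp at the respective ends. Coordinates are 1-based closed, as in
#' GTF.
#'
#' @param geneIds character vector of gene ids
#' @param spacing distance between consecutive TSS on a chromosome (bp)
#' @param nChrom number of chromosomes to spread genes over
#' @return data.frame with columns gene, chrom, strand, tss, txStart,
#'   txEnd, exonStarts, exonEnds, utr5Start, utr5End, utr3Start, utr3End
#' @export
generateTssTable <- function(geneIds, spacing = 10000, nChrom = 2) {
  n <- length(geneIds)
  if (!n) stop("geneIds must be non-empty")
  chrom <- paste0("chr", (seq_len(n) - 1L) %% nChrom + 1L)
  idxOnChrom <- ave(seq_len(n), chrom, FUN = seq_along)
  tss <- 5000L + (idxOnChrom - 1L) * as.integer(spacing)
  strand <- rep_len(c("+", "-"), n)
  bodyLen <- 2000L
  txStart <- ifelse(strand == "+", tss, tss - bodyLen)
  txEnd <- ifelse(strand == "+", tss + bodyLen, tss)
  # exon1 = first 500 bp from TSS, exon2 = last 800 bp (strand-aware)
  e1s <- ifelse(strand == "+", txStart, txEnd - 499L)
  e1e <- ifelse(strand == "+", txStart + 499L, txEnd)
  e2s <- ifelse(strand == "+", txEnd - 799L, txStart)
  e2e <- ifelse(strand == "+", txEnd, txStart + 799L)
  utr5s <- ifelse(strand == "+", txStart, txEnd - 99L)
  utr5e <- ifelse(strand == "+", txStart + 99L, txEnd)
  utr3s <- ifelse(strand == "+", txEnd - 99L, txStart)
  utr3e <- ifelse(strand == "+", txEnd, txStart + 99L)
  data.frame(
    gene = geneIds, chrom = chrom, strand = strand, tss = tss,
    txStart = txStart, txEnd = txEnd,
    exonStarts = paste(e1s, e2s, sep = ","),
    exonEnds = paste(e1e, e2e, sep = ","),
    utr5Start = utr5s, utr5End = utr5e,
    utr3Start = utr3s, utr3End = utr3e,
    stringsAsFactors = FALSE)
}

#' Generate paired ATAC peak tables with planted co-regulated peaks
#'
#' Two condition-level peak tables (activated vs quiescent) sharing the
#' same intervals but differing in signal. A fraction `fracCoreg` of peaks
#' is planted in the promoter window of a planted DEG from `bulkTruth`
#' with a signal fold change of `plantedFold` (>= 3) in the matching
#' direction; the remainder cycles through distractors: neutral peaks at
#' non-DEG promoters, direction-discordant peaks at DEG promoters, and
#' neutral intergenic peaks. Planted peaks are split between up- and
#' down-DEGs as the DEG table is, so equal-total normalization preserves
#' the planted folds.
#'
#' @param bulkTruth SyntheticTruth from [generateBulkPair()] (needs a
#'   non-empty degTable whenever `fracCoreg > 0`)
#' @param nPeaks number of peaks
#' @param fracCoreg fraction of peaks planted as co-regulated
#' @param tssTable annotation from [generateTssTable()]; must cover the
#'   genes of `bulkTruth` and the distractor genes
#' @param seed integer seed
#' @param plantedFold signal fold change of planted differential peaks
#' @return list with `activated` and `quiescent` ([GenomicRanges::GRanges]
#'   with mcols `signal`, names = peak ids) and `truth` (SyntheticTruth
#'   with `coregPeaks`)
#' @export
generateAtacPeaks <- function(bulkTruth, nPeaks = 1000, fracCoreg = 0.3,
                              tssTable, seed = 1L, plantedFold = 5) {
  stopifnot(is(bulkTruth, "SyntheticTruth"))
  deg <- bulkTruth@degTable
  if (fracCoreg > 0 && nrow(deg) == 0)
    stop("bulkTruth contains no planted DEGs but fracCoreg > 0")
  if (nrow(deg) && !all(deg$gene %in% tssTable$gene))
    stop("tssTable must cover all genes in bulkTruth")
  .checkScalar(fracCoreg, "fracCoreg", 0, 1)
  set.seed(as.integer(seed))

  nCoreg <- round(fracCoreg * nPeaks)
  nDist <- nPeaks - nCoreg
  # promoter slots: peak midpoints at TSS-800, TSS-300, TSS+50 (width 200)
  slotOffsets <- c(-800L, -300L, 50L)
  maxSlots <- length(slotOffsets)
  if (nCoreg > maxSlots * nrow(deg) && nrow(deg))
    stop("too many co-regulated peaks for the available DEG promoters")

  peakId <- sprintf("peak_%05d", seq_len(nPeaks))
  chrom <- character(nPeaks); pstart <- integer(nPeaks)
  sigAct <- numeric(nPeaks); sigQui <- numeric(nPeaks)
  base <- rgamma(nPeaks, shape = 4, rate = 0.2) + 5

  promoterInterval <- function(geneRow, slot) {
    # 0-based half-open interval of width 200 centred at the slot offset
    g <- tssTable[geneRow, ]
    off <- slotOffsets[slot]
    mid <- if (g$strand == "+") g$tss - 1L + off else g$tss - 1L - off
    c(mid - 100L, g$chrom)
  }

  truthRows <- list()
  usedSlots <- new.env(parent = emptyenv())
  nextSlot <- function(gene) {
    k <- if (is.null(usedSlots[[gene]])) 1L else usedSlots[[gene]] + 1L
    usedSlots[[gene]] <- k
    k
  }

  nonDegGenes <- setdiff(tssTable$gene, deg$gene)
  interOffset <- 0L
  lastTssByChrom <- tapply(tssTable$tss, tssTable$chrom, max)

  # planted co-regulated peaks: cycle through DEGs so both directions are hit
  degOrder <- if (nrow(deg)) rep_len(sample.int(nrow(deg)), max(nCoreg, 0L)) else integer()
  for (i in seq_len(nPeaks)) {
    if (i <= nCoreg) {
      d <- deg[degOrder[i], ]
      slot <- nextSlot(d$gene)
      if (slot > maxSlots) stop("promoter slots exhausted for gene ", d$gene)
      iv <- promoterInterval(match(d$gene, tssTable$gene), slot)
      pstart[i] <- as.integer(iv[1]); chrom[i] <- iv[2]
      if (d$direction == "up") {
        sigAct[i] <- base[i] * plantedFold; sigQui[i] <- base[i]
      } else {
        sigAct[i] <- base[i]; sigQui[i] <- base[i] * plantedFold
      }
      truthRows[[length(truthRows) + 1L]] <-
        data.frame(peak = peakId[i], direction = d$direction,
                   gene = d$gene, stringsAsFactors = FALSE)
    } else {
      kind <- c("neutral_gene", "discordant", "neutral_intergenic")[
        (i - nCoreg - 1L) %% 3L + 1L]
      if (kind == "neutral_gene" && length(nonDegGenes)) {
        g <- sample(nonDegGenes, 1L)
        slot <- nextSlot(g)
        if (slot > maxSlots) { kind <- "neutral_intergenic" } else {
          iv <- promoterInterval(match(g, tssTable$gene), slot)
          pstart[i] <- as.integer(iv[1]); chrom[i] <- iv[2]
          sigAct[i] <- base[i]; sigQui[i] <- base[i]
        }
      }
      if (kind == "discordant" && nrow(deg)) {
        d <- deg[sample.int(nrow(deg), 1L), ]
        slot <- nextSlot(d$gene)
        if (slot > maxSlots) { kind <- "neutral_intergenic" } else {
          iv <- promoterInterval(match(d$gene, tssTable$gene), slot)
          pstart[i] <- as.integer(iv[1]); chrom[i] <- iv[2]
          # opposite direction to the gene's planted change
          if (d$direction == "up") {
            sigAct[i] <- base[i]; sigQui[i] <- base[i] * plantedFold
          } else {
            sigAct[i] <- base[i] * plantedFold; sigQui[i] <- base[i]
          }
        }
      }
      if (kind == "neutral_intergenic" || chrom[i] == "") {
        ch <- names(lastTssByChrom)[(interOffset %% length(lastTssByChrom)) + 1L]
        pstart[i] <- as.integer(lastTssByChrom[[ch]] + 50000L +
                                  (interOffset %/% length(lastTssByChrom)) * 1000L)
        chrom[i] <- ch
        sigAct[i] <- base[i]; sigQui[i] <- base[i]
        interOffset <- interOffset + 1L
      }
    }
  }

  gr <- GRanges(chrom, IRanges(start = pstart + 1L, width = 200L))
  names(gr) <- peakId
  act <- gr; mcols(act)$signal <- sigAct
  qui <- gr; mcols(qui)$signal <- sigQui
  coreg <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(peak = character(), direction = character(),
               gene = character(), stringsAsFactors = FALSE)
  truth <- new("SyntheticTruth", degTable = deg, coregPeaks = coreg,
               seed = as.integer(seed))
  list(activated = act, quiescent = qui, truth = truth)
}

#' Generate a cell-type reference signature matrix
#'
#' Log-normal baseline expression with a block of boosted marker genes per
#' cell type; distinct marker blocks guarantee full column rank.
#'
#' @param nGenes number of genes
#' @param cellTypes character vector of cell-type names
#' @param seed integer seed
#' @param markersPerType marker genes per type
#' @param markerBoost fold elevation of markers in their own type
#' @return genes x cell-types non-negative matrix
#' @export
generateReference <- function(nGenes = 150, cellTypes, seed = 1L,
                              markersPerType = 6, markerBoost = 8) {
  k <- length(cellTypes)
  if (k < 2) stop("need at least 2 cell types")
  if (nGenes < markersPerType * k)
    stop("nGenes too small for distinct marker blocks")
  set.seed(as.integer(seed))
  geneIds <- sprintf("gene_%03d", seq_len(nGenes))
  ref <- matrix(rlnorm(nGenes * k, meanlog = 2, sdlog = 0.5), nGenes, k,
                dimnames = list(geneIds, cellTypes))
  for (i in seq_len(k)) {
    idx <- (i - 1L) * markersPerType + seq_len(markersPerType)
    ref[idx, i] <- ref[idx, i] * markerBoost
  }
  ref
}

#' Generate spatial spots as abundance-weighted mixtures of reference profiles
#'
#' True per-spot abundances are Dirichlet; within each planted niche set
#' the member types share a latent log-normal spatial factor so their
#' across-spot correlation is high in truth, and the first niche set's
#' factor is concentrated in the tumor-boundary (Bdy) region. Spot
#' expression is the abundance-weighted mixture of column-normalized
#' reference profiles times a library size, plus Gaussian noise truncated
#' at zero. Regions are concentric coordinate bands: core = Mal, ring =
#' Bdy, outside = nMal.
#'
#' @param nSpots number of spots
#' @param cellTypes character vector of cell types
#' @param nicheSets list of character vectors; each a planted co-localized
#'   set (members must be in `cellTypes`)
#' @param reference genes x cell-types signature matrix; generated with
#'   [generateReference()] when `NULL`
#' @param noiseSd standard deviation of additive Gaussian expression noise
#' @param seed integer seed
#' @param librarySize total expression per spot before noise
#' @param nicheStrength sd of the shared log-normal latent factor
#' @return list with `spots` (SummarizedExperiment, assay `expression`,
#'   colData region + x/y), `abundance` (true [AbundanceMatrix-class]),
#'   `reference`, and `truth` (SyntheticTruth with `nicheSets`)
#' @export
generateSpatial <- function(nSpots = 400,
                            cellTypes = c("PLXDC1_TPSC", "myCAF", "iCAF",
                                          "Malignant", "Ductal", "Tcell",
                                          "Myeloid", "Endothelial"),
                            nicheSets = list(c("PLXDC1_TPSC", "myCAF")),
                            reference = NULL, noiseSd = 1, seed = 1L,
                            librarySize = 1000, nicheStrength = 1) {
  k <- length(cellTypes)
  for (s in nicheSets)
    if (!all(s %in% cellTypes))
      stop("niche set names a cell type absent from cellTypes: ",
           paste(setdiff(s, cellTypes), collapse = ", "))
  set.seed(as.integer(seed))
  if (is.null(reference))
    reference <- generateReference(cellTypes = cellTypes,
                                   seed = as.integer(seed) + 1L)
  if (any(reference < 0)) stop("reference must be non-negative")
  if (!all(cellTypes %in% colnames(reference)))
    stop("reference must have one profile per cell type")
  reference <- reference[, cellTypes, drop = FALSE]

  side <- ceiling(sqrt(nSpots))
  gx <- ((seq_len(nSpots) - 1L) %% side + 0.5) / side
  gy <- ((seq_len(nSpots) - 1L) %/% side + 0.5) / side
  r <- sqrt((gx - 0.5)^2 + (gy - 0.5)^2)
  region <- ifelse(r <= 0.25, "Mal", ifelse(r <= 0.40, "Bdy", "nMal"))

  g <- matrix(rgamma(nSpots * k, shape = 1, rate = 1), nSpots, k,
              dimnames = list(sprintf("spot_%04d", seq_len(nSpots)),
                              cellTypes))
  # niche members: low-CV gammas scaled by a shared log-normal factor, so
  # the shared factor (not member-specific noise) dominates their spread;
  # the first set's factor is concentrated in the Bdy region
  for (j in seq_along(nicheSets)) {
    f <- exp(rnorm(nSpots, 0, nicheStrength))
    if (j == 1L) f <- f * ifelse(region == "Bdy", 2.5, 0.5)
    members <- nicheSets[[j]]
    g[, members] <- matrix(rgamma(nSpots * length(members), 8, 8),
                           nSpots, length(members)) * f
  }
  ab <- g / rowSums(g)

  refNorm <- sweep(reference, 2, colSums(reference), "/")
  expr <- refNorm %*% t(ab) * librarySize
  if (noiseSd > 0)
    expr <- pmax(expr + rnorm(length(expr), 0, noiseSd), 0)
  colnames(expr) <- rownames(ab)

  se <- SummarizedExperiment(
    assays = list(expression = expr),
    colData = DataFrame(x = gx, y = gy, region = region,
                        row.names = rownames(ab)))
  abundanceObj <- new("AbundanceMatrix", abundance = ab,
                      coords = cbind(x = gx, y = gy), region = region)
  truth <- new("SyntheticTruth", nicheSets = nicheSets,
               seed = as.integer(seed))
  list(spots = se, abundance = abundanceObj, reference = reference,
       truth = truth)
}

#' Generate a survival table under proportional hazards from a planted score
#'
#' A continuous score is Uniform(0, 1); event times are exponential with
#' the hazard multiplied by `trueHr` when the score exceeds its
#' `cutQuantile` quantile. Independent exponential censoring is calibrated
#' (by solving the competing-exponentials censoring probability) to hit
#' `censorRate`.
#'
#' @param nPatients number of patients
#' @param trueHr hazard ratio of the high-score group (> 0)
#' @param cutQuantile quantile of the score at which the hazard changes
#' @param censorRate target fraction censored, in [0, 1)
#' @param seed integer seed
#' @param baseHazard baseline exponential hazard (per month)
#' @return list with `survival` (data.frame patient/time/event/score) and
#'   `truth` (SyntheticTruth with `survivalEffect`)
#' @export
generateSurvival <- function(nPatients = 400, trueHr = 3, cutQuantile = 0.5,
                             censorRate = 0.2, seed = 1L, baseHazard = 0.05) {
  .checkScalar(trueHr, "trueHr", 0, strictLower = TRUE)
  .checkScalar(cutQuantile, "cutQuantile", 0, 1,
               strictLower = TRUE, strictUpper = TRUE)
  if (!is.numeric(censorRate) || censorRate < 0 || censorRate >= 1)
    stop("censorRate must be in [0, 1)")
  set.seed(as.integer(seed))

  score <- runif(nPatients)
  cut <- as.numeric(quantile(score, cutQuantile))
  high <- score > cut
  rate <- baseHazard * ifelse(high, trueHr, 1)
  eventTime <- rexp(nPatients, rate)

  if (censorRate > 0) {
    pHigh <- mean(high)
    censProb <- function(mu)
      pHigh * mu / (baseHazard * trueHr + mu) +
        (1 - pHigh) * mu / (baseHazard + mu) - censorRate
    mu <- uniroot(censProb, c(1e-8, 1e4))$root
    censTime <- rexp(nPatients, mu)
    time <- pmin(eventTime, censTime)
    event <- as.integer(eventTime <= censTime)
  } else {
    time <- eventTime
    event <- rep(1L, nPatients)
  }

  surv <- data.frame(
    patient = sprintf("pt_%04d", seq_len(nPatients)),
    time = time, event = event, score = score,
    stringsAsFactors = FALSE)
  truth <- new("SyntheticTruth",
               survivalEffect = c(hr = trueHr, cutQuantile = cutQuantile),
               seed = as.integer(seed))
  list(survival = surv, truth = truth)
}

#' Generate a peak-by-motif occurrence matrix with planted enrichment
#'
#' Bernoulli occurrences at `baseRate`, except the first `nEnriched`
#' motifs occur at `enrichedRate` within `enrichedPeaks` — a planted
#' foreground enrichment for the hypergeometric test.
#'
#' @param peakIds character vector of peak ids (matrix rows)
#' @param nMotifs number of motifs
#' @param enrichedPeaks peak ids forming the enriched foreground
#' @param nEnriched number of motifs planted as enriched
#' @param baseRate background occurrence probability
#' @param enrichedRate occurrence probability of enriched motifs within
#'   `enrichedPeaks`
#' @param seed integer seed
#' @return logical peaks x motifs matrix
#' @export
generateMotifOccurrences <- function(peakIds, nMotifs = 50,
                                     enrichedPeaks = character(),
                                     nEnriched = 1, baseRate = 0.1,
                                     enrichedRate = 0.6, seed = 1L) {
  set.seed(as.integer(seed))
  if (!all(enrichedPeaks %in% peakIds))
    stop("enrichedPeaks must be a subset of peakIds")
  occ <- matrix(runif(length(peakIds) * nMotifs) < baseRate,
                length(peakIds), nMotifs,
                dimnames = list(peakIds,
                                sprintf("motif_%02d", seq_len(nMotifs))))
  if (length(enrichedPeaks) && nEnriched > 0) {
    rows <- match(enrichedPeaks, peakIds)
    for (m in seq_len(min(nEnriched, nMotifs)))
      occ[rows, m] <- runif(length(rows)) < enrichedRate
  }
  occ
}
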