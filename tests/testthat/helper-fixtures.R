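suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(GenomicRanges)
})

## Small SummarizedExperiment from a plain matrix, with optional metadata.
makeSE <- function(counts, cluster = NULL, tissue = NULL, condition = NULL,
                   mito = NULL) {
  cd <- DataFrame(row.names = colnames(counts))
  if (!is.null(cluster)) cd$cluster <- cluster
  if (!is.null(tissue)) cd$tissue <- tissue
  if (!is.null(condition)) cd$condition <- condition
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(mito)) rd$mito <- mito
  SummarizedExperiment(assays = list(counts = counts),
                       colData = cd, rowData = rd)
}

## Peak GRanges from vectors, with signal and ids.
makePeaks <- function(chrom, start0, end0, signal,
                      ids = sprintf("pk%02d", seq_along(start0))) {
  gr <- GRanges(chrom, IRanges(start = start0 + 1L, end = end0))
  names(gr) <- ids
  mcols(gr)$signal <- signal
  gr
}

## Independent Wilcoxon rank-sum p-value: normal approximation with tie
## correction and continuity correction, the large-sample two-sided form.
bruteWilcoxP <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- W - mu
  corr <- sign(z) * 0.5
  z <- (z - corr) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

## Independent log-rank O/E/V via survival::survdiff (used as the oracle
## against the package's from-first-principles implementation).
survdiffOracle <- function(time, event, group) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = sd$chisq, obs = sd$obs, exp = sd$exp)
}
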