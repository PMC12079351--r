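## Plain-text readers/writers for the formats the pipeline consumes and
## emits: MTX + TSV metadata for count matrices, BED + signal for peaks,
## GMT gene sets, CSV survival tables, TSV result tables, JSON truth.

#' Read a count matrix from MTX plus row/column metadata TSVs
#'
#' @param mtxFile MatrixMarket file of counts (genes x observations)
#' @param genesFile TSV with a `gene` column (and optional `mito` flag)
#' @param obsFile TSV of per-observation metadata; first column taken as
#'   observation id
#' @return SummarizedExperiment with assay `counts`
#' @export
readCountMatrix <- function(mtxFile, genesFile, obsFile) {
  m <- as.matrix(Matrix::readMM(mtxFile))
  genes <- read.delim(genesFile, stringsAsFactors = FALSE)
  obs <- read.delim(obsFile, stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m) || nrow(obs) != ncol(m))
    stop("metadata dimensions do not match the matrix")
  rownames(m) <- genes$gene
  colnames(m) <- obs[[1]]
  rd <- DataFrame(genes[, setdiff(names(genes), "gene"), drop = FALSE],
                  row.names = genes$gene)
  cd <- DataFrame(obs[, -1, drop = FALSE], row.names = obs[[1]])
  SummarizedExperiment(assays = list(counts = m), rowData = rd,
                       colData = cd)
}

#' Write a count matrix as MTX plus row/column metadata TSVs
#'
#' @param se SummarizedExperiment
#' @param prefix path prefix; writes `<prefix>.mtx`, `<prefix>.genes.tsv`,
#'   `<prefix>.obs.tsv`
#' @return invisibly, the three file paths
#' @export
writeCountMatrix <- function(se, prefix) {
  m <- .assayMatrix(se)
  paths <- paste0(prefix, c(".mtx", ".genes.tsv", ".obs.tsv"))
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), paths[1])
  genes <- data.frame(gene = rownames(m),
                      as.data.frame(rowData(se)),
                      stringsAsFactors = FALSE)
  write.table(genes, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  obs <- data.frame(obs = colnames(m),
                    as.data.frame(colData(se)),
                    stringsAsFactors = FALSE)
  write.table(obs, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' @param file GMT path
#' @return named list of character vectors
#' @export
readGmt <- function(file) fgsea::gmtPathways(file)

#' Write gene sets to a GMT file
#'
#' @param geneSets named list of character vectors
#' @param file output path
#' @export
writeGmt <- function(geneSets, file) {
  lines <- vapply(names(geneSets), function(n)
    paste(c(n, "synthetic", geneSets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Write a peak table as BED (0-based half-open) with a signal column
#'
#' Columns: chrom, start, end, name, signal. Further metadata columns are
#' appended after the signal.
#'
#' @param peaks GRanges with mcols `signal` (at least)
#' @param file output path
#' @export
writePeakBed <- function(peaks, file) {
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = if (is.null(names(peaks)))
      sprintf("peak_%05d", seq_along(peaks)) else names(peaks),
    as.data.frame(mcols(peaks)),
    stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a peak table from BED (0-based half-open) with a signal column
#'
#' @param file BED path as written by [writePeakBed()]
#' @param extraCols names for metadata columns after the signal, if any
#' @return GRanges with mcols `signal` and peak-id names
#' @export
readPeakBed <- function(file, extraCols = character()) {
  df <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "signal", extraCols)[
    seq_len(ncol(df))]
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end))
  names(gr) <- df$name
  for (cc in c("signal", extraCols)) mcols(gr)[[cc]] <- df[[cc]]
  gr
}

#' Read a survival table from CSV
#'
#' @param file CSV with columns time, event and at least one score column
#' @return data.frame
#' @export
readSurvivalCsv <- function(file) {
  surv <- read.csv(file, stringsAsFactors = FALSE)
  .checkSurvTable(surv)
  surv
}

#' Write a survival table to CSV
#' @param surv data.frame with time/event/score columns
#' @param file output path
#' @export
writeSurvivalCsv <- function(surv, file) {
  write.csv(surv, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Serialize a SyntheticTruth to JSON
#' @param truth a [SyntheticTruth-class]
#' @param file output path
#' @export
writeTruthJson <- function(truth, file) {
  stopifnot(is(truth, "SyntheticTruth"))
  jsonlite::write_json(list(
    enrichedClusters = as.list(truth@enrichedClusters),
    degTable = truth@degTable,
    coregPeaks = truth@coregPeaks,
    nicheSets = truth@nicheSets,
    survivalEffect = as.list(truth@survivalEffect),
    seed = truth@seed
  ), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
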