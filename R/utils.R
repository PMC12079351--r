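#' Log-normalize a count matrix
#'
#' Counts-per-10k followed by `log1p`, the normalization used ahead of
#' marker testing and signature scoring. Columns with zero total are left
#' at zero.
#'
#' @param counts genes x observations matrix of non-negative counts
#' @param scaleFactor library-size target (default 1e4)
#' @return matrix of log-normalized expression, same dimensions
#' @export
logNormalizeCounts <- function(counts, scaleFactor = 1e4) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  log1p(sweep(counts, 2, tot, "/") * scaleFactor)
}

## Extract the first assay as a dense base matrix, accepting either a
## SummarizedExperiment or a plain/sparse matrix.
.assayMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x, 1L)
  as.matrix(x)
}

## Observation metadata as a data.frame from an SE or a data.frame.
.obsMeta <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(as.data.frame(SummarizedExperiment::colData(x)))
  as.data.frame(x)
}

.checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                         strictLower = FALSE, strictUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number")
  if (if (strictLower) x <= lower else x < lower)
    stop(name, " must be ", if (strictLower) "> " else ">= ", lower)
  if (if (strictUpper) x >= upper else x > upper)
    stop(name, " must be ", if (strictUpper) "< " else "<= ", upper)
  invisible(x)
}
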