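## Spatial stage: reference-based spot deconvolution (non-negative least
## squares), PSC spot assignment, region-stratified abundance, pairwise
## co-localization, NMF niche factorization, and abundance-abundance
## correlation across bulk samples.

#' Deconvolve spot (or bulk) expression into cell-type proportions
#'
#' Per observation, a non-negative least-squares fit of its expression to
#' the reference signature profiles on the shared genes, both normalized
#' to equal totals (each column scaled to sum 1). Coefficients are
#' rescaled to proportions; the per-spot residual norm is reported. This
#' is a deterministic linear stand-in with the same contract as
#' probabilistic deconvolution: an abundance per spot and cell type.
#'
#' @param spotExpr SummarizedExperiment (assay `expression` or `counts`)
#'   or genes x spots matrix
#' @param reference genes x cell-types signature matrix (at least 2 types)
#' @return an [AbundanceMatrix-class]; residual norms in
#'   `attr(abundance(result), "residual")`; coordinates/region carried
#'   over from the input colData when present
#' @export
deconvolve <- function(spotExpr, reference) {
  expr <- .assayMatrix(spotExpr)
  if (ncol(reference) < 2) stop("need at least 2 cell types")
  shared <- intersect(rownames(expr), rownames(reference))
  if (length(shared) < ncol(reference))
    stop("too few shared genes between expression and reference")
  expr <- expr[shared, , drop = FALSE]
  ref <- as.matrix(reference)[shared, , drop = FALSE]

  qrRef <- qr(ref)
  if (qrRef$rank < ncol(ref)) {
    dropped <- colnames(ref)[-sort(qrRef$pivot[seq_len(qrRef$rank)])]
    stop("reference is rank-deficient; collinear profiles: ",
         paste(dropped, collapse = ", "))
  }

  refN <- sweep(ref, 2, colSums(ref), "/")
  tot <- colSums(expr)
  tot[tot == 0] <- 1
  exprN <- sweep(expr, 2, tot, "/")

  nSpots <- ncol(exprN)
  ab <- matrix(0, nSpots, ncol(ref),
               dimnames = list(colnames(exprN), colnames(ref)))
  resid <- numeric(nSpots)
  for (i in seq_len(nSpots)) {
    fit <- pracma::lsqnonneg(refN, exprN[, i])
    coef <- fit$x
    s <- sum(coef)
    ab[i, ] <- if (s > 0) coef / s else 0
    resid[i] <- sqrt(fit$resid.norm)
  }
  attr(ab, "residual") <- resid

  coords <- matrix(numeric(), 0, 2)
  region <- character()
  if (is(spotExpr, "SummarizedExperiment")) {
    cd <- as.data.frame(colData(spotExpr))
    if (all(c("x", "y") %in% names(cd)))
      coords <- cbind(x = cd$x, y = cd$y)
    if ("region" %in% names(cd)) region <- as.character(cd$region)
  }
  new("AbundanceMatrix", abundance = ab, coords = coords, region = region)
}

#' Assign spots to PSC subclusters by the 10 percent + argmax rule
#'
#' A spot is assigned iff the summed abundance of the PSC subclusters
#' strictly exceeds `threshold` (default 10 percent); the label is the
#' subcluster with the highest proportion, ties broken toward the
#' lexicographically smallest label and flagged.
#'
#' @param a an [AbundanceMatrix-class]
#' @param pscTypes character vector of PSC subcluster columns
#' @param threshold minimal total PSC abundance (strict >)
#' @return data.frame per spot: spot, pscTotal, assigned (label or `NA`),
#'   tie
#' @export
assignPscSpots <- function(a, pscTypes, threshold = 0.10) {
  stopifnot(is(a, "AbundanceMatrix"))
  if (!length(pscTypes)) stop("pscTypes must be non-empty")
  ab <- abundance(a)
  if (!all(pscTypes %in% colnames(ab)))
    stop("pscTypes absent from the abundance matrix: ",
         paste(setdiff(pscTypes, colnames(ab)), collapse = ", "))
  sub <- ab[, sort(pscTypes), drop = FALSE]  # sorted: argmax tie-break
  total <- rowSums(sub)
  best <- max.col(sub, ties.method = "first")
  tie <- apply(sub, 1, function(r) sum(r == max(r)) > 1)
  assigned <- ifelse(total > threshold, colnames(sub)[best], NA_character_)
  data.frame(
    spot = rownames(ab), pscTotal = total, assigned = assigned,
    tie = tie & !is.na(assigned),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Region-stratified abundance of one cell type with rank-sum tests
#'
#' Splits a cell type's spot abundances by region label and compares each
#' region pair with a two-sided Wilcoxon rank-sum test, BH-adjusted over
#' the pairs. Regions with fewer than 3 spots are skipped.
#'
#' @param a an [AbundanceMatrix-class] with region labels
#' @param cellType the abundance column to stratify
#' @return list with `values` (abundances split by region) and `tests`
#'   (data.frame regionA, regionB, p, pAdj)
#' @export
regionAbundance <- function(a, cellType) {
  stopifnot(is(a, "AbundanceMatrix"))
  region <- spotRegions(a)
  if (!length(region)) stop("abundance matrix carries no region labels")
  ab <- abundance(a)
  if (!cellType %in% colnames(ab)) stop("unknown cell type ", cellType)
  values <- split(ab[, cellType], region)
  if (length(values) < 2)
    stop("need at least 2 regions to compare")
  usable <- names(values)[vapply(values, length, integer(1)) >= 3]
  pairs <- if (length(usable) >= 2) utils::combn(sort(usable), 2) else
    matrix(character(), 2, 0)
  tests <- data.frame(
    regionA = pairs[1, ], regionB = pairs[2, ],
    p = apply(pairs, 2, function(pr)
      suppressWarnings(
        wilcox.test(values[[pr[1]]], values[[pr[2]]])$p.value)),
    stringsAsFactors = FALSE, row.names = NULL)
  tests$pAdj <- p.adjust(tests$p, "BH")
  list(values = values, tests = tests)
}

#' Pairwise co-localization of cell types across spots
#'
#' Pearson correlation of per-spot proportions for every cell-type pair.
#' Zero-variance columns give missing entries (flagged), not zeros.
#'
#' @param a an [AbundanceMatrix-class] with at least 3 spots
#' @return symmetric correlation matrix with attributes `nSpots` and
#'   `constantTypes`
#' @export
colocalization <- function(a) {
  stopifnot(is(a, "AbundanceMatrix"))
  ab <- abundance(a)
  if (nrow(ab) < 3) stop("need at least 3 spots")
  sds <- apply(ab, 2, sd)
  cc <- suppressWarnings(cor(ab))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  attr(cc, "nSpots") <- nrow(ab)
  attr(cc, "constantTypes") <- colnames(ab)[sds == 0]
  cc
}

#' Non-negative matrix factorization of an abundance matrix into niches
#'
#' Multiplicative-update NMF minimizing squared reconstruction error,
#' seeded uniform-random initialization scaled by the matrix mean, run to
#' 500 iterations or a relative objective change below 1e-6. Factors are
#' sorted by total spot loading; the objective is checked to be
#' non-increasing every 50 iterations.
#'
#' @param a an [AbundanceMatrix-class] (or spots x types matrix)
#' @param k number of factors (default 6)
#' @param seed integer seed for the initialization
#' @param maxIter iteration cap
#' @param tol relative objective-change tolerance
#' @return a [NicheFactors-class]
#' @export
nmfNiches <- function(a, k = 6, seed = 1L, maxIter = 500, tol = 1e-6) {
  A <- if (is(a, "AbundanceMatrix")) abundance(a) else as.matrix(a)
  if (k > min(dim(A)))
    stop("k exceeds the rank bound min(spots, types) = ", min(dim(A)))
  set.seed(as.integer(seed))
  eps <- 1e-12
  scale0 <- sqrt(mean(A) / k)
  W <- matrix(runif(nrow(A) * k), nrow(A), k) * scale0
  H <- matrix(runif(k * ncol(A)), k, ncol(A)) * scale0

  objective <- numeric(0)
  obj <- function() sum((A - W %*% H)^2)
  prev <- obj()
  for (it in seq_len(maxIter)) {
    H <- H * (t(W) %*% A) / (t(W) %*% W %*% H + eps)
    W <- W * (A %*% t(H)) / (W %*% H %*% t(H) + eps)
    cur <- obj()
    objective <- c(objective, cur)
    if (it %% 50 == 0 && cur > prev + 1e-8)
      stop("NMF objective increased; numerical failure")
    if (abs(prev - cur) <= tol * max(prev, eps)) break
    prev <- cur
  }
  ord <- order(colSums(W), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  dimnames(W) <- list(rownames(A), paste0("factor_", seq_len(k)))
  dimnames(H) <- list(paste0("factor_", seq_len(k)), colnames(A))
  relErr <- sqrt(sum((A - W %*% H)^2)) / max(sqrt(sum(A^2)), eps)
  new("NicheFactors", spotLoadings = W, typeWeights = H,
      reconError = relErr, objective = objective)
}

#' Correlation between two cell types' abundances across bulk samples
#'
#' Pearson correlation (with two-sided p) of two abundance columns across
#' samples, as used to relate PSC subcluster infiltration to CAF
#' subclusters across bulk cohorts.
#'
#' @param bulkAbundance an [AbundanceMatrix-class] over samples
#' @param typeA,typeB cell-type column names
#' @return list with `r`, `p`, `n`
#' @export
abundanceCorrelation <- function(bulkAbundance, typeA, typeB) {
  stopifnot(is(bulkAbundance, "AbundanceMatrix"))
  ab <- abundance(bulkAbundance)
  if (!all(c(typeA, typeB) %in% colnames(ab)))
    stop("unknown cell type(s)")
  if (nrow(ab) < 3) stop("need at least 3 samples")
  if (typeA == typeB)
    return(list(r = 1, p = 0, n = nrow(ab)))
  ct <- cor.test(ab[, typeA], ab[, typeB], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(ab))
}
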