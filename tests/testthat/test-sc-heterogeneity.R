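test_that("QC filter matches per-cell brute-force evaluation", {
  # 12-cell fixture with known attributes, evaluated cell by cell
  set.seed(1)
  nGenes <- 40
  counts <- matrix(0L, nGenes, 12,
                   dimnames = list(c(paste0("MT-", 1:2),
                                     sprintf("g%02d", 1:(nGenes - 2))),
                                   sprintf("c%02d", 1:12)))
  mito <- startsWith(rownames(counts), "MT-")
  # craft cells: vary detected genes, UMI, mito fraction
  fill <- function(j, nDet, umi, mitoFrac) {
    det <- sample(which(!mito), nDet)
    counts[det, j] <<- as.integer(rmultinom(1, round(umi * (1 - mitoFrac)),
                                            rep(1, nDet)))
    counts[1, j] <<- as.integer(round(umi * mitoFrac))
  }
  fill(1, 20, 100, 0.05);  fill(2, 4, 100, 0.05)   # low detected
  fill(3, 20, 100, 0.30);  fill(4, 30, 500, 0.10)
  fill(5, 20, 5, 0)                                # low UMI
  fill(6, 35, 2000, 0.14); fill(7, 20, 100, 0.16)
  fill(8, 20, 100, 0.15);  fill(9, 10, 50, 0.5)
  fill(10, 25, 300, 0);    fill(12, 15, 80, 0.02)  # cell 11 all-zero
  se <- makeSE(counts, mito = mito)

  res <- qcFilterCells(se, minGenes = 10, maxGenes = 32, minUmi = 50,
                       maxUmi = 1000, maxMito = 0.15)

  detected <- colSums(counts > 0)
  umi <- colSums(counts)
  mf <- ifelse(umi > 0, colSums(counts[mito, ]) / umi, 1)
  keepExpected <- colnames(counts)[
    detected >= 10 & detected <= 32 & umi >= 50 & umi <= 1000 & mf <= 0.15]
  expect_identical(colnames(res), keepExpected)
  expect_false("c11" %in% colnames(res))     # all-zero cell removed
  expect_equal(nrow(res), nrow(se))          # gene set unchanged
  expect_named(metadata(res)$qcLog,
               c("input", "kept", "failedGenes", "failedUmi", "failedMito"))

  expect_error(qcFilterCells(makeSE(counts)), "mito")
  expect_warning(qcFilterCells(se, minUmi = 1e9), "no cell passed")
})

test_that("marker detection finds a perfectly specific gene and skips flat ones", {
  set.seed(2)
  n <- 25
  counts <- matrix(rpois(60 * 2 * n, 2), 60, 2 * n,
                   dimnames = list(sprintf("g%02d", 1:60),
                                   sprintf("c%02d", 1:(2 * n))))
  cl <- rep(c("A", "B"), each = n)
  counts["g01", cl == "A"] <- rpois(n, 20) + 1L  # 100% in A, elevated
  counts["g01", cl == "B"] <- 0L
  se <- makeSE(counts, cluster = cl)
  mk <- findMarkers(se)

  topA <- mk[mk$cluster == "A", ][1, ]
  expect_identical(topA$gene, "g01")
  expect_lt(topA$pAdj, 0.05)
  # flat genes are not strong markers of either cluster: g02 untouched
  expect_false(any(mk$gene == "g02" & mk$pAdj < 0.05))
})

test_that("genes below min.pct are never tested for that cluster", {
  set.seed(3)
  counts <- matrix(rpois(200, 3), 10, 20,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   sprintf("c%02d", 1:20)))
  cl <- rep(c("A", "B"), each = 10)
  counts["g01", cl == "A"] <- c(5L, rep(0L, 9))   # pct_in = 0.1 < 0.2
  mk <- findMarkers(makeSE(counts, cluster = cl), minPct = 0.2)
  expect_false(any(mk$cluster == "A" & mk$gene == "g01"))
})

test_that("marker p-values agree with a brute-force rank-sum oracle", {
  set.seed(4)
  counts <- matrix(rnbinom(20 * 120, mu = 4, size = 2), 20, 120,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("c%03d", 1:120)))
  cl <- rep(c("A", "B"), each = 60)
  counts[1:5, cl == "A"] <- counts[1:5, cl == "A"] + 3L
  se <- makeSE(counts, cluster = cl)
  mk <- findMarkers(se, minPct = 0, logfcThreshold = 0)
  ln <- logNormalizeCounts(counts)
  for (i in seq_len(nrow(mk))) {
    idx <- cl == mk$cluster[i]
    expect_equal(mk$p[i],
                 bruteWilcoxP(ln[mk$gene[i], idx], ln[mk$gene[i], !idx]),
                 tolerance = 1e-12)
  }
  expect_warning(
    findMarkers(makeSE(counts, cluster = c("tiny", "tiny", cl[-(1:2)]))),
    "fewer than 3 cells")
})

test_that("Ro/e equals the hand-computed contingency example", {
  meta <- data.frame(
    cluster = rep(c("A", "B"), each = 100),
    tissue = c(rep("tumor", 90), rep("normal", 10),
               rep("tumor", 10), rep("normal", 90)))
  rt <- roeEnrichment(meta)
  expect_equal(expectedCounts(rt)["A", "tumor"], 50)
  expect_equal(roe(rt)["A", "tumor"], 1.8)
  expect_equal(roe(rt)["B", "normal"], 1.8)
  # margins conserved
  expect_equal(rowSums(expectedCounts(rt)), rowSums(observedCounts(rt)))
  expect_equal(colSums(expectedCounts(rt)), colSums(observedCounts(rt)))
  expect_identical(prevalence(rt), c(A = "tumor", B = "normal"))

  expect_error(roeEnrichment(data.frame(cluster = "A", tissue = "t")),
               "single tissue")
})

test_that("Ro/e is invariant to scaling and identical composition gives 1", {
  # identical composition in both tissues
  meta <- data.frame(cluster = rep(c("A", "B"), times = c(40, 60)),
                     tissue = rep(c("t", "n"), 50))
  expect_true(all(abs(roe(roeEnrichment(meta)) - 1) < 1e-12))

  # multiplying every observed count by a positive constant leaves roe fixed
  m1 <- data.frame(cluster = rep(c("A", "B", "C"), times = c(10, 25, 15)),
                   tissue = rep(c("t", "n"), 25))
  m3 <- m1[rep(seq_len(nrow(m1)), 3), ]
  expect_equal(roe(roeEnrichment(m1)), roe(roeEnrichment(m3)))
})

test_that("prevalence classification uses strict Ro/e > 1", {
  obs <- matrix(c(30, 10, 10, 30, 20, 20), 3, 2, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("tumor", "normal")))
  # expand the contingency into per-cell rows
  meta <- do.call(rbind, lapply(rownames(obs), function(cl)
    do.call(rbind, lapply(colnames(obs), function(ti)
      if (obs[cl, ti] > 0)
        data.frame(cluster = rep(cl, obs[cl, ti]), tissue = ti)))))
  rt <- roeEnrichment(meta)
  cls <- classifyPrevalence(rt, "tumor")
  # cluster C has identical composition to the margin: roe exactly 1 -> common
  expect_equal(unname(roe(rt)["C", "tumor"]), 1, tolerance = 1e-12)
  expect_identical(unname(cls["C"]), "common")
  expect_identical(unname(cls["A"]), "tumor-associated")
  expect_identical(unname(cls["B"]), "common")
  expect_error(classifyPrevalence(rt, "nope"), "not present")
})

test_that("signature scores equal hand-computed z-score means", {
  # 3 observations x 2 genes; log-normalization then per-gene z-scores
  counts <- matrix(c(10L, 0L, 5L,
                     2L, 8L, 5L,
                     88L, 92L, 90L), 3, 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "filler"),
                                   c("o1", "o2", "o3")))
  ln <- logNormalizeCounts(counts)
  zA <- (ln["gA", ] - mean(ln["gA", ])) / sd(ln["gA", ])
  zB <- (ln["gB", ] - mean(ln["gB", ])) / sd(ln["gB", ])
  sc <- signatureScore(makeSE(counts), c("gA", "gB"), "demo")
  expect_equal(as.numeric(sc), unname((zA + zB) / 2), tolerance = 1e-12)
  expect_identical(attr(sc, "nGenesUsed"), 2L)

  # a single-gene set is just that gene's z-score
  s1 <- signatureScore(makeSE(counts), "gA")
  expect_equal(as.numeric(s1), unname(zA), tolerance = 1e-12)

  # absent genes are dropped; a fully absent set errors with the set name
  s2 <- signatureScore(makeSE(counts), c("gA", "missing"), "partial")
  expect_identical(attr(s2, "nGenesUsed"), 1L)
  expect_error(signatureScore(makeSE(counts), "missing", "mySet"), "mySet")
})

test_that("constant genes contribute zero to every observation's score", {
  counts <- matrix(c(4L, 4L, 4L, 4L,
                     1L, 9L, 3L, 7L), 2, 4, byrow = TRUE,
                   dimnames = list(c("flat", "varies"),
                                   paste0("o", 1:4)))
  # equal library sizes keep "flat" constant after normalization
  counts <- rbind(counts, filler = 20L - colSums(counts))
  sFlat <- signatureScore(makeSE(counts), "flat")
  expect_true(all(sFlat == 0))
  sBoth <- signatureScore(makeSE(counts), c("flat", "varies"))
  sVar <- signatureScore(makeSE(counts), "varies")
  expect_equal(as.numeric(sBoth), as.numeric(sVar) / 2, tolerance = 1e-12)
})

test_that("planted high-signature population separates from background", {
  set.seed(5)
  n <- 60
  counts <- matrix(rpois(50 * 2 * n, 3), 50, 2 * n,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("c%03d", 1:(2 * n))))
  sig <- sprintf("g%02d", 1:8)
  grp <- rep(c("hi", "lo"), each = n)
  counts[sig, grp == "hi"] <- counts[sig, grp == "hi"] + rpois(8 * n, 6)
  sc <- signatureScore(makeSE(counts), sig)
  p <- wilcox.test(sc[grp == "hi"], sc[grp == "lo"])$p.value
  expect_lt(p, 1e-6)
})

test_that("Shannon diversity matches closed forms", {
  # uniform counts over k genes -> H = ln k
  for (k in c(2, 10, 100)) {
    counts <- matrix(5L, k, 3)
    rownames(counts) <- sprintf("g%03d", 1:k)
    colnames(counts) <- paste0("c", 1:3)
    d <- expressionDiversity(makeSE(counts), rep("grp", 3))
    expect_equal(unname(d$perGroup["grp"]), log(k), tolerance = 1e-12)
    expect_equal(unname(d$perCell), rep(log(k), 3), tolerance = 1e-12)
  }
  # a single expressed gene -> H = 0
  counts <- matrix(c(7L, 0L, 0L), 3, 1,
                   dimnames = list(paste0("g", 1:3), "c1"))
  expect_equal(unname(expressionDiversity(makeSE(counts), "x")$perGroup),
               0)
  # proportions (0.5, 0.25, 0.25)
  counts <- matrix(c(2L, 1L, 1L), 3, 1,
                   dimnames = list(paste0("g", 1:3), "c1"))
  expect_equal(unname(expressionDiversity(makeSE(counts), "x")$perGroup),
               1.039721, tolerance = 1e-6)
  # H is bounded by ln(number of expressed genes); all-zero group warns
  set.seed(6)
  counts <- matrix(rpois(200, 1), 20, 10,
                   dimnames = list(sprintf("g%02d", 1:20), paste0("c", 1:10)))
  counts[, 10] <- 0L
  expect_warning(
    d <- expressionDiversity(makeSE(counts), c(rep("a", 9), "z")),
    "all-zero")
  expect_true(is.na(d$perGroup["z"]))
  expect_lte(d$perGroup["a"], log(sum(rowSums(counts[, 1:9]) > 0)))
  expect_gte(d$perGroup["a"], 0)
})
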