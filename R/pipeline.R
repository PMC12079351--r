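## End-to-end orchestration over a single config: synthetic generation ->
## single-cell heterogeneity -> bulk/ATAC integration -> spatial niches ->
## survival, with a machine-readable run report including a planted-truth
## recovery summary.

#' Default demonstration pipeline configuration
#'
#' A complete config at demonstration problem sizes; every stage enabled.
#' Pass to [runPipeline()], possibly after dropping or editing sections
#' (a missing stage section skips that stage).
#'
#' @param seed integer seed propagated to every generator
#' @param outDir output directory
#' @return nested list config
#' @export
demoConfig <- function(seed = 7L, outDir = tempfile("stellaniche_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = outDir,
    single_cell = list(n_cells = 3000, enrichment_factor = 3,
                       qc = list(min_genes = 10, max_genes = 6000,
                                 min_umi = 20, max_umi = 50000,
                                 max_mito = 0.15)),
    bulk = list(n_genes = 1200, n_reps = 3, frac_deg = 0.1,
                effect_log2fc = 3, dispersion = 0.05),
    atac = list(n_peaks = 600, frac_coreg = 0.5),
    spatial = list(n_spots = 300, noise_sd = 1, psc_threshold = 0.10,
                   nmf_k = 6),
    survival = list(n_patients = 300, true_hr = 3, cut_quantile = 0.5,
                    censor_rate = 0.2)
  )
}

#' Validate a pipeline config, listing every violation
#'
#' @param config nested list (or YAML path) as produced by [demoConfig()]
#' @return the config (as a list), invisibly, or an error naming all
#'   violations at once
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single integer")
  chk(is.character(config$out_dir) && nzchar(config$out_dir),
      "out_dir must be a non-empty path")
  sc <- config$single_cell
  if (!is.null(sc)) {
    chk(is.null(sc$enrichment_factor) || sc$enrichment_factor > 0,
        "single_cell$enrichment_factor must be > 0")
    q <- sc$qc
    if (!is.null(q))
      chk(is.null(q$max_mito) || (q$max_mito >= 0 && q$max_mito <= 1),
          "single_cell$qc$max_mito must be in [0, 1]")
  }
  bk <- config$bulk
  if (!is.null(bk)) {
    chk(is.null(bk$n_reps) || bk$n_reps >= 2, "bulk$n_reps must be >= 2")
    chk(is.null(bk$dispersion) || bk$dispersion > 0,
        "bulk$dispersion must be > 0")
    chk(is.null(bk$frac_deg) || (bk$frac_deg >= 0 && bk$frac_deg <= 1),
        "bulk$frac_deg must be in [0, 1]")
  }
  at <- config$atac
  if (!is.null(at)) {
    chk(!is.null(bk), "atac stage requires the bulk stage")
    chk(is.null(at$frac_coreg) ||
          (at$frac_coreg >= 0 && at$frac_coreg <= 1),
        "atac$frac_coreg must be in [0, 1]")
  }
  sp <- config$spatial
  if (!is.null(sp)) {
    chk(is.null(sp$psc_threshold) ||
          (sp$psc_threshold >= 0 && sp$psc_threshold < 1),
        "spatial$psc_threshold must be in [0, 1)")
    chk(is.null(sp$nmf_k) || sp$nmf_k >= 1, "spatial$nmf_k must be >= 1")
    chk(is.null(sp$noise_sd) || sp$noise_sd >= 0,
        "spatial$noise_sd must be >= 0")
  }
  sv <- config$survival
  if (!is.null(sv)) {
    chk(is.null(sv$true_hr) || sv$true_hr > 0,
        "survival$true_hr must be > 0")
    chk(is.null(sv$censor_rate) ||
          (sv$censor_rate >= 0 && sv$censor_rate < 1),
        "survival$censor_rate must be in [0, 1)")
    chk(is.null(sv$cut_quantile) ||
          (sv$cut_quantile > 0 && sv$cut_quantile < 1),
        "survival$cut_quantile must be in (0, 1)")
  }
  if (length(bad))
    stop("invalid config:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

.stageRecord <- function(name, params, nIn, nOut, seconds, warnings,
                         recovery = NULL) {
  list(name = name, params = params, nIn = nIn, nOut = nOut,
       seconds = round(seconds, 3), warnings = warnings,
       recovery = recovery)
}

#' Run the full synthetic-to-results pipeline from a config
#'
#' Executes the enabled stages in dependency order (synthetic generation
#' feeding single-cell heterogeneity, bulk + ATAC integration, spatial
#' niches, survival), writes every stage's tables under `out_dir`, and
#' writes a JSON run report with per-stage record counts, parameters,
#' wall times, warnings, and a planted-truth recovery summary. A failing
#' stage halts the run; the report written up to that point is preserved
#' and the error is re-thrown.
#'
#' @param config nested list or YAML path (see [demoConfig()]); validated
#'   first, with every violation reported at once
#' @return the run report, invisibly (also written as `run_report.json`)
#' @export
runPipeline <- function(config) {
  config <- validateConfig(if (is.character(config))
    yaml::read_yaml(config) else config)
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  report <- list(
    seed = seed,
    package = as.character(utils::packageVersion("stellaniche")),
    rVersion = R.version.string,
    stages = list(), completed = FALSE)
  saveReport <- function()
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")

  runStage <- function(name, params, fun) {
    warns <- character()
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        report$stages[[name]] <<- .stageRecord(
          name, params, NA, NA, proc.time()[["elapsed"]] - t0,
          c(warns, paste("ERROR:", conditionMessage(e))))
        saveReport()
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    report$stages[[name]] <<- .stageRecord(
      name, params, res$nIn, res$nOut,
      proc.time()[["elapsed"]] - t0, warns, res$recovery)
    saveReport()
    res
  }

  if (!is.null(config$single_cell)) {
    sc <- config$single_cell
    runStage("single_cell", sc, function() {
      gen <- generateSingleCell(
        nCells = sc$n_cells %||% 3000,
        enrichmentFactor = sc$enrichment_factor %||% 3,
        seed = seed)
      q <- sc$qc %||% list()
      filtered <- qcFilterCells(
        gen$counts,
        minGenes = q$min_genes %||% 300, maxGenes = q$max_genes %||% 6000,
        minUmi = q$min_umi %||% 500, maxUmi = q$max_umi %||% 50000,
        maxMito = q$max_mito %||% 0.15)
      roeTab <- roeEnrichment(colData(filtered))
      prev <- classifyPrevalence(roeTab, "tumor")
      div <- expressionDiversity(filtered, colData(filtered)$tissue)
      writeCountMatrix(filtered, file.path(outDir, "sc_counts"))
      write.table(
        data.frame(cluster = rownames(roe(roeTab)), roe(roeTab),
                   prevalence = prevalence(roeTab)),
        file.path(outDir, "roe_table.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(
        data.frame(group = names(div$perGroup), shannon = div$perGroup),
        file.path(outDir, "diversity.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      planted <- gen$truth@enrichedClusters
      recovered <- vapply(names(planted), function(cl)
        roe(roeTab)[cl, planted[[cl]]] > 1, logical(1))
      list(nIn = ncol(gen$counts), nOut = ncol(filtered),
           recovery = list(plantedEnrichedRecovered = unname(recovered),
                           allRecovered = all(recovered)))
    })
  }

  bulkRes <- NULL; bulkTruth <- NULL
  if (!is.null(config$bulk)) {
    bk <- config$bulk
    res <- runStage("bulk_de", bk, function() {
      gen <- generateBulkPair(
        nGenes = bk$n_genes %||% 1200, nReps = bk$n_reps %||% 3,
        fracDeg = bk$frac_deg %||% 0.1,
        effectLog2fc = bk$effect_log2fc %||% 3,
        dispersion = bk$dispersion %||% 0.05, seed = seed)
      de <- differentialExpressionBulk(gen$counts)
      write.table(de, file.path(outDir, "bulk_de.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      planted <- gen$truth@degTable
      hit <- merge(planted, de, by = "gene")
      recall <- if (nrow(planted))
        mean(hit$deg & hit$direction.x == hit$direction.y) else NA
      list(nIn = nrow(gen$counts), nOut = sum(de$deg),
           recovery = list(plantedDegRecall = recall,
                           degUp = sum(de$direction == "up"),
                           degDown = sum(de$direction == "down")),
           de = de, truth = gen$truth)
    })
    bulkRes <- res$de; bulkTruth <- res$truth
  }

  if (!is.null(config$atac)) {
    at <- config$atac
    runStage("atac_coreg", at, function() {
      tss <- generateTssTable(
        unique(c(bulkRes$gene, bulkTruth@degTable$gene)))
      atac <- generateAtacPeaks(
        bulkTruth, nPeaks = at$n_peaks %||% 600,
        fracCoreg = at$frac_coreg %||% 0.5, tssTable = tss, seed = seed)
      dp <- callDifferentialPeaks(atac$activated, atac$quiescent)
      dp <- annotatePeakRegions(dp, tss)
      coreg <- integrateCoRegulation(dp, bulkRes)
      writePeakBed(dp, file.path(outDir, "differential_peaks.bed"))
      write.table(peakGeneMap(coreg), file.path(outDir, "coreg_peaks.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      truthPeaks <- atac$truth@coregPeaks
      found <- c(coUpPeaks(coreg), coDownPeaks(coreg))
      tp <- length(intersect(found, truthPeaks$peak))
      prec <- if (length(found)) tp / length(found) else NA
      rec <- if (nrow(truthPeaks)) tp / nrow(truthPeaks) else NA
      list(nIn = length(atac$activated),
           nOut = length(found),
           recovery = list(coregPrecision = prec, coregRecall = rec))
    })
  }

  if (!is.null(config$spatial)) {
    sp <- config$spatial
    runStage("spatial", sp, function() {
      gen <- generateSpatial(nSpots = sp$n_spots %||% 300,
                             noiseSd = sp$noise_sd %||% 1, seed = seed)
      est <- deconvolve(gen$spots, gen$reference)
      pscTypes <- grep("PSC|CAF", colnames(abundance(est)), value = TRUE)
      assign <- assignPscSpots(est, pscTypes,
                               threshold = sp$psc_threshold %||% 0.10)
      coloc <- colocalization(est)
      k <- min(sp$nmf_k %||% 6, dim(abundance(est)))
      nf <- nmfNiches(est, k = k, seed = seed)
      write.table(data.frame(spot = rownames(abundance(est)),
                             abundance(est)),
                  file.path(outDir, "spot_abundance.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(assign, file.path(outDir, "spot_assignment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(type = rownames(coloc), coloc),
                  file.path(outDir, "colocalization.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      niche <- gen$truth@nicheSets[[1]]
      nicheCor <- coloc[niche[1], niche[2]]
      others <- setdiff(colnames(coloc), niche)
      maxOther <- max(coloc[niche[1], others], na.rm = TRUE)
      list(nIn = ncol(gen$spots), nOut = sum(!is.na(assign$assigned)),
           recovery = list(plantedNicheCor = nicheCor,
                           nicheExceedsOthers = nicheCor > maxOther))
    })
  }

  if (!is.null(config$survival)) {
    sv <- config$survival
    runStage("survival", sv, function() {
      gen <- generateSurvival(
        nPatients = sv$n_patients %||% 300, trueHr = sv$true_hr %||% 3,
        cutQuantile = sv$cut_quantile %||% 0.5,
        censorRate = sv$censor_rate %||% 0.2, seed = seed)
      cp <- maxstatCutpoint(gen$survival)
      writeSurvivalCsv(gen$survival, file.path(outDir, "survival.csv"))
      write.table(
        data.frame(cutpoint = cp@cutpoint, statistic = cp@statistic,
                   hr = cp@hr, ciLower = cp@ciLower, ciUpper = cp@ciUpper,
                   coxP = cp@coxP, logrankP = cp@logrankP),
        file.path(outDir, "survival_cutpoint.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(nIn = nrow(gen$survival), nOut = nrow(gen$survival),
           recovery = list(
             hrAboveOne = cp@hr > 1,
             cutpointQuantile = mean(gen$survival$score <= cp@cutpoint)))
    })
  }

  report$completed <- TRUE
  saveReport()
  invisible(report)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
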