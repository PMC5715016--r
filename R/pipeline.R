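#' Configuration for a full pipeline run
#'
#' Validates paths, stage toggles, thresholds, and the master seed for
#' [runPipeline()]. When `countsFile`/`metaFile` are `NULL`, the bundled
#' simulator generates the study (using a seed derived from the master
#' seed); when no `signatureFile` is given, a clearly-synthetic signature
#' matrix is generated for the deconvolution stage.
#'
#' @param outDir Output directory (created if needed).
#' @param countsFile,metaFile,signatureFile,targetsFile,eqtlFile Optional
#'   input paths (counts TSV, metadata TSV, signature TSV, targets GMT,
#'   plain-text eQTL gene list).
#' @param stages Character vector of stages to run, a subset of
#'   `c("normalize", "screen", "deconvolve", "coexpress", "causal",
#'   "project", "kda")`.
#' @param sim A [simulationConfig()] used when no counts are supplied.
#' @param pPeanut,pTop Response-gene thresholds (defaults 0.005, 0.01).
#' @param driverFdr Key-driver FDR threshold (default 0.05).
#' @param K Key-driver path-length cap (default 7).
#' @param beta Soft-threshold power (default 6).
#' @param topVarFrac Causal-network variance fraction (default 0.25).
#' @param deconvPerms Permutations per sample in deconvolution (default 100).
#' @param causalRestarts Hill-climbing restarts (default 5).
#' @param minModuleSize Minimum coexpression module size (default 30).
#' @param seed Master seed; per-stage seeds are derived from it by stage
#'   name, so toggling one stage does not shift another's random stream.
#' @return A list of class `"RunConfig"`.
#' @export
pipelineConfig <- function(outDir,
                           countsFile = NULL, metaFile = NULL,
                           signatureFile = NULL, targetsFile = NULL,
                           eqtlFile = NULL,
                           stages = c("normalize", "screen", "deconvolve",
                                      "coexpress", "causal", "project", "kda"),
                           sim = simulationConfig(),
                           pPeanut = 0.005, pTop = 0.01, driverFdr = 0.05,
                           K = 7, beta = 6, topVarFrac = 0.25,
                           deconvPerms = 100, causalRestarts = 5,
                           minModuleSize = 30, seed = 1) {
  for (f in c(countsFile, metaFile, signatureFile, targetsFile, eqtlFile))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  bad <- setdiff(stages, c("normalize", "screen", "deconvolve", "coexpress",
                           "causal", "project", "kda"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (t in c(pPeanut, pTop, driverFdr))
    if (t <= 0 || t >= 1) stop("thresholds must lie in (0, 1)")
  structure(list(outDir = outDir, countsFile = countsFile,
                 metaFile = metaFile, signatureFile = signatureFile,
                 targetsFile = targetsFile, eqtlFile = eqtlFile,
                 stages = stages, sim = sim, pPeanut = pPeanut, pTop = pTop,
                 driverFdr = driverFdr, K = K, beta = beta,
                 topVarFrac = topVarFrac, deconvPerms = deconvPerms,
                 causalRestarts = causalRestarts,
                 minModuleSize = minModuleSize, seed = seed),
            class = "RunConfig")
}

# Internal: synthetic leukocyte-like signature anchored on the study's own
# mean expression so deconvolution fits are non-degenerate in demo runs.
syntheticSignature <- function(geneMeans, nTypes = 5, seed = 1) {
  set.seed(deriveSeed(seed, "synthetic-signature"))
  nG <- min(length(geneMeans), 200L)
  gs <- sort(sample(names(geneMeans), nG))
  base <- pmax(geneMeans[gs], 1)
  sig <- base * matrix(stats::rlnorm(nG * nTypes, 0, 0.3), nG, nTypes,
                       dimnames = list(gs, sprintf("cellType%02d",
                                                   seq_len(nTypes))))
  # marker stripes: each type over-expresses its own gene block
  stripe <- split(seq_len(nG), rep(seq_len(nTypes), length.out = nG))
  for (ct in seq_len(nTypes))
    sig[stripe[[ct]], ct] <- sig[stripe[[ct]], ct] * 5
  sig
}

#' Run the integrated challenge-response analysis pipeline
#'
#' Executes the enabled stages in dependency order — normalize, interaction
#' screen, leukocyte deconvolution, coexpression modules with response-gene
#' enrichment, causal network learning, target projection, and key driver
#' analysis — writing each stage's outputs as TSV under `cfg$outDir` and
#' returning (and writing) a JSON-compatible run report with stage statuses,
#' output paths, derived seeds, and headline numbers. Reruns with an
#' identical configuration reproduce byte-identical outputs. A stage failure
#' halts its dependents and is recorded in the report.
#'
#' @param cfg A [pipelineConfig()].
#' @return The run report, invisibly a list (also written to
#'   `report.json`).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = list(seed = cfg$seed, stages = cfg$stages),
                 seeds = list(), stages = list(), headline = list())
  failed <- character()
  outPath <- function(f) file.path(cfg$outDir, f)
  mark <- function(name, status, outputs = character(), ...) {
    report$stages[[name]] <<- c(list(status = status,
                                     outputs = as.list(outputs)), list(...))
    message(sprintf("[pipeline] %-10s %s", name, status))
  }
  canRun <- function(name, deps = character()) {
    if (!name %in% cfg$stages) {
      mark(name, "disabled")
      return(FALSE)
    }
    bad <- intersect(deps, failed)
    if (length(bad)) {
      mark(name, paste("skipped: dependency failed:",
                       paste(bad, collapse = ", ")))
      failed <<- c(failed, name)
      return(FALSE)
    }
    TRUE
  }

  # ---- inputs -----------------------------------------------------------
  if (!is.null(cfg$countsFile)) {
    counts <- readCounts(cfg$countsFile)
    design <- readSampleDesign(cfg$metaFile)
    truth <- NULL
  } else {
    simCfg <- cfg$sim
    simCfg$seed <- deriveSeed(cfg$seed, "simulate")
    report$seeds$simulate <- simCfg$seed
    sim <- simulateChallengeDataset(simCfg)
    counts <- sim$counts
    design <- sim$design
    truth <- sim$truth
    writeCounts(counts, outPath("counts.tsv"))
    writeSampleDesign(design, outPath("meta.tsv"))
    utils::write.table(truth, outPath("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  ce <- ChallengeExperiment(counts, design)

  # ---- normalize --------------------------------------------------------
  ceN <- NULL
  if (canRun("normalize")) {
    res <- tryCatch({
      ceN <- normalizeChallenge(ce)
      utils::write.table(
        data.frame(gene = rownames(ceN), log2cpm(ceN), check.names = FALSE),
        outPath("log2cpm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(gene = rownames(ceN), precisionWeights(ceN),
                   check.names = FALSE),
        outPath("weights.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample = colnames(ceN), factor = unname(normFactors(ceN))),
        outPath("factors.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(metadata(ceN)$outlierSamples, outPath("outliers.txt"))
      report$headline$nGenesKept <- nrow(ceN)
      report$headline$nOutlierSamples <- length(metadata(ceN)$outlierSamples)
      mark("normalize", "ok",
           c("log2cpm.tsv", "weights.tsv", "factors.tsv", "outliers.txt"))
      TRUE
    }, error = function(e) {
      mark("normalize", paste("failed:", conditionMessage(e)))
      FALSE
    })
    if (!res) failed <- c(failed, "normalize")
  } else failed <- c(failed, "normalize")

  # ---- interaction screen ----------------------------------------------
  peanutGenes <- NULL
  if (canRun("screen", "normalize")) {
    ok <- tryCatch({
      scr <- screenAllGenes(ceN, pPeanut = cfg$pPeanut, pTop = cfg$pTop)
      utils::write.table(scr, outPath("screen.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      peanutGenes <- scr$gene[scr$isPeanutGene]
      report$headline$nPeanutGenes <- length(peanutGenes)
      report$headline$nTopGenes <- sum(scr$isTop)
      mark("screen", "ok", "screen.tsv")
      TRUE
    }, error = function(e) {
      mark("screen", paste("failed:", conditionMessage(e)))
      FALSE
    })
    if (!ok) failed <- c(failed, "screen")
  } else failed <- c(failed, "screen")

  # targets: screen output, else user GMT
  targets <- peanutGenes
  if (is.null(targets) && !is.null(cfg$targetsFile))
    targets <- unique(unlist(readGmt(cfg$targetsFile)))

  # ---- deconvolution ----------------------------------------------------
  if (canRun("deconvolve", "normalize")) {
    ok <- tryCatch({
      sig <- if (!is.null(cfg$signatureFile)) readSignature(cfg$signatureFile)
             else syntheticSignature(rowMeans(assay(ceN, "counts")),
                                     seed = deriveSeed(cfg$seed, "deconvolve"))
      report$seeds$deconvolve <- deriveSeed(cfg$seed, "deconvolve")
      fr <- deconvolveStudy(assay(ceN, "counts"), sig,
                            nPerm = cfg$deconvPerms,
                            seed = report$seeds$deconvolve)
      utils::write.table(fr, outPath("fractions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cs <- cellFractionScreen(fr, cbind(sample = colnames(ceN),
                                         sampleDesign(ceN)))
      utils::write.table(cs, outPath("cellscreen.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      report$headline$nSignificantCellTypes <- sum(cs$fdr < 0.05, na.rm = TRUE)
      mark("deconvolve", "ok", c("fractions.tsv", "cellscreen.tsv"))
      TRUE
    }, error = function(e) {
      mark("deconvolve", paste("failed:", conditionMessage(e)))
      FALSE
    })
    if (!ok) failed <- c(failed, "deconvolve")
  } else failed <- c(failed, "deconvolve")

  # ---- coexpression -----------------------------------------------------
  moduleTargets <- NULL
  if (canRun("coexpress", "normalize")) {
    ok <- tryCatch({
      resid <- residualizeDates(log2cpm(ceN), sampleDesign(ceN)$collectionDate)
      A <- adjacencyMatrix(resid, beta = cfg$beta)
      tom <- topologicalOverlap(A)
      part <- detectModules(tom, minSize = cfg$minModuleSize)
      utils::write.table(
        data.frame(gene = names(part), module = unname(part)),
        outPath("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      report$headline$nModules <- length(unique(part[part > 0]))
      if (is.null(targets))
        stop("missing targets: enable the screen stage or supply a targets GMT")
      enr <- moduleEnrichmentTable(part, targets)
      utils::write.table(enr, outPath("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (nrow(enr)) {
        report$headline$topModuleFold <- enr$fold[1]
        topMod <- enr$module[1]
        moduleTargets <- intersect(names(part)[part == topMod], targets)
      }
      mark("coexpress", "ok", c("modules.tsv", "enrichment.tsv"))
      TRUE
    }, error = function(e) {
      mark("coexpress", paste("failed:", conditionMessage(e)))
      FALSE
    })
    if (!ok) failed <- c(failed, "coexpress")
  } else failed <- c(failed, "coexpress")

  # ---- causal network ---------------------------------------------------
  net <- NULL
  if (canRun("causal", "normalize")) {
    ok <- tryCatch({
      resid <- residualizeDates(log2cpm(ceN), sampleDesign(ceN)$collectionDate)
      topGenes <- selectTopVarianceGenes(resid, cfg$topVarFrac)
      eqtl <- if (!is.null(cfg$eqtlFile)) readLines(cfg$eqtlFile) else character()
      report$seeds$causal <- deriveSeed(cfg$seed, "causal")
      disc <- discretizeExpression(resid[topGenes, , drop = FALSE],
                                   seed = report$seeds$causal)
      net <- learnStructure(disc, structurePrior(eqtlGenes = eqtl),
                            nRestarts = cfg$causalRestarts,
                            seed = report$seeds$causal)
      writeEdgeList(net, outPath("network.tsv"))
      report$headline$nNetworkEdges <- nrow(networkEdges(net))
      mark("causal", "ok", "network.tsv")
      TRUE
    }, error = function(e) {
      mark("causal", paste("failed:", conditionMessage(e)))
      FALSE
    })
    if (!ok) failed <- c(failed, "causal")
  } else failed <- c(failed, "causal")

  # ---- projection -------------------------------------------------------
  subnet <- NULL
  projTargets <- if (!is.null(moduleTargets) && length(moduleTargets))
    moduleTargets else targets
  if (canRun("project", c("causal", "screen"))) {
    ok <- tryCatch({
      subnet <- projectTargets(net, projTargets)
      writeEdgeList(subnet, outPath("subnetwork.tsv"))
      report$headline$subnetworkSize <- length(networkNodes(subnet))
      mark("project", "ok", "subnetwork.tsv")
      TRUE
    }, error = function(e) {
      mark("project", paste("failed:", conditionMessage(e)))
      FALSE
    })
    if (!ok) failed <- c(failed, "project")
  } else failed <- c(failed, "project")

  # ---- key driver analysis ---------------------------------------------
  if (canRun("kda", c("causal", "screen"))) {
    ok <- tryCatch({
      kda <- keyDriverAnalysis(net, projTargets, K = cfg$K,
                               fdrCut = cfg$driverFdr)
      utils::write.table(kda, outPath("kda.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      report$headline$nKeyDrivers <- sum(kda$isKeyDriver)
      if (!is.null(subnet)) {
        lev <- assignLevels(subnet)
        le <- levelEnrichment(lev, kda$gene[kda$isKeyDriver])
        utils::write.table(
          data.frame(gene = names(lev), level = unname(lev)),
          outPath("levels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(le, outPath("level_enrichment.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      mark("kda", "ok", c("kda.tsv", "levels.tsv", "level_enrichment.tsv"))
      TRUE
    }, error = function(e) {
      mark("kda", paste("failed:", conditionMessage(e)))
      FALSE
    })
    if (!ok) failed <- c(failed, "kda")
  }

  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
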