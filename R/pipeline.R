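#' Run the full compartment-transcriptome pipeline
#'
#' Orchestrates simulate -> differential expression -> enrichment /
#' matrisome -> network / MCODE -> regulon -> cross-platform comparison
#' from a single configuration, writing per-stage TSV outputs and a JSON
#' run manifest (parameter echo, seed, package version, input checksums)
#' into `outdir`. Every stage is driven by the exported stage functions, so
#' the pipeline is deterministic given the seed; re-running with the same
#' configuration reproduces the outputs byte-for-byte.
#'
#' The configuration is a named list (or a YAML file path). Recognised
#' entries, all optional:
#' \describe{
#'   \item{seed}{integer run seed (default 1).}
#'   \item{stages}{character subset of `c("simulate", "de", "enrich",
#'     "matrisome", "network", "regulon", "compare")`; omitted stages are
#'     skipped (stages depending on them are skipped too).}
#'   \item{simulate}{arguments for [simulationConfig()] (e.g. `nGenes`,
#'     `cellsPerSample`, `deFraction`).}
#'   \item{countsDir}{instead of simulating, read a count triple written by
#'     [writeCountsMTX()].}
#'   \item{de}{arguments for [runPermutedDE()] (`poolSize`,
#'     `nPermutations`, `fdrAlpha`, `normalize`); defaults are the study
#'     procedure (pool 20, 10 permutations, FDR 0.05).}
#'   \item{network}{`scoreThreshold` (default 0.7) and MCODE parameters.}
#'   \item{regulon}{`nesMin` (default 3).}
#'   \item{resume}{reuse stage outputs already present in `outdir`
#'     (default FALSE).}
#' }
#' When resource files are not supplied, stage fixtures (gene sets,
#' category table, interaction table, regulons, the partner platform DE
#' table) are generated from the simulation ground truth with the
#' `simulate*` generators, so a fully synthetic end-to-end run needs no
#' external input.
#'
#' @param config named list or path to a YAML file.
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config = list(), outdir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  allStages <- c("simulate", "de", "enrich", "matrisome", "network",
                 "regulon", "compare")
  stages <- config$stages %||% allStages
  bad <- setdiff(stages, allStages)
  if (length(bad) > 0L) stopf("unknown stage '%s'", bad[1L])
  resume <- isTRUE(config$resume)
  results <- list()
  manifest <- list(package = "ivdSCT",
                   version = as.character(utils::packageVersion("ivdSCT")),
                   seed = seed, stages = stages,
                   parameters = config, inputs = list())
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ## --- counts: simulate or load -------------------------------------------
  sce <- NULL
  if (!is.null(config$countsDir)) {
    sce <- runStage("load-counts", readCountsMTX(config$countsDir))
    manifest$inputs$countsDir <- unname(tools::md5sum(
      file.path(config$countsDir, "matrix.mtx")))
  } else if ("simulate" %in% stages) {
    simArgs <- config$simulate %||% list()
    simArgs$seed <- simArgs$seed %||% seed
    cfg <- do.call(simulationConfig, simArgs)
    sce <- runStage("simulate", simulateCounts(cfg))
    simDir <- file.path(outdir, "counts")
    if (!resume || !file.exists(file.path(simDir, "matrix.mtx"))) {
      writeCountsMTX(sce, simDir)
      truth <- as.data.frame(SummarizedExperiment::rowData(sce))
      truth <- data.frame(gene = rownames(sce), truth)
      write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    results$counts <- sce
  }

  ## --- differential expression --------------------------------------------
  de <- NULL
  dePath <- file.path(outdir, "de.tsv")
  if ("de" %in% stages) {
    if (is.null(sce)) stopf("stage 'de' needs counts (simulate or countsDir)")
    deArgs <- config$de %||% list()
    de <- runStage("de", do.call(runPermutedDE, c(
      list(sce = sce,
           poolSize = deArgs$poolSize %||% 20L,
           nPermutations = deArgs$nPermutations %||% 10L,
           fdrAlpha = deArgs$fdrAlpha %||% 0.05,
           seed = deArgs$seed %||% seed,
           normalize = deArgs$normalize %||% "cpm"))))
    if (!resume || !file.exists(dePath)) writeDETable(asDETable(de), dePath)
    results$de <- de
  }

  detected <- if (!is.null(de)) deTable(de)$gene else character(0)
  sigNP <- if (!is.null(de)) significantGenes(de, "NP-high") else character(0)
  sigAF <- if (!is.null(de)) significantGenes(de, "AF-high") else character(0)

  ## --- enrichment ----------------------------------------------------------
  if ("enrich" %in% stages && !is.null(de)) {
    sets <- if (!is.null(config$gmt)) readGMT(config$gmt) else {
      simulateGeneSets(detected, nSets = 25L,
                       sizeRange = c(10L, min(50L, length(detected))),
                       enrichedIn = sigNP, seed = childSeed(seed, 101L))
    }
    enr <- runStage("enrich",
                    enrichGeneSets(c(sigNP, sigAF), sets, detected))
    write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$enrichment <- enr
  }

  ## --- matrisome landscape -------------------------------------------------
  if ("matrisome" %in% stages && !is.null(de)) {
    cats <- if (!is.null(config$categories)) {
      readCategoryTable(config$categories)
    } else {
      simulateCategoryTable(detected, seed = childSeed(seed, 102L))
    }
    land <- runStage("matrisome", classifyMatrisome(de, cats))
    write.table(land$counts, file.path(outdir, "matrisome_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(land$assignment,
                file.path(outdir, "matrisome_assignment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$matrisome <- land
  }

  ## --- interaction network and MCODE --------------------------------------
  complexes <- list()
  if ("network" %in% stages && !is.null(de)) {
    netArgs <- config$network %||% list()
    edgeTab <- if (!is.null(config$interactions)) {
      readInteractions(config$interactions)
    } else {
      nPlant <- min(12L, max(4L, length(sigNP))); nPlant <- max(4L, nPlant)
      fix <- simulateInteractionTable(
        nBackground = max(10L, length(detected) %/% 20L),
        planted = list(c(nPlant, 0.9)), noiseEdges = 50L,
        seed = childSeed(seed, 103L))
      fix$table
    }
    net <- runStage("network", buildNetwork(
      edgeTab, scoreThreshold = netArgs$scoreThreshold %||% 0.7,
      restrictTo = netArgs$restrictTo))
    topo <- topologyMetrics(net)
    write.table(data.frame(metric = names(topo),
                           value = unlist(topo, use.names = FALSE)),
                file.path(outdir, "topology.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    complexes <- mcodeFindComplexes(
      net,
      degreeCutoff = netArgs$degreeCutoff %||% 2L,
      nodeScoreCutoff = netArgs$nodeScoreCutoff %||% 0.2,
      kCore = netArgs$kCore %||% 2L,
      maxDepth = netArgs$maxDepth %||% 100L)
    if (length(complexes) > 0L) {
      compTab <- do.call(rbind, lapply(seq_along(complexes), function(i) {
        x <- complexes[[i]]
        data.frame(complex = i, score = round(complexScore(x), 1L),
                   nNodes = length(members(x)), nEdges = x@nEdges,
                   members = paste(members(x), collapse = ","))
      }))
      write.table(compTab, file.path(outdir, "complexes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    results$network <- net
    results$topology <- topo
    results$complexes <- complexes
  }

  ## --- regulon / signature TF ----------------------------------------------
  if ("regulon" %in% stages && length(complexes) > 0L) {
    clusterGenes <- members(complexes[[1L]])
    regArgs <- config$regulon %||% list()
    regTab <- if (!is.null(config$regulons)) {
      readRegulons(config$regulons)
    } else {
      simulateRegulons(tfs = c("TF1", "TF2", "TF3"),
                       targets = detected, coverTargets = clusterGenes,
                       seed = childSeed(seed, 104L))
    }
    filt <- filterRegulons(regTab, nesMin = regArgs$nesMin %||% 3)
    tfNet <- runStage("regulon", selectSignatureTF(clusterGenes, filt))
    if (nrow(tfNet$edges) > 0L) {
      write.table(tfNet$edges, file.path(outdir, "tf_network.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results$tfNetwork <- tfNet
  }

  ## --- cross-platform comparison -------------------------------------------
  if ("compare" %in% stages && !is.null(de)) {
    tabA <- asDETable(de)
    tabB <- if (!is.null(config$arrayDE)) readDETable(config$arrayDE) else {
      truth <- data.frame(
        gene = rownames(results$counts %||% sce),
        trueLog2FC = SummarizedExperiment::rowData(
          results$counts %||% sce)$trueLog2FC)
      simulatePlatformPair(truth, seed = childSeed(seed, 105L))$b
    }
    venn <- runStage("compare", vennPartition(
      tabA, tabB,
      sigA = tabA$gene[tabA$significant %in% TRUE],
      sigB = filterMicroarrayDEGs(tabB)$gene))
    sp <- tryCatch(spearmanLogFC(tabA, tabB), error = function(e) NULL)
    cmp <- data.frame(quantity = c(names(venn), "spearmanRho", "spearmanP"),
                      value = c(unlist(venn, use.names = FALSE),
                                sp$rho %||% NA_real_, sp$p %||% NA_real_))
    write.table(cmp, file.path(outdir, "comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$comparison <- list(venn = venn, spearman = sp)
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  results$manifest <- manifest
  invisible(results)
}
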