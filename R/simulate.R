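#' Simulation configuration for the two-compartment count generator
#'
#' Builds and validates the parameter set that [simulateCounts()] consumes.
#' Defaults emulate the study design the package targets: two compartments
#' (AF, NP) sequenced for two donors in separate batches, a few hundred cells
#' per sample, roughly 12,000 genes, negative-binomial counts with log-normal
#' gene means, a planted fraction of compartment-DE genes with fold changes
#' spanning roughly 2-50x, and per-cell library sizes around 10,000-12,000
#' UMI.
#'
#' @param nGenes number of genes.
#' @param cellsPerSample integer vector of cell counts, one per
#'   (compartment, donor) sample, recycled over the
#'   `2 * nDonors` samples in order (AF donor1, NP donor1, AF donor2, ...).
#'   The default mirrors the per-sample sizes of a two-batch design
#'   (535/719 and 190/291 cells).
#' @param nDonors number of donors (each donor contributes one AF and one NP
#'   sample).
#' @param deFraction fraction of genes with a true compartment effect.
#' @param logfcLocation,logfcScale location and scale of the normal
#'   distribution from which |true log2 fold change| magnitudes are drawn
#'   (absolute value taken, floored at 0.25); defaults span approximately
#'   2-50 fold.
#' @param nbDispersion negative-binomial dispersion \eqn{\phi} in
#'   \eqn{var = \mu + \phi \mu^2}, shared across genes.
#' @param libsizeLogMean,libsizeLogSd log-normal parameters of per-cell
#'   library size (defaults centred near 11,000 UMI).
#' @param geneMeanLogMean,geneMeanLogSd log-normal parameters of baseline
#'   relative gene abundance.
#' @param batchEffectSd standard deviation of a per-donor log2 shift applied
#'   to gene means (0 = no batch effect).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a validated list of class `SimulationConfig`.
#' @seealso [simulateCounts()]
#' @export
simulationConfig <- function(nGenes = 12000L,
                             cellsPerSample = c(535L, 719L, 190L, 291L),
                             nDonors = 2L,
                             deFraction = 0.18,
                             logfcLocation = 2,
                             logfcScale = 1,
                             nbDispersion = 0.3,
                             libsizeLogMean = log(11000),
                             libsizeLogSd = 0.25,
                             geneMeanLogMean = 0,
                             geneMeanLogSd = 1.5,
                             batchEffectSd = 0,
                             seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes),
              cellsPerSample = as.integer(cellsPerSample),
              nDonors = as.integer(nDonors),
              deFraction = deFraction,
              logfcLocation = logfcLocation,
              logfcScale = logfcScale,
              nbDispersion = nbDispersion,
              libsizeLogMean = libsizeLogMean,
              libsizeLogSd = libsizeLogSd,
              geneMeanLogMean = geneMeanLogMean,
              geneMeanLogSd = geneMeanLogSd,
              batchEffectSd = batchEffectSd,
              seed = as.integer(seed))
  if (cfg$nGenes < 1L || cfg$nDonors < 1L || any(cfg$cellsPerSample < 1L)) {
    stopf("invalid config: dimensions must be positive")
  }
  if (cfg$deFraction < 0 || cfg$deFraction > 1) {
    stopf("invalid config: deFraction must lie in [0,1]")
  }
  if (cfg$nbDispersion < 0) stopf("invalid config: nbDispersion must be >= 0")
  if (cfg$logfcScale <= 0 || cfg$libsizeLogSd <= 0 || cfg$geneMeanLogSd <= 0) {
    stopf("invalid config: scale parameters must be > 0")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a two-compartment, multi-donor single-cell count matrix
#'
#' Draws negative-binomial counts for `nGenes` genes across
#' `2 * nDonors` samples (compartments AF and NP for each donor). Gene g in
#' cell c has mean \eqn{\mu_g \cdot 2^{lfc_g \cdot [compartment=NP]} \cdot s_c}
#' where \eqn{\mu_g} is a log-normal baseline, \eqn{lfc_g} the planted true
#' log2 fold change (0 for non-DE genes) and \eqn{s_c} the cell's library-size
#' factor, so that a cell's expected total count equals its drawn library
#' size. Variance follows \eqn{\mu + \phi\mu^2}.
#'
#' @param config a [simulationConfig()].
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts`, `colData` columns `compartment` ("AF"/"NP") and `donor`, and
#'   ground truth in `rowData` (`trueLog2FC`, `isDE`).
#' @examples
#' sce <- simulateCounts(simulationConfig(nGenes = 200,
#'                                        cellsPerSample = 40, seed = 7))
#' table(sce$compartment, sce$donor)
#' @export
simulateCounts <- function(config = simulationConfig()) {
  if (!inherits(config, "SimulationConfig")) {
    stopf("config must come from simulationConfig()")
  }
  withr::with_seed(config$seed, {
    G <- config$nGenes
    nSamples <- 2L * config$nDonors
    cps <- rep_len(config$cellsPerSample, nSamples)
    compartment <- rep(rep(c("AF", "NP"), config$nDonors), times = cps)
    donor <- rep(rep(paste0("donor", seq_len(config$nDonors)), each = 2L),
                 times = cps)
    nCells <- sum(cps)

    ## planted truth
    lfc <- numeric(G)
    nDE <- round(config$deFraction * G)
    if (nDE > 0) {
      deIdx <- sample.int(G, nDE)
      mag <- pmax(abs(rnorm(nDE, config$logfcLocation, config$logfcScale)),
                  0.25)
      lfc[deIdx] <- mag * sample(c(-1, 1), nDE, replace = TRUE)
    }

    baseMean <- rlnorm(G, config$geneMeanLogMean, config$geneMeanLogSd)
    lib <- rlnorm(nCells, config$libsizeLogMean, config$libsizeLogSd)

    ## per-donor batch shift on log2 gene means (default off)
    batch <- matrix(0, nrow = G, ncol = config$nDonors)
    if (config$batchEffectSd > 0) {
      batch[] <- rnorm(G * config$nDonors, 0, config$batchEffectSd)
    }

    counts <- matrix(0L, nrow = G, ncol = nCells)
    isNP <- compartment == "NP"
    donorIdx <- as.integer(factor(donor, levels = unique(donor)))
    for (j in seq_len(nCells)) {
      mu_g <- baseMean * 2^(batch[, donorIdx[j]])
      if (isNP[j]) mu_g <- mu_g * 2^lfc
      mu <- mu_g / sum(mu_g) * lib[j]   # s_c scaled so E[total] = library size
      counts[, j] <- if (config$nbDispersion > 0) {
        rnbinom(G, mu = mu, size = 1 / config$nbDispersion)
      } else {
        rpois(G, mu)
      }
    }
    rownames(counts) <- sprintf("GENE%05d", seq_len(G))
    colnames(counts) <- sprintf("CELL%05d", seq_len(nCells))

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(compartment = compartment, donor = donor,
                                     row.names = colnames(counts)),
      rowData = S4Vectors::DataFrame(trueLog2FC = lfc, isDE = lfc != 0,
                                     row.names = rownames(counts))
    )
    S4Vectors::metadata(sce)$config <- config
    sce
  })
}

#' Simulate a protein-protein interaction table with planted dense components
#'
#' Generates a STRING-style edge table (`gene_a`, `gene_b`,
#' `combined_score`) containing background genes connected by random noise
#' edges plus one or more planted dense components whose realized edge
#' density is at least the requested density. Planted components are
#' connected (a spanning path is laid down first) and their edges carry high
#' combined scores (> 0.7) so they survive the standard score filter; noise
#' edges carry scores drawn across the whole range.
#'
#' @param nBackground number of background genes.
#' @param planted list of `c(size, density)` pairs; each plants one component
#'   of `size` genes at at least the given edge density. Sizes below 3 are
#'   rejected.
#' @param noiseEdges number of random background edges.
#' @param seed integer seed.
#' @return list with `table` (the edge `data.frame`) and `membership`
#'   (list of character vectors, the planted component members).
#' @examples
#' fix <- simulateInteractionTable(20, list(c(6, 1.0)), noiseEdges = 10,
#'                                 seed = 3)
#' head(fix$table)
#' @export
simulateInteractionTable <- function(nBackground, planted = list(),
                                     noiseEdges = 0L, seed = 1L) {
  for (pl in planted) {
    if (pl[1] < 3) stopf("invalid config: planted cluster size %d < 3", pl[1])
    if (pl[2] <= 0 || pl[2] > 1) {
      stopf("invalid config: planted density must lie in (0,1]")
    }
  }
  withr::with_seed(as.integer(seed), {
    edges <- list()
    membership <- list()
    for (i in seq_along(planted)) {
      n <- as.integer(planted[[i]][1])
      dens <- planted[[i]][2]
      nodes <- sprintf("CL%d_G%02d", i, seq_len(n))
      membership[[i]] <- nodes
      nEdges <- max(n - 1L, as.integer(ceiling(dens * choose(n, 2) - 1e-9)))
      ## spanning path guarantees connectivity, then random extra pairs
      allPairs <- t(combn(nodes, 2L))
      pathSel <- vapply(seq_len(n - 1L), function(k) {
        which(allPairs[, 1] == nodes[k] & allPairs[, 2] == nodes[k + 1L])
      }, integer(1L))
      rest <- setdiff(seq_len(nrow(allPairs)), pathSel)
      extra <- sample(rest, nEdges - (n - 1L))
      sel <- c(pathSel, extra)
      edges[[length(edges) + 1L]] <- data.frame(
        gene_a = allPairs[sel, 1], gene_b = allPairs[sel, 2],
        combined_score = round(runif(length(sel), 0.75, 0.999), 3),
        stringsAsFactors = FALSE)
    }
    if (noiseEdges > 0L) {
      if (nBackground < 2L) stopf("need >= 2 background genes for noise edges")
      bg <- sprintf("BG_G%03d", seq_len(nBackground))
      a <- sample(bg, noiseEdges, replace = TRUE)
      b <- sample(bg, noiseEdges, replace = TRUE)
      keep <- a != b
      edges[[length(edges) + 1L]] <- data.frame(
        gene_a = a[keep], gene_b = b[keep],
        combined_score = round(runif(sum(keep), 0.15, 0.999), 3),
        stringsAsFactors = FALSE)
    }
    tab <- if (length(edges) > 0L) do.call(rbind, edges) else {
      data.frame(gene_a = character(0), gene_b = character(0),
                 combined_score = numeric(0))
    }
    list(table = tab, membership = membership)
  })
}

#' Simulate a gene-set collection, optionally with one planted enrichment
#'
#' Draws `nSets` random gene sets from a universe; when `enrichedIn` is
#' given, the first set is oversampled from that gene list (fraction
#' `enrichedFraction`) so a known over-representation is planted for
#' downstream testing.
#'
#' @param universe character vector of gene symbols.
#' @param nSets number of sets.
#' @param sizeRange integer range `c(min, max)` of set sizes.
#' @param enrichedIn optional character vector (e.g. DEGs) to oversample the
#'   first set from.
#' @param enrichedFraction fraction of the planted set drawn from
#'   `enrichedIn`.
#' @param seed integer seed.
#' @return named list of character vectors (a gene-set collection); set
#'   descriptions are carried in the `"descriptions"` attribute.
#' @export
simulateGeneSets <- function(universe, nSets, sizeRange = c(10L, 50L),
                             enrichedIn = NULL, enrichedFraction = 0.8,
                             seed = 1L) {
  if (length(universe) == 0L) stopf("empty universe")
  if (max(sizeRange) > length(universe)) {
    stopf("sizeRange exceeds universe size")
  }
  withr::with_seed(as.integer(seed), {
    sets <- vector("list", nSets)
    names(sets) <- if (nSets > 0) sprintf("SET%03d", seq_len(nSets)) else NULL
    for (i in seq_len(nSets)) {
      sz <- sample(seq(sizeRange[1], sizeRange[2]), 1L)
      if (i == 1L && !is.null(enrichedIn)) {
        pool <- intersect(enrichedIn, universe)
        nHit <- min(length(pool), round(enrichedFraction * sz))
        sets[[i]] <- unique(c(sample(pool, nHit),
                              sample(setdiff(universe, pool), sz - nHit)))
      } else {
        sets[[i]] <- sample(universe, sz)
      }
    }
    attr(sets, "descriptions") <-
      if (nSets > 0) rep("simulated gene set", nSets) else character(0)
    sets
  })
}

#' Simulate a regulon table (TF, target, NES)
#'
#' Each TF receives a random subset of targets with NES values drawn
#' uniformly from `nesRange`. When `coverTargets` is given, the first TF is
#' assigned exactly that target set (at the top of the NES range), planting a
#' regulator whose regulon spans a known gene set.
#'
#' @param tfs character vector of transcription-factor symbols (non-empty).
#' @param targets character vector of candidate target genes.
#' @param nesRange numeric range of normalized enrichment scores (positive).
#' @param coverTargets optional character vector the first TF must cover.
#' @param seed integer seed.
#' @return `data.frame` with columns `tf`, `target`, `nes`.
#' @export
simulateRegulons <- function(tfs, targets, nesRange = c(1, 8),
                             coverTargets = NULL, seed = 1L) {
  if (length(tfs) == 0L) stopf("empty TF list")
  if (any(nesRange <= 0)) stopf("nesRange must be positive")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (i in seq_along(tfs)) {
      if (i == 1L && !is.null(coverTargets)) {
        tg <- unique(coverTargets)
        nes <- round(runif(length(tg), 0.8 * nesRange[2], nesRange[2]), 3)
      } else {
        nt <- sample(seq(2L, max(2L, length(targets) %/% 3L)), 1L)
        tg <- sample(targets, min(nt, length(targets)))
        nes <- round(runif(length(tg), nesRange[1], nesRange[2]), 3)
      }
      rows[[i]] <- data.frame(tf = tfs[i], target = tg, nes = nes,
                              stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab[!duplicated(tab[, c("tf", "target")]), , drop = FALSE]
  })
}

#' Simulate a matched pair of cross-platform DE tables
#'
#' Produces two differential-expression tables that share the same true log2
#' fold changes, each perturbed by independent platform noise and thinned by
#' platform-specific detection dropout -- a fixture for the cross-platform
#' comparison stage (Venn partitions and fold-change correlation).
#'
#' P values are generated from the noisy fold change via a normal reference
#' (`p = 2 * pnorm(-|logFC| / se)`) so that genes with larger planted effects
#' get smaller p values.
#'
#' @param truth `data.frame` with columns `gene` and `trueLog2FC` (e.g. from
#'   `rowData` of [simulateCounts()]).
#' @param noiseSd numeric length 2: per-platform fold-change noise SD.
#' @param dropout numeric length 2 in `[0,1]`: fraction of genes each
#'   platform fails to detect.
#' @param seed integer seed.
#' @return list of two `data.frame`s (`a`, `b`) with columns
#'   `gene`, `logFC`, `p`.
#' @export
simulatePlatformPair <- function(truth, noiseSd = c(0.5, 0.8),
                                 dropout = c(0.1, 0.25), seed = 1L) {
  if (any(noiseSd < 0)) stopf("noiseSd must be >= 0")
  if (any(dropout < 0 | dropout > 1)) stopf("dropout must lie in [0,1]")
  noiseSd <- rep_len(noiseSd, 2L)
  dropout <- rep_len(dropout, 2L)
  withr::with_seed(as.integer(seed), {
    mk <- function(sd, drop) {
      g <- truth$gene
      lfc <- truth$trueLog2FC + rnorm(length(g), 0, sd)
      se <- max(sd, 0.1)
      p <- pmin(1, pmax(2 * pnorm(-abs(lfc) / se), .Machine$double.xmin))
      keep <- runif(length(g)) >= drop
      data.frame(gene = g[keep], logFC = lfc[keep], p = p[keep],
                 stringsAsFactors = FALSE)
    }
    list(a = mk(noiseSd[1], dropout[1]), b = mk(noiseSd[2], dropout[2]))
  })
}

#' Simulate a matrisome-style category table
#'
#' Assigns a random subset of genes to the six matrisome categories with
#' divisions consistent with each category (core matrisome: ECM
#' glycoproteins, collagens, proteoglycans; matrisome-associated:
#' ECM-affiliated proteins, ECM regulators, secreted factors). A fixture for
#' [classifyMatrisome()].
#'
#' @param genes candidate gene symbols.
#' @param fraction fraction of genes to classify.
#' @param seed integer seed.
#' @return `data.frame` with columns `gene`, `division`, `category`.
#' @export
simulateCategoryTable <- function(genes, fraction = 0.3, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n <- round(fraction * length(genes))
    sel <- sample(genes, n)
    cat <- sample(names(.matrisomeCategories), n, replace = TRUE)
    data.frame(gene = sel,
               division = unname(.matrisomeCategories[cat]),
               category = cat, stringsAsFactors = FALSE)
  })
}
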