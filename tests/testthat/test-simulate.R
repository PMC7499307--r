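test_that("count simulation is deterministic and respects the null config", {
  cfg <- simulationConfig(nGenes = 150, cellsPerSample = 30, nDonors = 2,
                          deFraction = 0, seed = 1)
  a <- simulateCounts(cfg)
  b <- simulateCounts(cfg)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_true(all(SummarizedExperiment::rowData(a)$trueLog2FC == 0))
  expect_false(any(SummarizedExperiment::rowData(a)$isDE))
  expect_identical(as.vector(table(a$compartment)), c(60L, 60L))
  cfg2 <- simulationConfig(nGenes = 150, cellsPerSample = 30, seed = 2)
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(simulateCounts(cfg2))))
})

test_that("simulated counts follow the NB mean-variance law var = mu + phi mu^2", {
  ## library-size variation is switched off so the per-gene NB law is the
  ## exact truth the moment oracle can be compared to
  cfg <- simulationConfig(nGenes = 2000, cellsPerSample = 400, nDonors = 1,
                          deFraction = 0, nbDispersion = 0.3,
                          libsizeLogSd = 1e-6, seed = 42)
  sce <- simulateCounts(cfg)
  m <- SummarizedExperiment::assay(sce)[, sce$compartment == "AF"]
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu > 0.5
  ## least squares for phi in (var - mu) = phi * mu^2, through the origin
  phiHat <- sum((v[keep] - mu[keep]) * mu[keep]^2) / sum(mu[keep]^4)
  expect_gt(phiHat, 0.3 * 0.85)
  expect_lt(phiHat, 0.3 * 1.15)
})

test_that("expected library size matches the drawn per-cell size", {
  cfg <- simulationConfig(nGenes = 1500, cellsPerSample = 50, nDonors = 1,
                          deFraction = 0, libsizeLogMean = log(11000),
                          libsizeLogSd = 0.25, seed = 3)
  sce <- simulateCounts(cfg)
  tot <- colSums(SummarizedExperiment::assay(sce))
  ## cell totals concentrate around the log-normal library-size location
  expect_gt(mean(tot), 11000 * exp(0.25^2 / 2) * 0.9)
  expect_lt(mean(tot), 11000 * exp(0.25^2 / 2) * 1.1)
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulationConfig(nGenes = 0), "positive")
  expect_error(simulationConfig(deFraction = 1.5), "deFraction")
  expect_error(simulationConfig(logfcScale = 0), "scale")
})

test_that("interaction fixture plants components at the requested density", {
  fix <- simulateInteractionTable(0, planted = list(c(26, 311 / 325)),
                                  seed = 2)
  expect_identical(nrow(fix$table), 311L)
  expect_length(fix$membership[[1]], 26)
  ## K6 at density 1: all 15 pairs present
  k6 <- simulateInteractionTable(0, planted = list(c(6, 1.0)), seed = 1)
  got <- sort(paste(pmin(k6$table$gene_a, k6$table$gene_b),
                    pmax(k6$table$gene_a, k6$table$gene_b)))
  want <- apply(combn(sort(k6$membership[[1]]), 2), 2, paste, collapse = " ")
  expect_identical(got, sort(want))
  ## planted component is connected
  g <- buildNetwork(fix$table, scoreThreshold = 0)
  expect_equal(igraph::components(g)$no, 1)
  expect_identical(nrow(simulateInteractionTable(5, list(), 0, seed = 1)$table),
                   0L)
  expect_error(simulateInteractionTable(5, planted = list(c(2, 1))), "size")
})

test_that("gene-set fixture plants a detectable enrichment", {
  universe <- sprintf("G%03d", 1:200)
  degs <- universe[1:40]
  sets <- simulateGeneSets(universe, nSets = 5, sizeRange = c(15, 25),
                           enrichedIn = degs, seed = 7)
  expect_true(all(unlist(sets) %in% universe))
  enr <- enrichGeneSets(degs, sets, universe)
  expect_identical(enr$set[1], "SET001")
  expect_lt(enr$p[1], 0.01)
  expect_length(simulateGeneSets(universe, nSets = 0, seed = 1), 0)
  expect_error(simulateGeneSets(character(0), 3), "universe")
})

test_that("regulon fixture covers a requested target set and respects unions", {
  reg <- simulateRegulons(c("TFA", "TFB"), targets = sprintf("T%02d", 1:30),
                          coverTargets = sprintf("T%02d", 1:10), seed = 1)
  sel <- selectSignatureTF(sprintf("T%02d", 1:10), reg)
  expect_identical(sel$tf, "TFA")
  expect_setequal(sel$targets, sprintf("T%02d", 1:10))
  ## coverage arithmetic agrees with brute-force set union
  perTF <- split(reg$target, reg$tf)
  expect_identical(sel$ranking$coverage[sel$ranking$tf == "TFB"],
                   length(unique(intersect(perTF$TFB, sprintf("T%02d", 1:10)))))
  expect_error(simulateRegulons(character(0), "T1"), "TF")
})

test_that("platform pair fixture honours noise and dropout settings", {
  truth <- data.frame(gene = sprintf("G%03d", 1:300),
                      trueLog2FC = c(rep(2, 50), rep(0, 250)))
  clean <- simulatePlatformPair(truth, noiseSd = c(0, 0), dropout = c(0, 0),
                                seed = 1)
  sp <- spearmanLogFC(clean$a, clean$b)
  expect_equal(sp$rho, 1)
  oneGone <- simulatePlatformPair(truth, dropout = c(0, 1), seed = 1)
  expect_identical(nrow(oneGone$b), 0L)
  ## heavy noise destroys the correlation up to Monte-Carlo tolerance
  noisy <- simulatePlatformPair(truth, noiseSd = c(50, 50),
                                dropout = c(0, 0), seed = 2)
  expect_lt(abs(spearmanLogFC(noisy$a, noisy$b)$rho), 0.15)
  expect_error(simulatePlatformPair(truth, dropout = c(-0.1, 0)), "dropout")
})
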