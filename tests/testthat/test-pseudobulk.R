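test_that("pooling partitions samples into disjoint groups and conserves counts", {
  withr::with_seed(1, {
    m <- matrix(rpois(50 * 40, 5), nrow = 50)
  })
  sce <- makeSCE(m, compartment = rep(c("AF", "NP"), each = 20))
  pooled <- poolCells(sce, poolSize = 20, permutationIndex = 1, seed = 1)
  pm <- SummarizedExperiment::assay(pooled)
  expect_identical(ncol(pm), 2L)
  ## all 40 cells used exactly once: totals conserved
  expect_equal(sum(pm), sum(m))
  expect_equal(as.vector(rowSums(pm)), as.vector(rowSums(m)))
  expect_identical(SummarizedExperiment::colData(pooled)$compartment,
                   c("AF", "NP"))
})

test_that("remainder cells are discarded and pool size 1 is a permutation", {
  withr::with_seed(2, m <- matrix(rpois(30 * 45, 5), nrow = 30))
  sce <- makeSCE(m, compartment = rep("AF", 45))
  pooled <- poolCells(sce, poolSize = 20, permutationIndex = 1, seed = 3)
  expect_identical(ncol(SummarizedExperiment::assay(pooled)), 2L)  # floor(45/20)
  ## g = 1: pseudo-cells are the original cells up to order
  p1 <- SummarizedExperiment::assay(poolCells(sce, poolSize = 1,
                                              permutationIndex = 1, seed = 3))
  expect_identical(ncol(p1), 45L)
  expect_equal(sort(unname(colSums(p1))), sort(unname(colSums(m))))
  ## different permutation indices draw different partitions at g = 20
  pA <- SummarizedExperiment::assay(poolCells(sce, 20, 1, seed = 3))
  pB <- SummarizedExperiment::assay(poolCells(sce, 20, 2, seed = 3))
  expect_false(identical(pA, pB))
  expect_error(poolCells(sce, poolSize = 50), "fewer than 50")
})

test_that("CPM normalization scales columns exactly and is idempotent", {
  m <- matrix(c(5, 15, 2, 8), nrow = 2)
  cpm <- cpmNormalize(m)
  expect_equal(cpm[, 1], c(250000, 750000))
  expect_equal(colSums(cpm), c(1e6, 1e6))
  expect_equal(cpmNormalize(cpm), cpm)
  m0 <- cbind(m, c(0, 0)); colnames(m0) <- c("a", "b", "zero")
  expect_error(cpmNormalize(m0), "zero")
})

test_that("size-factor normalization is robust to composition shifts", {
  ## two columns identical except one dominant gene quadrupled: the median
  ## ratio ignores it, total-count scaling would not
  base <- c(1000, 50, 40, 30, 20, 10, 60, 70, 80, 90)
  m <- cbind(a = base, b = base)
  m[1, 2] <- 4000
  norm <- sizeFactorNormalize(m)
  expect_equal(attr(norm, "sizeFactors"), c(a = 1, b = 1))
  expect_equal(norm[-1, "a"], norm[-1, "b"])
})

test_that("moment dispersion estimates recover the generating dispersion", {
  grp <- rep(c("A", "B"), each = 15)
  withr::with_seed(11, {
    mu <- rlnorm(1000, log(50), 0.8)
    pois <- t(vapply(mu, function(x) rpois(30, x), numeric(30)))
    nb <- t(vapply(mu, function(x) rnbinom(30, mu = x, size = 1 / 0.3),
                   numeric(30)))
  })
  expect_lte(estimateCommonDispersion(pois, grp)$common, 0.02)
  phiHat <- estimateCommonDispersion(nb, grp)$common
  expect_gte(phiHat, 0.2)
  expect_lte(phiHat, 0.4)
  const <- matrix(7, nrow = 5, ncol = 6)
  expect_identical(estimateCommonDispersion(const, rep(c("A", "B"), 3))$common,
                   0)
  expect_error(estimateCommonDispersion(nb[, 1:3], c("A", "A", "B")),
               "fewer than 2")
})

test_that("the NB likelihood-ratio test matches a direct likelihood oracle", {
  ## identical groups: null identity
  same <- nbLRT(c(4, 4, 4, 4), c("A", "A", "B", "B"), phi = 0.2)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(same$log2FC, 0)
  ## phi = 0 equals the Poisson LRT, checked by independent dpois evaluation
  y <- c(2, 2, 8, 8); grp <- c("A", "A", "B", "B")
  res <- nbLRT(y, grp, phi = 0)
  llFull <- sum(dpois(y[1:2], 2, log = TRUE)) +
    sum(dpois(y[3:4], 8, log = TRUE))
  llNull <- sum(dpois(y, 5, log = TRUE))
  expect_equal(res$D, 2 * (llFull - llNull), tolerance = 1e-12)
  expect_equal(res$p, pchisq(2 * (llFull - llNull), 1, lower.tail = FALSE))
  ## phi > 0 equals independent dnbinom evaluation at the group means
  res3 <- nbLRT(y, grp, phi = 0.4)
  nbll <- function(yy, mu) sum(dnbinom(yy, mu = mu, size = 1 / 0.4, log = TRUE))
  D <- 2 * (nbll(y[1:2], 2) + nbll(y[3:4], 8) - nbll(y, 5))
  expect_equal(res3$D, D, tolerance = 1e-10)
  ## label swap: p invariant, fold change flips
  sw <- nbLRT(y, c("B", "B", "A", "A"), phi = 0)
  expect_equal(sw$p, res$p)
  expect_equal(sw$log2FC, -res$log2FC)
  expect_error(nbLRT(y, c("A", "A", "A", "A")), "two groups")
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bhFDR(rep(0.03, 5)), rep(0.03, 5))
  ## hand-applied step-up: q_i = min_{j>=i} m p_(j) / j
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(4, p <- runif(50))
  q <- bhFDR(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  ## monotone after sorting by p
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bhFDR(c(0.1, NaN)), "NaN")
  expect_error(bhFDR(c(0.1, 1.2)), "\\[0,1\\]")
})

test_that("a single permutation equals one pooled analysis and runs are label-antisymmetric", {
  cfg <- simulationConfig(nGenes = 200, cellsPerSample = 60, nDonors = 1,
                          deFraction = 0.1, seed = 21)
  sce <- simulateCounts(cfg)
  de1 <- suppressMessages(runPermutedDE(sce, nPermutations = 1, seed = 5))
  ## manual single round with the same child seed
  pooled <- poolCells(sce, 20, permutationIndex = 1, seed = 5)
  pm <- SummarizedExperiment::assay(pooled)
  norm <- sizeFactorNormalize(pm)
  phi <- estimateCommonDispersion(
    norm, SummarizedExperiment::colData(pooled)$compartment)$common
  manual <- ivdSCT:::.nbLRTMatrix(
    norm, SummarizedExperiment::colData(pooled)$compartment == "NP", phi)
  expect_equal(deTable(de1)$meanLog2FC, unname(manual$log2FC))
  expect_equal(deTable(de1)$combinedP, unname(pmin(1, manual$p)), tolerance = 1e-10)
  ## swapping compartment labels flips every fold change, keeps p
  swapped <- sce
  swapped$compartment <- ifelse(sce$compartment == "AF", "NP", "AF")
  deSw <- suppressMessages(runPermutedDE(swapped, nPermutations = 2, seed = 5))
  deOr <- suppressMessages(runPermutedDE(sce, nPermutations = 2, seed = 5))
  expect_equal(deTable(deSw)$meanLog2FC, -deTable(deOr)$meanLog2FC)
  expect_equal(deTable(deSw)$combinedP, deTable(deOr)$combinedP)
})

test_that("averaging over more permutations stabilizes the evidence", {
  cfg <- simulationConfig(nGenes = 150, cellsPerSample = 60, nDonors = 1,
                          deFraction = 0.2, seed = 31)
  sce <- simulateCounts(cfg)
  runs <- function(R) vapply(1:4, function(s) {
    deTable(suppressMessages(
      runPermutedDE(sce, nPermutations = R, seed = 100 + s)))$meanNegLog10P
  }, numeric(nrow(sce)))
  sd1 <- apply(runs(1), 1, sd)
  sd10 <- apply(runs(10), 1, sd)
  expect_lt(mean(sd10), mean(sd1))
})

test_that("detection power grows with the planted fold change", {
  recallAt <- function(lfc) {
    cfg <- simulationConfig(nGenes = 300, cellsPerSample = 100, nDonors = 1,
                            deFraction = 0.1, logfcLocation = lfc,
                            logfcScale = 1e-9, seed = 77)
    sce <- simulateCounts(cfg)
    de <- suppressMessages(runPermutedDE(sce, seed = 7))
    truth <- rownames(sce)[SummarizedExperiment::rowData(sce)$isDE]
    mean(truth %in% significantGenes(de))
  }
  r <- vapply(c(0.5, 1, 2), recallAt, numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_gt(r[3], 0.9)
})

test_that("unexpressed genes are dropped and both compartments are required", {
  withr::with_seed(3, m <- matrix(rpois(20 * 80, 4), nrow = 20))
  m[5, ] <- 0L
  sce <- makeSCE(m, compartment = rep(c("AF", "NP"), each = 40))
  expect_message(de <- runPermutedDE(sce, poolSize = 10, nPermutations = 2),
                 "1 gene")
  expect_identical(nrow(deTable(de)), 19L)
  expect_equal(de@nDropped, 1)
  onlyAF <- makeSCE(m, compartment = rep("AF", 80))
  expect_error(runPermutedDE(onlyAF), "compartments")
})
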