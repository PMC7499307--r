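#' Pool cells into pseudo-cells within each (compartment, donor) sample
#'
#' Within every sample, cells are randomly partitioned (seeded by
#' `(seed, permutationIndex)`) into `floor(n / poolSize)` disjoint groups of
#' exactly `poolSize` cells; remainder cells are set aside for that
#' permutation (a fresh partition is drawn each permutation, so all cells
#' contribute across permutations). Each pseudo-cell is the per-gene sum of
#' its member cells' counts and inherits the compartment and donor of its
#' sample.
#'
#' @param sce a `SingleCellExperiment` with assay `counts` and `colData`
#'   columns `compartment`, `donor`.
#' @param poolSize cells per pseudo-cell (default 20).
#' @param permutationIndex which permutation this partition belongs to.
#' @param seed integer run seed.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (genes x pseudo-cells) and `colData` columns `compartment`,
#'   `donor`, `sample`.
#' @export
poolCells <- function(sce, poolSize = 20L, permutationIndex = 1L, seed = 1L) {
  if (poolSize < 1L) stopf("poolSize must be >= 1")
  counts <- SummarizedExperiment::assay(sce, "counts")
  cd <- SummarizedExperiment::colData(sce)
  sample <- paste(cd$compartment, cd$donor, sep = ":")
  samples <- unique(sample)
  tooSmall <- samples[table(sample)[samples] < poolSize]
  if (length(tooSmall) > 0L) {
    stopf("sample '%s' has fewer than %d cells", tooSmall[1L], poolSize)
  }
  withr::with_seed(childSeed(seed, permutationIndex), {
    cols <- list(); comp <- character(0); don <- character(0); sam <- character(0)
    for (s in samples) {
      idx <- which(sample == s)
      idx <- idx[sample.int(length(idx))]
      nPools <- length(idx) %/% poolSize
      for (k in seq_len(nPools)) {
        memberIdx <- idx[((k - 1L) * poolSize + 1L):(k * poolSize)]
        cols[[length(cols) + 1L]] <-
          rowSums(counts[, memberIdx, drop = FALSE])
        comp <- c(comp, cd$compartment[idx[1L]])
        don <- c(don, cd$donor[idx[1L]])
        sam <- c(sam, s)
      }
    }
    pm <- do.call(cbind, cols)
    rownames(pm) <- rownames(counts)
    colnames(pm) <- sprintf("%s.p%02d.%03d", sam, permutationIndex,
                            seq_along(sam))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = pm),
      colData = S4Vectors::DataFrame(compartment = comp, donor = don,
                                     sample = sam,
                                     row.names = colnames(pm)))
  })
}

#' Counts-per-million normalization of a pseudo-cell matrix
#'
#' Scales each column to sum to `scale` (default 1e6). Idempotent up to the
#' scale; errors on an all-zero column, naming it.
#'
#' @param m numeric matrix (genes x pseudo-cells) or a
#'   `SummarizedExperiment` carrying one in assay `counts`.
#' @param scale target column sum.
#' @return object of the same shape with normalized values (assay `cpm`
#'   when the input is a `SummarizedExperiment`).
#' @export
cpmNormalize <- function(m, scale = 1e6) {
  isSE <- methods::is(m, "SummarizedExperiment")
  x <- if (isSE) SummarizedExperiment::assay(m, "counts") else m
  tot <- colSums(x)
  if (any(tot == 0)) {
    bad <- colnames(x)[which(tot == 0)[1L]]
    stopf("all-zero pseudo-cell '%s' cannot be CPM-normalized",
          if (is.null(bad)) as.character(which(tot == 0)[1L]) else bad)
  }
  out <- sweep(x, 2L, tot / scale, "/")
  if (isSE) {
    SummarizedExperiment::assays(m)$cpm <- out
    m
  } else out
}

#' Median-of-ratios size-factor normalization
#'
#' Divides each column by its median-of-ratios size factor: the median,
#' over genes with a positive geometric-mean reference, of the ratio of
#' the column's counts to the reference profile. Robust to composition
#' shifts caused by a minority of strongly differential genes, unlike
#' total-count scaling, and leaves values on the count scale.
#'
#' @param m numeric matrix, genes x pseudo-cells, no all-zero column.
#' @return matrix of normalized values; size factors in the
#'   `"sizeFactors"` attribute.
#' @export
sizeFactorNormalize <- function(m) {
  logRef <- rowMeans(log(m))
  usable <- is.finite(logRef)
  if (!any(usable)) {
    stopf("no gene has positive counts in every pseudo-cell; cannot form a reference")
  }
  ref <- exp(logRef[usable])
  sf <- apply(m[usable, , drop = FALSE], 2L, function(col) {
    median(col / ref)
  })
  if (any(sf <= 0)) {
    bad <- colnames(m)[which(sf <= 0)[1L]]
    stopf("non-positive size factor for pseudo-cell '%s'", bad)
  }
  out <- sweep(m, 2L, sf, "/")
  attr(out, "sizeFactors") <- sf
  out
}

#' Moment estimate of the common negative-binomial dispersion
#'
#' For each gene, within each group, the method-of-moments dispersion
#' \eqn{\phi_g = \max(0, (s^2_g - \bar\mu_g) / \bar\mu_g^2)} is computed and
#' pooled across groups (weighted by group degrees of freedom). The common
#' dispersion is the median of the per-gene estimates over genes whose
#' overall mean exceeds `meanFloor`, which screens out genes too weakly
#' expressed to inform the estimate.
#'
#' @param m numeric matrix, genes x pseudo-cells.
#' @param groups group label per column (two or more groups; each with at
#'   least 2 columns).
#' @param meanFloor minimum overall gene mean for inclusion in the median.
#' @return list with `common` (the pooled dispersion, >= 0) and `perGene`
#'   (diagnostic per-gene estimates).
#' @export
estimateCommonDispersion <- function(m, groups, meanFloor = 1) {
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) stopf("groups length must match columns")
  tab <- table(groups)
  if (any(tab < 2L)) {
    stopf("group '%s' has fewer than 2 pseudo-cells",
          names(tab)[which(tab < 2L)[1L]])
  }
  num <- 0; den <- 0
  for (g in names(tab)) {
    sub <- m[, groups == g, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1L, var)
    phi <- ifelse(mu > 0, (v - mu) / mu^2, 0)
    w <- ncol(sub) - 1L
    num <- num + w * phi
    den <- den + w
  }
  perGene <- pmax(0, num / den)
  overallMean <- rowMeans(m)
  keep <- overallMean > meanFloor
  common <- if (any(keep)) max(0, median(perGene[keep])) else 0
  list(common = common, perGene = perGene)
}

## Negative-binomial log-likelihood terms that depend on the mean, for a
## group with n observations summing to S, at common mean mu and dispersion
## phi.  The lgamma terms that do not involve mu cancel in the LRT and are
## omitted.  phi = 0 is the Poisson limit.
.nbMeanLoglik <- function(n, S, mu, phi) {
  out <- numeric(length(mu))
  zero <- mu <= 0
  ## mu = 0 contributes 0 when S = 0 (0 log 0 := 0), -Inf otherwise
  out[zero] <- ifelse(S[zero] == 0, 0, -Inf)
  ok <- !zero
  if (phi > 0) {
    a <- 1 / phi
    out[ok] <- n * a * log(a / (a + mu[ok])) +
      S[ok] * log(mu[ok] / (a + mu[ok]))
  } else {
    out[ok] <- -n * mu[ok] + S[ok] * log(mu[ok])
  }
  out
}

## Vectorized two-group NB likelihood-ratio test over the rows of a matrix.
## Group means are the fixed-dispersion MLEs, so the LRT is closed-form.
.nbLRTMatrix <- function(m, isB, phi, priorCount = 0.5) {
  nA <- sum(!isB); nB <- sum(isB)
  SA <- rowSums(m[, !isB, drop = FALSE])
  SB <- rowSums(m[, isB, drop = FALSE])
  muA <- SA / nA; muB <- SB / nB; mu0 <- (SA + SB) / (nA + nB)
  D <- 2 * (.nbMeanLoglik(nA, SA, muA, phi) +
              .nbMeanLoglik(nB, SB, muB, phi) -
              .nbMeanLoglik(nA, SA, mu0, phi) -
              .nbMeanLoglik(nB, SB, mu0, phi))
  D <- pmax(D, 0)
  p <- pchisq(D, df = 1L, lower.tail = FALSE)
  log2FC <- log2((muB + priorCount) / (muA + priorCount))
  ## genes with zero counts everywhere carry no evidence
  allZero <- SA == 0 & SB == 0
  p[allZero] <- 1
  log2FC[allZero] <- 0
  list(log2FC = log2FC, p = p, D = D)
}

#' Two-group negative-binomial likelihood-ratio test for one gene
#'
#' Compares a full model with one NB mean per group against a null with a
#' common mean, at fixed dispersion `phi` (the group mean is the maximum
#' likelihood estimate of the NB mean when the dispersion is fixed, so the
#' test is closed-form). The statistic is referred to \eqn{\chi^2_1};
#' `phi = 0` degrades exactly to the Poisson likelihood-ratio test. The
#' fold change is `log2((mean_B + prior) / (mean_A + prior))` where B is the
#' second group level (alphabetically, or the second factor level), so with
#' AF/NP labels positive values mean NP-high.
#'
#' @param values numeric vector of (normalized) counts for one gene.
#' @param groups two-level grouping vector aligned with `values`.
#' @param phi NB dispersion (>= 0).
#' @param priorCount pseudo-count protecting the fold change from division
#'   by zero.
#' @return list with `log2FC`, `p`, and the deviance `D`.
#' @examples
#' nbLRT(c(2, 2, 8, 8), c("AF", "AF", "NP", "NP"), phi = 0)
#' @export
nbLRT <- function(values, groups, phi = 0, priorCount = 0.5) {
  if (phi < 0) stopf("phi must be >= 0")
  f <- factor(groups)
  if (nlevels(f) != 2L) stopf("exactly two groups required")
  if (any(table(f) == 0L)) stopf("both groups must be non-empty")
  res <- .nbLRTMatrix(matrix(values, nrow = 1L), isB = f == levels(f)[2L],
                      phi = phi, priorCount = priorCount)
  lapply(res, `[[`, 1L)
}

#' Benjamini-Hochberg q values
#'
#' Step-up false-discovery-rate adjustment; a thin, validating wrapper
#' around [stats::p.adjust()].
#'
#' @param p numeric vector of p values in `[0,1]`; `NaN` is rejected.
#' @return q values, same length, capped at 1.
#' @export
bhFDR <- function(p) {
  if (any(is.nan(p))) stopf("NaN p value")
  if (any(is.na(p))) stopf("missing p value")
  if (any(p < 0 | p > 1)) stopf("p values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Pooled pseudo-cell permutation differential expression
#'
#' The package's core procedure. For each of `nPermutations` rounds, cells
#' are pooled into pseudo-cells of `poolSize` within each (compartment,
#' donor) sample ([poolCells()]), pseudo-cell profiles are normalized to
#' counts per million ([cpmNormalize()]), a common NB dispersion is
#' estimated ([estimateCommonDispersion()]), and every gene is tested for a
#' compartment effect (NP vs AF) with the closed-form NB likelihood-ratio
#' test. Log2 fold changes and \eqn{-\log_{10} p} values are then averaged
#' over the rounds; the combined p value is the back-transform
#' \eqn{10^{-\mathrm{mean}(-\log_{10} p)}}; Benjamini-Hochberg q values are
#' computed on the combined p values and genes with `q < fdrAlpha` are
#' called significant.
#'
#' Genes expressed in zero cells are dropped before testing (their count is
#' reported in the result). Pooling in round r is seeded deterministically
#' from `(seed, r)`, so runs are reproducible and rounds independent.
#'
#' @param sce `SingleCellExperiment` with assay `counts` and `colData`
#'   columns `compartment` (AF/NP; both must be present) and `donor`.
#' @param poolSize cells per pseudo-cell (default 20).
#' @param nPermutations number of pooling rounds (default 10).
#' @param fdrAlpha FDR level for the significance call (default 0.05).
#' @param seed integer run seed.
#' @param cpmScale counts-per-million scale (default 1e6).
#' @param priorCount fold-change pseudo-count (default 0.5).
#' @param normalize library-size normalization applied to the pseudo-cell
#'   profiles before testing. `"ratio"` (default) divides each pseudo-cell
#'   by its median-of-ratios size factor (the median, over genes, of the
#'   ratio of the pseudo-cell's counts to the geometric-mean reference
#'   profile), which removes depth differences while staying robust to
#'   composition shifts from strongly differential genes and keeps values
#'   on the count scale on which the NB mean-variance model is calibrated.
#'   `"median"` scales every pseudo-cell total to the median pseudo-cell
#'   library size (composition-sensitive). `"cpm"` scales totals to counts
#'   per million; because that inflates pseudo-cell counts several-fold,
#'   the common dispersion under-covers weakly expressed genes and their
#'   tests become anticonservative, so this mode is provided for
#'   comparability rather than as the default (see the methods vignette).
#' @return a [DEResult-class] object.
#' @seealso [deTable()], [significantGenes()]
#' @export
runPermutedDE <- function(sce, poolSize = 20L, nPermutations = 10L,
                          fdrAlpha = 0.05, seed = 1L, cpmScale = 1e6,
                          priorCount = 0.5,
                          normalize = c("ratio", "median", "cpm")) {
  normalize <- match.arg(normalize)
  if (nPermutations < 1L) stopf("nPermutations must be >= 1")
  if (fdrAlpha <= 0 || fdrAlpha >= 1) stopf("fdrAlpha must lie in (0,1)")
  cd <- SummarizedExperiment::colData(sce)
  if (!all(c("AF", "NP") %in% cd$compartment)) {
    stopf("both compartments (AF, NP) must be present")
  }
  counts <- SummarizedExperiment::assay(sce, "counts")
  expressed <- rowSums(counts) > 0
  nDropped <- sum(!expressed)
  if (nDropped > 0L) {
    msgf("dropping %d gene(s) expressed in zero cells", nDropped)
    sce <- sce[expressed, ]
  }
  genes <- rownames(sce)
  sumLfc <- numeric(length(genes))
  sumNlp <- numeric(length(genes))
  for (r in seq_len(nPermutations)) {
    pooled <- poolCells(sce, poolSize = poolSize, permutationIndex = r,
                        seed = seed)
    pm <- SummarizedExperiment::assay(pooled, "counts")
    norm <- if (normalize == "ratio") {
      sizeFactorNormalize(pm)
    } else {
      cpmNormalize(pm, scale = if (normalize == "cpm") cpmScale
                               else median(colSums(pm)))
    }
    grp <- SummarizedExperiment::colData(pooled)$compartment
    phi <- estimateCommonDispersion(norm, grp)$common
    res <- .nbLRTMatrix(norm, isB = grp == "NP", phi = phi,
                        priorCount = priorCount)
    sumLfc <- sumLfc + res$log2FC
    sumNlp <- sumNlp + (-log10(pmax(res$p, .Machine$double.xmin)))
  }
  meanLfc <- sumLfc / nPermutations
  meanNlp <- sumNlp / nPermutations
  combinedP <- pmin(1, 10^(-meanNlp))
  q <- bhFDR(combinedP)
  tab <- data.frame(
    gene = genes,
    meanLog2FC = meanLfc,
    meanNegLog10P = meanNlp,
    combinedP = combinedP,
    q = q,
    significant = q < fdrAlpha,
    direction = ifelse(meanLfc > 0, "NP-high",
                       ifelse(meanLfc < 0, "AF-high", "none")),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  methods::new("DEResult", table = tab,
               params = list(poolSize = poolSize,
                             nPermutations = nPermutations,
                             fdrAlpha = fdrAlpha, seed = seed,
                             cpmScale = cpmScale, priorCount = priorCount,
                             normalize = normalize),
               nDropped = nDropped)
}

#' Export a DEResult as a DE table
#'
#' Reshapes a [DEResult-class] into the generic (gene, logFC, p, q) DE-table
#' layout used by the cross-platform module and the on-disk TSV format.
#'
#' @param de a `DEResult`.
#' @return `data.frame` with columns `gene`, `logFC`, `p`, `q`,
#'   `significant`, `direction`.
#' @export
asDETable <- function(de) {
  tab <- deTable(de)
  data.frame(gene = tab$gene, logFC = tab$meanLog2FC, p = tab$combinedP,
             q = tab$q, significant = tab$significant,
             direction = tab$direction, stringsAsFactors = FALSE)
}
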