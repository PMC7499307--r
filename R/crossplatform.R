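#' Two-layer Venn partition of a pair of DE tables
#'
#' Set algebra on the detected and significant layers of two
#' differential-expression tables (e.g. a single-cell dataset vs a
#' microarray compendium): counts of genes detected only in A, only in B,
#' and in common; likewise for the significant genes; and the
#' "novel-to-A" count, significant-in-A minus significant-in-common.
#'
#' @param tableA,tableB DE `data.frame`s with at least a `gene` column.
#' @param sigA,sigB character vectors of the significant genes of each
#'   table (defaults: `q < 0.05` when a `q` column exists, otherwise
#'   `p < 0.05`).
#' @return named list of counts: `detectedA`, `detectedB`,
#'   `detectedCommon`, `detectedOnlyA`, `detectedOnlyB`, `sigA`, `sigB`,
#'   `sigCommon`, `sigOnlyA`, `sigOnlyB`, `novelToA`.
#' @export
vennPartition <- function(tableA, tableB,
                          sigA = defaultSigGenes(tableA),
                          sigB = defaultSigGenes(tableB)) {
  gA <- unique(canonicalizeSymbols(tableA$gene))
  gB <- unique(canonicalizeSymbols(tableB$gene))
  sA <- intersect(unique(canonicalizeSymbols(sigA)), gA)
  sB <- intersect(unique(canonicalizeSymbols(sigB)), gB)
  detectedCommon <- length(intersect(gA, gB))
  sigCommon <- length(intersect(sA, sB))
  list(detectedA = length(gA), detectedB = length(gB),
       detectedCommon = detectedCommon,
       detectedOnlyA = length(gA) - detectedCommon,
       detectedOnlyB = length(gB) - detectedCommon,
       sigA = length(sA), sigB = length(sB), sigCommon = sigCommon,
       sigOnlyA = length(sA) - sigCommon,
       sigOnlyB = length(sB) - sigCommon,
       novelToA = length(sA) - sigCommon)
}

defaultSigGenes <- function(tab) {
  if ("q" %in% names(tab)) tab$gene[tab$q < 0.05]
  else tab$gene[tab$p < 0.05]
}

#' Filter a microarray DE table for significant genes
#'
#' Keeps rows with `p < pMax` and fold change above `logfcMin` (strict
#' inequalities). By default the magnitude `|logFC|` is compared so both
#' directions are retained; `signed = TRUE` compares the signed value
#' instead.
#'
#' @param table DE `data.frame` with columns `gene`, `logFC`, `p`.
#' @param pMax p-value threshold (exclusive), default 0.05.
#' @param logfcMin fold-change threshold (exclusive), default 1.
#' @param signed compare signed `logFC` instead of `|logFC|`.
#' @return the filtered `data.frame`.
#' @export
filterMicroarrayDEGs <- function(table, pMax = 0.05, logfcMin = 1,
                                 signed = FALSE) {
  need <- c("gene", "logFC", "p")
  if (!all(need %in% names(table))) {
    stopf("DE table needs columns %s", paste(need, collapse = ", "))
  }
  lfc <- if (signed) table$logFC else abs(table$logFC)
  out <- table[table$p < pMax & lfc > logfcMin, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman correlation of fold changes between two DE tables
#'
#' Average-rank Spearman correlation of the log fold changes of the genes
#' common to both tables (optionally restricted to a supplied subset, e.g.
#' the common significant genes), with the p value from the t
#' approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}.
#'
#' @param tableA,tableB DE `data.frame`s with columns `gene`, `logFC`.
#' @param genes optional character vector restricting the comparison.
#' @return list with `rho`, `p`, and `n` (number of gene pairs used).
#' @export
spearmanLogFC <- function(tableA, tableB, genes = NULL) {
  a <- tableA[, c("gene", "logFC")]
  b <- tableB[, c("gene", "logFC")]
  a$gene <- canonicalizeSymbols(a$gene)
  b$gene <- canonicalizeSymbols(b$gene)
  m <- merge(a, b, by = "gene", suffixes = c("A", "B"))
  if (!is.null(genes)) {
    m <- m[m$gene %in% canonicalizeSymbols(genes), , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 3L) stopf("fewer than 3 common genes (%d)", n)
  ra <- rank(m$logFCA, ties.method = "average")
  rb <- rank(m$logFCB, ties.method = "average")
  rho <- cor(ra, rb)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' qPCR fold change of a target gene in a test condition relative to a
#' control condition, each normalized to a reference gene:
#' \deqn{FC = 2^{-((Ct_{target,test} - Ct_{ref,test}) -
#'               (Ct_{target,ctrl} - Ct_{ref,ctrl}))}}
#'
#' @param ctTargetTest,ctRefTest,ctTargetCtrl,ctRefCtrl cycle-threshold
#'   values (finite; vectors recycle).
#' @return the fold change(s).
#' @examples
#' deltaDeltaCt(20, 15, 22, 15)   # 4
#' @export
deltaDeltaCt <- function(ctTargetTest, ctRefTest, ctTargetCtrl, ctRefCtrl) {
  vals <- c(ctTargetTest, ctRefTest, ctTargetCtrl, ctRefCtrl)
  if (any(!is.finite(vals))) stopf("Ct values must be finite")
  ddct <- (ctTargetTest - ctRefTest) - (ctTargetCtrl - ctRefCtrl)
  2^(-ddct)
}
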