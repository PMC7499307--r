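#' Upper-tail (cumulative) hypergeometric test
#'
#' Probability of observing `k` or more annotated genes in a query of size
#' `n` drawn from a universe of `N` genes of which `K` carry the
#' annotation:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}
#' computed stably in log space via [stats::phyper()].
#'
#' @param k overlap count.
#' @param K annotated genes in the universe (set size).
#' @param n query size.
#' @param N universe size.
#' @return the upper-tail p value (1 when `k = 0`).
#' @examples
#' hypergeometricTest(3, 5, 4, 10)
#' @export
hypergeometricTest <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    stopf("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set for over-representation in a query list with the
#' upper-tail hypergeometric test against a stated universe, then adjusts
#' across tested sets with Benjamini-Hochberg. Query genes outside the
#' universe are dropped with a message; sets are restricted to the universe
#' and sets with no universe member are skipped.
#'
#' @param query character vector of query gene symbols (e.g. the
#'   significant DEGs of one compartment).
#' @param sets named list of character vectors (e.g. from [readGMT()] or
#'   [simulateGeneSets()]).
#' @param universe character vector of background gene symbols; typically
#'   all genes detected in the DE analysis.
#' @return `data.frame` sorted by q then p with columns `set`, `k`, `K`,
#'   `n`, `N`, `p`, `q`, `genes` (overlap, comma-separated).
#' @export
enrichGeneSets <- function(query, sets, universe) {
  universe <- unique(canonicalizeSymbols(universe))
  if (length(universe) == 0L) stopf("empty universe")
  query <- unique(canonicalizeSymbols(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    msgf("dropping %d query gene(s) outside the universe", length(outside))
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    mem <- intersect(unique(canonicalizeSymbols(sets[[nm]])), universe)
    if (length(mem) == 0L) return(NULL)
    hit <- intersect(mem, query)
    data.frame(set = nm, k = length(hit), K = length(mem), n = n, N = N,
               p = hypergeometricTest(length(hit), length(mem), n, N),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), genes = character(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bhFDR(out$p)
  out <- out[order(out$q, out$p, out$set), c("set", "k", "K", "n", "N",
                                             "p", "q", "genes")]
  rownames(out) <- NULL
  out
}

#' Matrisome landscape of a differential-expression result
#'
#' Splits the significant genes by direction (AF-high vs NP-high), then by
#' matrisome division (core matrisome vs matrisome-associated) and category
#' (ECM glycoproteins, collagens, proteoglycans | ECM-affiliated proteins,
#' ECM regulators, secreted factors), mirroring the ECM-landscape profiling
#' of disc compartments. Significant genes absent from the category table
#' are counted as unclassified.
#'
#' @param de a [DEResult-class] (or a DE table `data.frame` with columns
#'   `gene`, `logFC`, `significant`, `direction`).
#' @param categories category `data.frame` as returned by
#'   [readCategoryTable()] (columns `gene`, `division`, `category`).
#' @return list with `counts` (compartment x division x category tallies,
#'   long format), `assignment` (per-gene table carrying `log2FC` and
#'   `log10FC` for heatmap export), and `unclassified` (per-compartment
#'   counts of significant genes without a category).
#' @export
classifyMatrisome <- function(de, categories) {
  validateCategories(categories)
  tab <- if (methods::is(de, "DEResult")) asDETable(de) else de
  sig <- tab[tab$significant %in% TRUE, , drop = FALSE]
  sig$gene <- canonicalizeSymbols(sig$gene)
  m <- merge(sig, categories, by = "gene")
  compartment <- sub("-high$", "", m$direction)
  assignment <- data.frame(gene = m$gene, compartment = compartment,
                           division = m$division, category = m$category,
                           log2FC = m$logFC,
                           log10FC = m$logFC * log10(2),
                           stringsAsFactors = FALSE)
  assignment <- assignment[order(assignment$compartment,
                                 assignment$division,
                                 assignment$category, assignment$gene), ]
  rownames(assignment) <- NULL
  grid <- expand.grid(compartment = c("AF", "NP"),
                      category = names(.matrisomeCategories),
                      stringsAsFactors = FALSE)
  grid$division <- unname(.matrisomeCategories[grid$category])
  grid$n <- mapply(function(co, ca) {
    sum(assignment$compartment == co & assignment$category == ca)
  }, grid$compartment, grid$category)
  counts <- grid[order(grid$compartment, grid$division, grid$category),
                 c("compartment", "division", "category", "n")]
  rownames(counts) <- NULL
  unclassified <- vapply(c(AF = "AF-high", NP = "NP-high"), function(d) {
    sum(!(sig$gene[sig$direction == d] %in% categories$gene))
  }, numeric(1))
  list(counts = counts, assignment = assignment,
       unclassified = unclassified)
}

#' Map differentially expressed genes onto pathway gene sets
#'
#' Intersects the significant genes of a DE result with each pathway set
#' (e.g. glycolysis, TCA cycle, electron transport chain, pyruvate
#' metabolism) and attaches signed fold changes on the log10 scale for
#' heatmap export. A gene belonging to several pathways appears once per
#' pathway.
#'
#' @param de a [DEResult-class] or DE table (see [classifyMatrisome()]).
#' @param pathwaySets named list of character vectors.
#' @return `data.frame` with columns `pathway`, `gene`, `log2FC`,
#'   `log10FC`, `direction`.
#' @export
mapPathwayGenes <- function(de, pathwaySets) {
  tab <- if (methods::is(de, "DEResult")) asDETable(de) else de
  sig <- tab[tab$significant %in% TRUE, , drop = FALSE]
  sig$gene <- canonicalizeSymbols(sig$gene)
  rows <- lapply(names(pathwaySets), function(nm) {
    mem <- unique(canonicalizeSymbols(pathwaySets[[nm]]))
    hit <- sig[sig$gene %in% mem, , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    data.frame(pathway = nm, gene = hit$gene, log2FC = hit$logFC,
               log10FC = hit$logFC * log10(2), direction = hit$direction,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(pathway = character(0), gene = character(0),
                      log2FC = numeric(0), log10FC = numeric(0),
                      direction = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pathway, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Annotate a DE result with a transcription-factor list
#'
#' Intersects the significant genes with a list of annotated DNA-binding
#' transcription factors and splits the hits by direction, carrying fold
#' change and q value -- the per-compartment TF tables of the analysis.
#'
#' @param de a [DEResult-class] or DE table.
#' @param tfList character vector of TF symbols.
#' @return list with elements `AF` and `NP`, each a `data.frame` with
#'   columns `gene`, `logFC`, `q`.
#' @export
annotateTFs <- function(de, tfList) {
  tab <- if (methods::is(de, "DEResult")) asDETable(de) else de
  tfList <- unique(canonicalizeSymbols(tfList))
  sig <- tab[tab$significant %in% TRUE, , drop = FALSE]
  sig$gene <- canonicalizeSymbols(sig$gene)
  pick <- function(d) {
    hit <- sig[sig$direction == d & sig$gene %in% tfList, , drop = FALSE]
    out <- data.frame(gene = hit$gene, logFC = hit$logFC, q = hit$q,
                      stringsAsFactors = FALSE)
    out[order(out$q, out$gene), , drop = FALSE]
  }
  list(AF = pick("AF-high"), NP = pick("NP-high"))
}
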