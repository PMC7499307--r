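#' Filter a regulon table by normalized enrichment score
#'
#' Keeps motif/TF-target associations with NES strictly above `nesMin`
#' (default 3, the conventional high-confidence cut-off for motif
#' enrichment).
#'
#' @param table regulon `data.frame` with columns `tf`, `target`, `nes`
#'   (see [readRegulons()]).
#' @param nesMin NES threshold (exclusive).
#' @return the filtered `data.frame`.
#' @export
filterRegulons <- function(table, nesMin = 3) {
  need <- c("tf", "target", "nes")
  if (!all(need %in% names(table))) {
    stopf("regulon table needs columns %s", paste(need, collapse = ", "))
  }
  out <- table[table$nes > nesMin, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the signature transcription factor for a gene set
#'
#' Identifies the TF whose (pre-filtered) regulon covers the most genes of
#' a query set -- typically the members of a top MCODE complex -- and
#' returns the TF-to-target edge list of the covered genes. Ties are broken
#' by higher maximal NES, then lexicographic TF name, so selection is
#' deterministic and invariant to row order. When no TF covers any query
#' gene an empty result is returned (not an error).
#'
#' @param queryGenes character vector of query gene symbols.
#' @param regulons regulon `data.frame`, already filtered with
#'   [filterRegulons()].
#' @return list with `tf` (selected symbol or `NA`), `targets` (covered
#'   query genes), `nes` (maximal supporting NES), `edges` (`data.frame`
#'   tf/target/nes), and `ranking` (all candidate TFs with coverage and
#'   NES, ordered by coverage and, as an alternative view, by NES).
#' @export
selectSignatureTF <- function(queryGenes, regulons) {
  queryGenes <- unique(canonicalizeSymbols(queryGenes))
  regulons$tf <- canonicalizeSymbols(regulons$tf)
  regulons$target <- canonicalizeSymbols(regulons$target)
  hits <- regulons[regulons$target %in% queryGenes, , drop = FALSE]
  emptyRanking <- data.frame(tf = character(0), coverage = integer(0),
                             maxNES = numeric(0))
  if (nrow(hits) == 0L) {
    return(list(tf = NA_character_, targets = character(0),
                nes = NA_real_,
                edges = hits[, c("tf", "target", "nes"), drop = FALSE],
                ranking = emptyRanking))
  }
  cov <- vapply(split(hits$target, hits$tf),
                function(x) length(unique(x)), integer(1))
  maxNes <- vapply(split(hits$nes, hits$tf), max, numeric(1))
  ranking <- data.frame(tf = names(cov), coverage = unname(cov),
                        maxNES = unname(maxNes), stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$coverage, -ranking$maxNES, ranking$tf), ]
  rownames(ranking) <- NULL
  ranking$nesRank <- rank(-ranking$maxNES, ties.method = "min")
  best <- ranking$tf[1L]
  edges <- hits[hits$tf == best, c("tf", "target", "nes"), drop = FALSE]
  edges <- edges[order(edges$target), ]
  rownames(edges) <- NULL
  list(tf = best, targets = sort(unique(edges$target)),
       nes = max(edges$nes), edges = edges, ranking = ranking)
}
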