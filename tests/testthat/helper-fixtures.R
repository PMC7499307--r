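## Small deterministic fixtures built in code.

## A tiny SingleCellExperiment with hand-set counts and labels.
makeSCE <- function(counts, compartment, donor = "donor1") {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("C%03d", seq_len(ncol(counts)))
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      compartment = compartment,
      donor = rep_len(donor, ncol(counts)),
      row.names = colnames(counts)))
}

## igraph from a two-column edge matrix of vertex names.
makeGraph <- function(edges, vertices = NULL) {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  if (!is.null(vertices)) {
    g <- igraph::add_vertices(g, length(setdiff(vertices, igraph::V(g)$name)),
                              name = setdiff(vertices, igraph::V(g)$name))
  }
  g
}

## Interaction data.frame from an edge matrix, uniform score.
edgeTable <- function(edges, score = 0.9) {
  data.frame(gene_a = edges[, 1], gene_b = edges[, 2],
             combined_score = score, stringsAsFactors = FALSE)
}

## Brute-force all-pairs shortest paths (Floyd-Warshall) on an igraph,
## independent of igraph's distance routines.
floydWarshall <- function(g) {
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  for (i in seq_len(nrow(el))) {
    d[el[i, 1], el[i, 2]] <- 1
    d[el[i, 2], el[i, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

## Brute-force upper-tail hypergeometric by enumerating all draws of size n
## from a universe of N with K marked elements.
enumHyper <- function(k, K, n, N) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}
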