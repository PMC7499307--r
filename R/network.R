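#' Build a score-filtered interaction network
#'
#' Keeps interactions with combined score strictly above `scoreThreshold`
#' (0.7 by default, the high-confidence STRING cut-off), optionally
#' restricted to a gene list (e.g. the DEGs of one compartment), and builds
#' a simple undirected weighted graph. Nodes lacking a connection are
#' excluded by construction.
#'
#' @param table interaction `data.frame` with columns `gene_a`, `gene_b`,
#'   `combined_score` (see [readInteractions()]).
#' @param scoreThreshold minimum combined score (exclusive).
#' @param restrictTo optional character vector; both endpoints must belong
#'   to it.
#' @return an [igraph::graph] with edge attribute `weight`.
#' @export
buildNetwork <- function(table, scoreThreshold = 0.7, restrictTo = NULL) {
  tab <- cleanInteractions(table)
  keep <- tab$combined_score > scoreThreshold
  if (!is.null(restrictTo)) {
    restrictTo <- canonicalizeSymbols(restrictTo)
    keep <- keep & tab$gene_a %in% restrictTo & tab$gene_b %in% restrictTo
  }
  tab <- tab[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = tab$gene_a, to = tab$gene_b,
               weight = tab$combined_score), directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Topology report of an interaction network
#'
#' Computes the NetworkAnalyzer-style summary of a simple undirected graph:
#' mean local clustering coefficient (nodes with fewer than two neighbours
#' contribute 0), number of connected components, diameter and radius (from
#' eccentricities on the largest component when the graph is disconnected),
#' Freeman degree centralization \eqn{\sum_i (d_{max} - d_i) / ((n-1)(n-2))},
#' the number and percentage of connected ordered vertex pairs (shortest
#' paths), mean degree ("average neighbors"), characteristic path length
#' (mean shortest-path length over connected ordered pairs), density
#' \eqn{2E / (n(n-1))}, and heterogeneity (population SD of the degree
#' divided by the mean degree). Edge weights are ignored.
#'
#' @param net an [igraph::graph], non-empty.
#' @return named list with elements `nNodes`, `nEdges`,
#'   `clusteringCoefficient`, `connectedComponents`, `diameter`, `radius`,
#'   `centralization`, `shortestPaths`, `shortestPathsPct`,
#'   `avgNeighbors`, `characteristicPathLength`, `density`,
#'   `heterogeneity`. `centralization` is `NA` for fewer than 3 nodes.
#' @export
topologyMetrics <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stopf("empty network")
  E <- igraph::ecount(net)
  deg <- igraph::degree(net)
  localCC <- igraph::transitivity(net, type = "local", isolates = "zero")
  localCC[is.na(localCC)] <- 0
  comp <- igraph::components(net)
  ## diameter/radius on the largest component (finite by construction)
  big <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  ecc <- igraph::eccentricity(big)
  d <- igraph::distances(net, weights = NA)
  finite <- is.finite(d) & row(d) != col(d)
  nPairs <- sum(finite)
  centralization <- if (n >= 3L) {
    sum(max(deg) - deg) / ((n - 1) * (n - 2))
  } else NA_real_
  popSd <- sqrt(mean((deg - mean(deg))^2))
  list(nNodes = as.integer(n),
       nEdges = as.integer(E),
       clusteringCoefficient = mean(localCC),
       connectedComponents = as.integer(comp$no),
       diameter = as.integer(max(ecc)),
       radius = as.integer(min(ecc)),
       centralization = centralization,
       shortestPaths = as.integer(nPairs),
       shortestPathsPct = 100 * nPairs / (n * (n - 1)),
       avgNeighbors = mean(deg),
       characteristicPathLength = mean(d[finite]),
       density = if (n > 1L) 2 * E / (n * (n - 1)) else 0,
       heterogeneity = if (mean(deg) > 0) popSd / mean(deg) else 0)
}

#' MCODE vertex weighting
#'
#' For each node v, takes the subgraph induced by the closed neighbourhood
#' N[v], finds the highest k for which that subgraph has a non-empty
#' k-core, and sets \eqn{weight(v) = k \times density} of that highest
#' k-core. Dense, mutually connected neighbourhoods therefore receive high
#' weights.
#'
#' @param net an [igraph::graph].
#' @return named numeric vector of vertex weights.
#' @export
mcodeVertexWeights <- function(net) {
  nms <- igraph::V(net)$name
  w <- vapply(seq_len(igraph::vcount(net)), function(v) {
    nb <- igraph::neighborhood(net, order = 1L, nodes = v)[[1L]]
    sub <- igraph::induced_subgraph(net, nb)
    if (igraph::ecount(sub) == 0L) return(0)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    coreSub <- igraph::induced_subgraph(sub, which(core >= kmax))
    nc <- igraph::vcount(coreSub)
    dens <- if (nc > 1L) {
      2 * igraph::ecount(coreSub) / (nc * (nc - 1))
    } else 0
    kmax * dens
  }, numeric(1))
  names(w) <- nms
  w
}

#' MCODE molecular-complex detection
#'
#' From-scratch implementation of the molecular complex detection
#' algorithm: vertices are weighted by the density of the highest k-core of
#' their closed neighbourhood ([mcodeVertexWeights()]); complexes are grown
#' breadth-first from the highest-weight unseen seed (ties broken
#' lexicographically for determinism), including neighbours whose weight is
#' at least `(1 - nodeScoreCutoff)` times the seed weight, up to
#' `maxDepth`; included nodes are marked seen so complexes are
#' node-disjoint. Post-processing removes members with in-complex degree
#' below 2 when `haircut` is on, and discards complexes lacking a
#' `kCore`-core. Each complex is scored as subgraph density times node
#' count and the list is returned sorted by score, descending.
#'
#' @param net an [igraph::graph].
#' @param degreeCutoff minimum degree for a node to seed a complex
#'   (default 2).
#' @param nodeScoreCutoff fraction of the seed weight a neighbour may fall
#'   short by and still be included (default 0.2).
#' @param haircut remove singly-connected complex members (default TRUE).
#' @param fluff unsupported MCODE branch, must remain FALSE.
#' @param kCore discard complexes without a k-core of this order
#'   (default 2).
#' @param maxDepth breadth-first search depth limit from the seed
#'   (default 100).
#' @return list of [McodeComplex-class] objects, highest score first.
#' @export
mcodeFindComplexes <- function(net, degreeCutoff = 2L,
                               nodeScoreCutoff = 0.2, haircut = TRUE,
                               fluff = FALSE, kCore = 2L,
                               maxDepth = 100L) {
  if (isTRUE(fluff)) stopf("the fluff post-processing branch is not supported")
  if (nodeScoreCutoff < 0 || nodeScoreCutoff > 1) {
    stopf("nodeScoreCutoff must lie in [0,1]")
  }
  n <- igraph::vcount(net)
  if (n == 0L || igraph::ecount(net) == 0L) return(list())
  w <- mcodeVertexWeights(net)
  deg <- igraph::degree(net)
  nms <- igraph::V(net)$name
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  seen <- rep(FALSE, n)
  ## seeds: eligible nodes by decreasing weight, name as tie-break
  ord <- order(-w, nms)
  ord <- ord[deg[ord] >= degreeCutoff]
  complexes <- list()
  for (s in ord) {
    if (seen[s]) next
    threshold <- (1 - nodeScoreCutoff) * w[s]
    membersIdx <- s
    seen[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0L && depth < maxDepth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!seen[u] && w[u] >= threshold) {
            seen[u] <- TRUE
            membersIdx <- c(membersIdx, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(net, membersIdx)
    if (haircut) {
      keep <- igraph::V(sub)[igraph::degree(sub) >= 2L]
      sub <- igraph::induced_subgraph(sub, keep)
    }
    if (igraph::vcount(sub) < 2L) next
    if (max(igraph::coreness(sub)) < kCore) next
    mem <- sort(igraph::V(sub)$name)
    complexes[[length(complexes) + 1L]] <- methods::new(
      "McodeComplex", members = mem,
      nEdges = as.numeric(igraph::ecount(sub)),
      score = scoreCluster(igraph::vcount(sub), igraph::ecount(sub)),
      seed = nms[s])
  }
  scores <- vapply(complexes, complexScore, numeric(1))
  complexes[order(-scores,
                  vapply(complexes, function(x) x@seed, character(1)))]
}

#' MCODE complex score
#'
#' Score of a complex with `n` nodes and `E` induced edges:
#' density times node count, \eqn{(2E / (n(n-1))) \times n}. A complete
#' graph on n nodes therefore scores exactly n; summaries report the score
#' to one decimal place.
#'
#' @param n number of nodes (>= 2).
#' @param E number of induced edges.
#' @return the score.
#' @examples
#' scoreCluster(26, 311)   # 24.88, printed as 24.9
#' scoreCluster(7, 20)     # 6.67, printed as 6.7
#' @export
scoreCluster <- function(n, E) {
  if (n < 2L) stopf("a cluster needs at least 2 nodes")
  if (E < 0 || E > choose(n, 2)) stopf("edge count incompatible with n")
  (2 * E / (n * (n - 1))) * n
}
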