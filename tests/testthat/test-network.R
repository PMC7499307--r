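test_that("network construction applies the strict score filter and restriction", {
  tab <- data.frame(gene_a = c("A", "B", "C", "D"),
                    gene_b = c("B", "C", "D", "E"),
                    combined_score = c(0.9, 0.7, 0.71, 0.2))
  net <- buildNetwork(tab, scoreThreshold = 0.7)
  ## strictly greater than: the 0.7 edge is dropped, isolates excluded
  expect_setequal(igraph::V(net)$name, c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(net), 2)
  expect_equal(igraph::ecount(buildNetwork(tab, scoreThreshold = 1)), 0)
  all4 <- buildNetwork(tab, scoreThreshold = 0)
  expect_equal(igraph::ecount(all4), 4)
  restricted <- buildNetwork(tab, scoreThreshold = 0,
                             restrictTo = c("A", "B", "C"))
  expect_setequal(igraph::V(restricted)$name, c("A", "B", "C"))
  ## node count equals endpoints of surviving edges, brute force
  withr::with_seed(6, {
    rt <- data.frame(gene_a = sample(LETTERS[1:10], 40, TRUE),
                     gene_b = sample(LETTERS[1:10], 40, TRUE),
                     combined_score = runif(40))
    rt <- rt[rt$gene_a != rt$gene_b, ]
    g <- buildNetwork(rt, scoreThreshold = 0.5)
    surv <- rt[rt$combined_score > 0.5, ]
    expect_setequal(igraph::V(g)$name, unique(c(surv$gene_a, surv$gene_b)))
  })
})

test_that("topology metrics reproduce closed forms on canonical graphs", {
  k4 <- makeGraph(t(combn(c("A", "B", "C", "D"), 2)))
  tk4 <- topologyMetrics(k4)
  expect_equal(tk4$density, 1)
  expect_equal(tk4$clusteringCoefficient, 1)
  expect_identical(tk4$diameter, 1L)
  expect_equal(tk4$heterogeneity, 0)
  expect_equal(tk4$centralization, 0)
  ## star with one hub and three leaves: Freeman's maximal configuration
  star <- makeGraph(cbind("HUB", c("L1", "L2", "L3")))
  ts <- topologyMetrics(star)
  expect_equal(ts$centralization, 1)
  expect_equal(ts$density, 0.5)
  expect_equal(ts$clusteringCoefficient, 0)
  ## path A-B-C: characteristic path length 4/3, radius 1, diameter 2
  path <- makeGraph(rbind(c("A", "B"), c("B", "C")))
  tp <- topologyMetrics(path)
  expect_equal(tp$characteristicPathLength, 4 / 3)
  expect_identical(tp$diameter, 2L)
  expect_identical(tp$radius, 1L)
  expect_equal(tp$shortestPathsPct, 100)
  ## two components: percentages and component count reflect disconnection
  two <- makeGraph(rbind(c("A", "B"), c("C", "D")))
  tt <- topologyMetrics(two)
  expect_identical(tt$connectedComponents, 2L)
  expect_equal(tt$shortestPathsPct, 100 * 4 / 12)
})

test_that("topology metrics agree with brute-force recomputation on random graphs", {
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(4:12, 1)
      g <- igraph::sample_gnp(n, runif(1, 0.2, 0.8))
      igraph::V(g)$name <- paste0("N", seq_len(n))
      if (igraph::ecount(g) == 0) next
      g <- igraph::induced_subgraph(g, which(igraph::degree(g) > 0))
      n <- igraph::vcount(g)
      topo <- topologyMetrics(g)
      d <- floydWarshall(g)
      deg <- rowSums(d == 1)
      finite <- is.finite(d) & row(d) != col(d)
      expect_equal(topo$density, sum(deg) / (n * (n - 1)))
      expect_equal(topo$avgNeighbors, mean(deg))
      expect_equal(topo$characteristicPathLength, mean(d[finite]))
      expect_equal(topo$shortestPaths, sum(finite))
      expect_equal(topo$heterogeneity,
                   sqrt(mean((deg - mean(deg))^2)) / mean(deg))
      if (n >= 3) {
        expect_equal(topo$centralization,
                     sum(max(deg) - deg) / ((n - 1) * (n - 2)))
      }
      ## components via reachability; diameter/radius on the largest one
      reach <- is.finite(d)
      comp <- rep(NA_integer_, n)
      cid <- 0L
      for (v in seq_len(n)) {
        if (is.na(comp[v])) { cid <- cid + 1L; comp[reach[v, ]] <- cid }
      }
      expect_identical(topo$connectedComponents, max(comp))
      big <- which(comp == which.max(tabulate(comp)))
      ecc <- apply(d[big, big, drop = FALSE], 1, max)
      expect_equal(topo$diameter, max(ecc))
      expect_equal(topo$radius, min(ecc))
      ## local clustering: triangles / possible neighbour pairs
      cc <- vapply(seq_len(n), function(v) {
        nb <- which(d[v, ] == 1)
        if (length(nb) < 2) return(0)
        sub <- d[nb, nb, drop = FALSE] == 1
        sum(sub) / 2 / choose(length(nb), 2)
      }, numeric(1))
      expect_equal(topo$clusteringCoefficient, mean(cc))
    }
  })
})

test_that("MCODE vertex weights equal exhaustive highest-k-core search", {
  ## K4: every closed neighbourhood is K4, 3-core density 1, weight 3
  k4 <- makeGraph(t(combn(c("A", "B", "C", "D"), 2)))
  expect_equal(unname(mcodeVertexWeights(k4)), rep(3, 4))
  ## isolated edge: closed neighbourhood K2, 1-core density 1, weight 1
  e <- makeGraph(rbind(c("X", "Y")))
  expect_equal(unname(mcodeVertexWeights(e)), c(1, 1))
  ## brute-force oracle on random graphs with <= 8 nodes: kmax is the best
  ## min-degree over all subsets of N[v]; the core is the union of subsets
  ## attaining it
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- sample(4:8, 1)
      g <- igraph::sample_gnp(n, 0.5)
      igraph::V(g)$name <- paste0("V", 1:n)
      w <- mcodeVertexWeights(g)
      adjm <- as.matrix(igraph::as_adjacency_matrix(g))
      for (v in seq_len(n)) {
        nb <- sort(unique(c(v, which(adjm[v, ] == 1))))
        best <- 0; coreNodes <- integer(0)
        for (sz in seq_along(nb)) {
          for (ss in as.data.frame(combn(nb, sz))) {
            sub <- adjm[ss, ss, drop = FALSE]
            mindeg <- if (length(ss) == 1) 0 else min(rowSums(sub))
            if (mindeg > best) { best <- mindeg; coreNodes <- ss }
            else if (mindeg == best && best > 0) {
              coreNodes <- union(coreNodes, ss)
            }
          }
        }
        expWeight <- if (best == 0) 0 else {
          m <- length(coreNodes)
          dens <- sum(adjm[coreNodes, coreNodes]) / (m * (m - 1))
          best * dens
        }
        expect_equal(unname(w[v]), expWeight, tolerance = 1e-12)
      }
    }
  })
})

test_that("MCODE recovers planted dense components joined by a bridge", {
  k6 <- t(combn(paste0("A", 1:6), 2))
  k4 <- t(combn(paste0("B", 1:4), 2))
  bridge <- rbind(c("A1", "B1"))
  g <- makeGraph(rbind(k6, k4, bridge))
  found <- mcodeFindComplexes(g)
  expect_length(found, 2)
  expect_setequal(members(found[[1]]), paste0("A", 1:6))
  expect_setequal(members(found[[2]]), paste0("B", 1:4))
  expect_equal(complexScore(found[[1]]), 6)
  expect_equal(complexScore(found[[2]]), 4)
  ## complexes are node-disjoint and deterministic
  again <- mcodeFindComplexes(g)
  expect_identical(lapply(found, members), lapply(again, members))
  expect_length(intersect(members(found[[1]]), members(found[[2]])), 0)
  ## edgeless after filtering: empty result
  expect_length(mcodeFindComplexes(makeGraph(rbind(c("A", "B")))), 0)
})

test_that("haircut trims singly-connected members", {
  ## K4 with a pendant vertex: a permissive score cutoff lets the pendant
  ## join the growing complex, and only the haircut removes it
  k4 <- t(combn(paste0("A", 1:4), 2))
  g <- makeGraph(rbind(k4, c("A1", "P")))
  loose <- mcodeFindComplexes(g, nodeScoreCutoff = 0.9, haircut = FALSE)
  expect_setequal(members(loose[[1]]), c(paste0("A", 1:4), "P"))
  trimmed <- mcodeFindComplexes(g, nodeScoreCutoff = 0.9, haircut = TRUE)
  expect_length(trimmed, 1)
  expect_setequal(members(trimmed[[1]]), paste0("A", 1:4))
})

test_that("complex scores equal density times node count", {
  expect_equal(round(scoreCluster(26, 311), 1), 24.9)
  expect_equal(round(scoreCluster(7, 20), 1), 6.7)
  for (n in 2:10) expect_equal(scoreCluster(n, choose(n, 2)), n)
  expect_error(scoreCluster(1, 0), "at least 2")
  expect_error(scoreCluster(4, 10), "incompatible")
})
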