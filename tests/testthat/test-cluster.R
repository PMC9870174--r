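two_cliques_bridge_edge <- function() {
  g <- igraph::make_empty_graph(8, directed = FALSE)
  igraph::V(g)$name <- c(paste0("a", 1:4), paste0("b", 1:4))
  for (i in 1:3) for (j in (i + 1):4)
    g <- igraph::add_edges(g, c(i, j, 4 + i, 4 + j))
  igraph::add_edges(g, c(1, 5))
}

test_that("NBR-Clust separates the two cliques and reassigns the bridge node", {
  br <- bridge_graph()
  for (m in c("vat", "integrity")) {
    p <- nbr_clust(br, m)
    expect_setequal(names(p$labels), igraph::V(br)$name)
    expect_equal(p$n_clusters, 2)
    expect_equal(length(unique(p$labels[paste0("a", 1:5)])), 1)
    expect_equal(length(unique(p$labels[paste0("b", 1:5)])), 1)
    expect_true(p$labels["bridge"] %in% p$labels[c("a1", "b1")])
    expect_identical(p$attack_set, "bridge")
  }
})

test_that("a clique stays a single cluster under NBR-Clust", {
  k6 <- clique_graph(6)
  p <- nbr_clust(k6, "vat")
  expect_equal(p$n_clusters, 1)
  p2 <- nbr_clust(k6, "integrity")
  expect_equal(p2$n_clusters, 1)
})

test_that("louvain prefers the two-community split of two bridged cliques", {
  g <- two_cliques_bridge_edge()
  p <- louvain_partition(g, seed = 1)
  expect_equal(p$n_clusters, 2)
  memb <- p$labels[igraph::V(g)$name] + 1
  m_split <- igraph::modularity(g, memb)
  m_single <- igraph::modularity(g, rep(1, 8))
  expect_gt(m_split, m_single)
  expect_equal(m_single, 0)
  expect_error(louvain_partition(igraph::make_empty_graph(3, directed = FALSE)),
               "edge")
})

test_that("disconnected cliques each form their own community", {
  g1 <- clique_graph(4); g2 <- clique_graph(4)
  igraph::V(g2)$name <- paste0("m", 1:4)
  g <- igraph::disjoint_union(g1, g2)
  igraph::V(g)$name <- paste0("n", 1:8)
  p <- louvain_partition(g, seed = 2)
  expect_equal(p$n_clusters, 2)
  expect_equal(length(unique(p$labels[paste0("n", 1:4)])), 1)
})

test_that("leiden returns connected communities", {
  g <- two_cliques_bridge_edge()
  p <- leiden_partition(g, seed = 3)
  expect_equal(p$n_clusters, 2)
  for (s in 1:5) {
    gr <- random_connected_graph(25, seed = 300 + s)
    pr <- leiden_partition(gr, seed = s)
    for (cl in unique(pr$labels)) {
      memb <- names(pr$labels)[pr$labels == cl]
      expect_true(igraph::is_connected(igraph::induced_subgraph(gr, memb)))
    }
  }
})

test_that("partitions cover all nodes with contiguous labels from 0", {
  gr <- random_connected_graph(30, seed = 77)
  for (m in c("louvain", "leiden", "nbr_vat", "nbr_integrity")) {
    p <- cluster_graph(gr, m, seed = 5)
    expect_setequal(names(p$labels), igraph::V(gr)$name)
    expect_setequal(unique(unname(p$labels)), 0:(p$n_clusters - 1))
  }
})

test_that("modularity methods and NBR-integrity recover a planted 3-block graph", {
  skip_if_not_installed("mclust")
  res <- generate_planted_graph(45, 3, 0.6, 0.01, seed = 123)
  truth <- res$partition$labels
  for (m in c("louvain", "leiden", "nbr_integrity")) {
    p <- cluster_graph(res$graph, m, seed = 1)
    ari <- mclust::adjustedRandIndex(p$labels[names(truth)], truth)
    expect_gte(ari, 0.9)
  }
})

test_that("NBR-VAT cuts along planted block boundaries", {
  # VAT rewards cheap cuts: at these benchmark densities its minimum is
  # often the single cheapest boundary (2 clusters), so we assert that
  # the cut respects the planted blocks rather than full recovery
  res <- generate_planted_graph(45, 3, 0.6, 0.01, seed = 123)
  truth <- res$partition$labels
  p <- cluster_graph(res$graph, "nbr_vat", seed = 1)
  expect_gte(p$n_clusters, 2)
  # each recovered cluster should be (nearly) a union of planted blocks:
  # at most 2 of its members disagree with the block majority
  for (cl in unique(p$labels)) {
    memb <- names(p$labels)[p$labels == cl]
    blocks <- truth[memb]
    agree <- sum(vapply(split(names(truth), truth), function(bl)
      max(0L, length(intersect(bl, memb)) *
            (length(intersect(bl, memb)) > length(bl) / 2)), integer(1)))
    expect_gte(agree, length(memb) - 2)
  }
})

test_that("clustering a graph is reproducible under a fixed seed", {
  gr <- random_connected_graph(40, seed = 55)
  for (m in c("louvain", "leiden")) {
    p1 <- cluster_graph(gr, m, seed = 11)
    p2 <- cluster_graph(gr, m, seed = 11)
    expect_identical(p1$labels, p2$labels)
  }
})
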