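test_that("BFS distances match the Floyd-Warshall oracle", {
  expect_equal(bfs_distances(path_graph(3), 1), c(0, 1, 2))
  for (seed in 1:5) {
    g <- random_connected_graph(15, 0.25, seed)
    D <- fw_distances(g)
    for (root in c(1, 7, 15)) {
      expect_equal(bfs_distances(g, root), unname(D[root, ]))
      expect_equal(bfs_distances(g, root),
                   vapply(seq_len(15), function(v)
                     bfs_distances(g, v)[root], 1))  # symmetry
    }
  }
})

test_that("BFS tree is a shortest-path tree with lowest-index parents", {
  # on a tree the BFS tree is the tree itself, re-rooted
  tr <- random_tree(10, 1)
  bt <- bfs_tree(tr, 3)
  for (v in setdiff(1:10, 3))
    expect_true(igraph::are_adjacent(tr, v, bt$parent[v]))

  # cycle of 4 rooted at 1: the antipodal node 3 gets its lowest neighbour 2
  bt4 <- bfs_tree(cycle_graph(4), 1)
  expect_equal(bt4$parent[3], 2L)

  for (seed in 1:5) {
    g <- random_connected_graph(20, 0.2, seed)
    bt <- bfs_tree(g, 5)
    d <- bfs_distances(g, 5)
    expect_equal(bt$depth, d)
    for (v in setdiff(seq_len(20), 5))
      expect_equal(d[bt$parent[v]], d[v] - 1)
  }
})

test_that("shortest-path enumeration matches the DFS oracle", {
  pe <- enumerate_shortest_paths(path_graph(4), 1, 4)
  expect_equal(pe$count, 1)
  expect_equal(pe$paths, list(1:4))

  pe4 <- enumerate_shortest_paths(cycle_graph(4), 1, 3)
  expect_equal(pe4$count, 2)
  expect_equal(length(pe4$paths), 2)
  expect_equal(pe4$length, 2)

  # complete bipartite K_{2,3}: two nodes on the 2-side, 3 paths of length 2
  kb <- igraph::make_full_bipartite_graph(2, 3)
  pe_b <- enumerate_shortest_paths(kb, 1, 2)
  expect_equal(pe_b$count, 3)
  expect_equal(length(pe_b$paths), 3)

  for (seed in 1:5) {
    g <- random_connected_graph(12, 0.3, seed)
    D <- fw_distances(g)
    pairs <- withr::with_seed(seed, cbind(sample.int(12, 4), sample.int(12, 4)))
    for (i in seq_len(nrow(pairs))) {
      u <- pairs[i, 1]; v <- pairs[i, 2]
      if (u == v) next
      oracle <- dfs_all_shortest_paths(g, u, v, D)
      pe <- enumerate_shortest_paths(g, u, v, cap = 1000)
      expect_equal(pe$count, length(oracle))
      expect_equal(pe$paths, oracle)
      # edge union equals the union over the oracle's paths
      o_edges <- unique(unlist(lapply(oracle, function(p)
        paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1])))))
      p_edges <- paste(pe$edge_union[, 1], pe$edge_union[, 2])
      expect_setequal(p_edges, o_edges)
    }
  }
})

test_that("the path cap truncates the listing but not the count", {
  kb <- igraph::make_full_bipartite_graph(2, 3)
  pe <- enumerate_shortest_paths(kb, 1, 2, cap = 2)
  expect_equal(length(pe$paths), 2)
  expect_equal(pe$count, 3)
  expect_equal(nrow(pe$edge_union), 6)  # exact despite the cap
})

test_that("path correlation is the shared-edge fraction", {
  expect_equal(path_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(path_correlation(c(1, 2, 4), c(1, 3, 4)), 0)
  expect_equal(path_correlation(c(1, 2, 3, 4), c(1, 2, 5, 4)), 1 / 3)
  expect_error(path_correlation(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("Jaccard index of edge sets", {
  ab <- rbind(c(1, 2)); bc <- rbind(c(2, 3)); cd <- rbind(c(3, 4))
  expect_equal(jaccard_edges(rbind(ab, bc), rbind(ab, bc)), 1)
  expect_equal(jaccard_edges(ab, cd), 0)
  expect_equal(jaccard_edges(rbind(ab, bc), rbind(bc, cd)), 1 / 3)
  expect_equal(jaccard_edges(ab[0, , drop = FALSE], ab[0, , drop = FALSE]), 0)
  # orientation is ignored
  expect_equal(jaccard_edges(rbind(c(2, 1)), ab), 1)
})

test_that("min-of-Gaussians moments: closed form and degenerate cases", {
  m <- min_gaussian_moments(0, 0, 1, 1, 0)
  expect_equal(m$ey, -sqrt(2) * stats::dnorm(0))
  expect_gt(m$variance, 0)

  # rho = 1 with equal sigmas: Y is X1 itself
  m2 <- min_gaussian_moments(3, 3, 2, 2, 1)
  expect_equal(m2$ey, 3)
  expect_equal(m2$variance, 4)

  # wide separation: the smaller-mean variable dominates
  m3 <- min_gaussian_moments(-5, 5, 1, 1, 0)
  expect_lt(abs(m3$ey - (-5)), 1e-4)
  expect_lt(abs(m3$variance - 1), 1e-3)

  expect_error(min_gaussian_moments(0, 0, 1, 1, 1.5), "rho")
})
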