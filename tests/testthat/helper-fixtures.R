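# Fixture graphs (built in code) and independent brute-force oracles used to
# check the package's path machinery and estimators.

path_graph <- function(n) {
  igraph::make_graph(as.vector(rbind(seq_len(n - 1), 2:n)),
                     n = n, directed = FALSE)
}
star_graph <- function(leaves) {
  igraph::make_graph(as.vector(rbind(1, 1 + seq_len(leaves))),
                     n = leaves + 1, directed = FALSE)
}
cycle_graph <- function(n) igraph::make_ring(n)

random_connected_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g)) return(g)
    }
  })
}

random_tree <- function(n, seed) {
  # random Pruefer sequence -> uniform labelled tree
  withr::with_seed(seed, {
    if (n == 2) return(path_graph(2))
    prufer <- sample.int(n, n - 2, replace = TRUE)
    igraph::make_from_prufer(prufer)
  })
}

# ---- independent oracles ------------------------------------------------

# All-pairs hop distances by Floyd-Warshall on the adjacency matrix.
fw_distances <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n))
    D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  D
}

# Enumerate ALL shortest u->v paths by depth-first search guided by a
# distance matrix (no predecessor-DAG machinery shared with the package).
dfs_all_shortest_paths <- function(g, u, v, D = fw_distances(g)) {
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  out <- list()
  walk <- function(x, acc) {
    if (x == v) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (w in sort(adj[[x]]))
      if (D[w, v] == D[x, v] - 1) walk(w, c(acc, w))
  }
  walk(u, u)
  out
}

# Betweenness by explicit path counting: for every ordered pair (i, j) count
# shortest paths and those through v.
brute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  D <- fw_distances(g)
  btw <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !is.finite(D[i, j])) next
    paths <- dfs_all_shortest_paths(g, i, j, D)
    interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(interior))
      btw <- btw + tabulate(interior, n) / length(paths)
  }
  btw
}

# ---- Gaussian tree-delay generator (test data, not an oracle) -----------

# Draws i.i.d. N(mu, sigma^2) delays per tree edge from `source`; a node's
# arrival time is the sum along the unique tree path.
gaussian_tree_times <- function(tree, source, mu, sigma) {
  el <- igraph::as_edgelist(tree, names = FALSE)
  delay <- stats::rnorm(nrow(el), mu, sigma)
  n <- igraph::vcount(tree)
  times <- rep(NA_real_, n)
  times[source] <- 0
  adj_e <- lapply(seq_len(n), function(v)
    which(el[, 1] == v | el[, 2] == v))
  queue <- source
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (e in adj_e[[x]]) {
      other <- setdiff(el[e, ], x)
      if (is.na(times[other])) {
        times[other] <- times[x] + delay[e]
        queue <- c(queue, other)
      }
    }
  }
  times
}

# Exhaustive maximum-likelihood source estimate on a tree under Gaussian
# per-link delays: maximises the log-likelihood of the reference-based delay
# vector, with the covariance built from explicit edge-set intersections of
# the unique tree paths (independent of the package's scoring route).
tree_ml_argmax <- function(tree, obs_nodes, obs_times, mu, sigma2) {
  n <- igraph::vcount(tree)
  D <- igraph::distances(tree)
  ref <- obs_nodes[which.min(obs_times)]
  oth <- setdiff(obs_nodes, ref)
  d <- obs_times[match(oth, obs_nodes)] - obs_times[match(ref, obs_nodes)]
  edge_sets <- lapply(oth, function(o) {
    p <- igraph::shortest_paths(tree, ref, o)$vpath[[1]]
    p <- as.integer(p)
    paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]))
  })
  m <- length(oth)
  Lambda <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m))
    Lambda[a, b] <- sigma2 * length(intersect(edge_sets[[a]], edge_sets[[b]]))
  Li <- solve(Lambda + diag(1e-12, m))
  ll <- vapply(seq_len(n), function(s) {
    mu_s <- mu * (D[s, oth] - D[s, ref])
    -0.5 * drop(t(d - mu_s) %*% Li %*% (d - mu_s))
  }, 1)
  which(ll == max(ll))
}
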