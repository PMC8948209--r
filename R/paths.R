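# Shortest-path machinery shared by the placement and localisation methods.

# Sorted integer adjacency list; ascending order makes every tie-break and
# enumeration order deterministic.
sorted_adj <- function(g) {
  lapply(igraph::as_adj_list(g), function(x) sort(as.integer(x)))
}

#' Hop distances from a root node
#'
#' @param g An \code{igraph} graph.
#' @param root Vertex index.
#' @return Numeric vector of shortest-path hop counts from \code{root} to
#'   every vertex (\code{Inf} if unreachable).
#' @export
bfs_distances <- function(g, root) {
  as.vector(igraph::distances(g, v = root))
}

#' Deterministic BFS shortest-path tree
#'
#' Spanning shortest-path tree rooted at \code{root}; among multiple shortest
#' predecessors the lowest-index neighbour becomes the parent, so the tree is
#' deterministic for a fixed vertex indexing.
#'
#' @param g An \code{igraph} graph.
#' @param root Vertex index.
#' @return List with \code{parent} (integer vector, \code{NA} at the root)
#'   and \code{depth} (hop distance from the root).
#' @export
bfs_tree <- function(g, root) {
  adj <- sorted_adj(g)
  d <- bfs_distances(g, root)
  bfs_tree_impl(adj, d, root)
}

bfs_tree_impl <- function(adj, d, root) {
  n <- length(adj)
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    if (v == root || !is.finite(d[v])) next
    nb <- adj[[v]]
    pred <- nb[d[nb] == d[v] - 1]
    parent[v] <- pred[1L]  # adj sorted ascending -> lowest index
  }
  list(parent = parent, depth = d, root = root)
}

# Tree distance between u and v from parent/depth vectors (climb to the LCA).
tree_distance <- function(parent, depth, u, v) {
  steps <- 0L
  while (depth[u] > depth[v]) { u <- parent[u]; steps <- steps + 1L }
  while (depth[v] > depth[u]) { v <- parent[v]; steps <- steps + 1L }
  while (u != v) { u <- parent[u]; v <- parent[v]; steps <- steps + 2L }
  steps
}

# Number of shortest paths from `root` to every node, by dynamic programming
# over the BFS level structure. Returned as doubles (counts can be huge).
sp_counts_from <- function(adj, d) {
  n <- length(adj)
  sigma <- numeric(n)
  ord <- order(d)
  for (v in ord) {
    if (!is.finite(d[v])) break
    if (d[v] == 0) { sigma[v] <- 1; next }
    nb <- adj[[v]]
    pred <- nb[d[nb] == d[v] - 1]
    sigma[v] <- sum(sigma[pred])
  }
  sigma
}

# Enumerate shortest u->v paths lexicographically (ascending vertex index)
# over the predecessor DAG, stopping after `cap` paths. d_v = distances to v.
enum_paths_impl <- function(adj, d_v, u, v, cap) {
  paths <- vector("list", 0)
  if (!is.finite(d_v[u])) return(paths)
  stack_path <- integer(d_v[u] + 1)
  walk <- function(x, pos) {
    stack_path[pos] <<- x
    if (x == v) {
      paths[[length(paths) + 1L]] <<- stack_path[seq_len(pos)]
      return(invisible())
    }
    nb <- adj[[x]]
    succ <- nb[d_v[nb] == d_v[x] - 1]
    for (w in succ) {
      if (length(paths) >= cap) return(invisible())
      walk(w, pos + 1L)
    }
  }
  if (is.finite(d_v[u])) walk(u, 1L)
  paths
}

# All edges lying on at least one shortest u->v path, as a 2-column matrix
# (each row an edge, smaller endpoint first). d_u, d_v: distances from u / v.
edges_on_paths <- function(el, d_u, d_v, L) {
  a <- el[, 1]; b <- el[, 2]
  on <- (d_u[a] + 1 + d_v[b] == L) | (d_u[b] + 1 + d_v[a] == L)
  el[on, , drop = FALSE]
}

#' Enumerate all shortest paths between two nodes
#'
#' Distinct shortest paths are enumerated deterministically (lexicographic by
#' vertex index) via the BFS predecessor DAG, with the listing truncated at
#' \code{cap}. The reported \code{count} is the exact number of shortest
#' paths (computed by dynamic programming, independent of the cap), and
#' \code{edge_union} is the exact set of edges lying on any shortest path,
#' also independent of the cap.
#'
#' @param g An \code{igraph} graph.
#' @param u,v Vertex indices (must be connected).
#' @param cap Maximum number of paths to materialise (default 64).
#' @return An object of class \code{path_ensemble}: list with
#'   \code{endpoints}, \code{paths} (list of vertex sequences),
#'   \code{edge_union} (2-column matrix), \code{count}, \code{length}.
#' @export
enumerate_shortest_paths <- function(g, u, v, cap = 64) {
  adj <- sorted_adj(g)
  d_v <- bfs_distances(g, v)
  d_u <- bfs_distances(g, u)
  if (!is.finite(d_v[u])) stop("nodes ", u, " and ", v, " are not connected")
  L <- d_v[u]
  sigma <- sp_counts_from(adj, d_u)
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  structure(list(endpoints = c(u, v),
                 paths = enum_paths_impl(adj, d_v, u, v, cap),
                 edge_union = edges_on_paths(el, d_u, d_v, L),
                 count = sigma[v],
                 length = L),
            class = "path_ensemble")
}

# Encode the edges of a path (vertex sequence) as comparable keys.
path_edge_keys <- function(p, n) {
  if (length(p) < 2) return(numeric(0))
  a <- p[-length(p)]; b <- p[-1]
  pmin(a, b) * (n + 1) + pmax(a, b)
}

#' Correlation between two shortest paths of equal length
#'
#' The fraction of edges the two paths share: (number of common edges) / L.
#' Used as the correlation coefficient between the Gaussian traversal times
#' of two parallel shortest paths.
#'
#' @param p1,p2 Vertex sequences of two equal-length paths.
#' @return A real in [0, 1].
#' @export
path_correlation <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("paths must have equal length")
  L <- length(p1) - 1
  if (L == 0) return(0)
  n <- max(p1, p2)
  length(intersect(path_edge_keys(p1, n), path_edge_keys(p2, n))) / L
}

#' Jaccard index of two edge sets
#'
#' |intersection| / |union|; two empty sets give 0 by convention.
#'
#' @param e1,e2 Edge sets as 2-column matrices (one edge per row, orientation
#'   ignored).
#' @return A real in [0, 1].
#' @export
jaccard_edges <- function(e1, e2) {
  key <- function(e) {
    if (is.null(e) || nrow(e) == 0) return(character(0))
    unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  k1 <- key(e1); k2 <- key(e2)
  u <- length(union(k1, k2))
  if (u == 0) return(0)
  length(intersect(k1, k2)) / u
}
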