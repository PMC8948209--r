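#' Generate a Barabasi-Albert preferential-attachment graph
#'
#' Grows a scale-free network by preferential attachment, starting from a
#' complete graph on \code{m + 1} nodes with \code{m = mean_degree / 2} edges
#' added per new node. The realised mean degree is close to \code{mean_degree}
#' (slightly below it for small \code{n_nodes}, since the first nodes attach
#' to fewer targets).
#'
#' @param n_nodes Number of nodes N (positive integer).
#' @param mean_degree Target mean degree; must be a positive even integer
#'   smaller than \code{n_nodes} (the attachment parameter is
#'   \code{mean_degree / 2}).
#' @param seed Optional integer seed for reproducibility.
#' @return A connected undirected \code{igraph} graph with vertex names
#'   \code{"1"..."N"}.
#' @export
generate_ba <- function(n_nodes, mean_degree, seed = NULL) {
  stopifnot(n_nodes >= 2, mean_degree >= 2)
  if (mean_degree %% 2 != 0)
    stop("mean_degree must be even (attachment parameter m = mean_degree/2)")
  if (mean_degree >= n_nodes)
    stop("mean_degree must be smaller than n_nodes")
  m <- mean_degree / 2
  gen <- function() {
    igraph::sample_pa(n_nodes, m = m, directed = FALSE,
                      start.graph = igraph::make_full_graph(m + 1),
                      algorithm = "psumtree")
  }
  g <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

#' Generate an Erdos-Renyi random graph (giant component)
#'
#' Draws G(N, p) with \code{p = mean_degree / (n_nodes - 1)}. If the draw is
#' disconnected, the largest connected component is retained and reindexed
#' (SI spreading cannot reach other components and distance-based scoring
#' needs finite distances); the fraction of discarded nodes is recorded in
#' the graph attribute \code{discarded_fraction}.
#'
#' @param n_nodes Number of nodes before component extraction.
#' @param mean_degree Target mean degree, in \code{(0, n_nodes - 1)}.
#' @param seed Optional integer seed.
#' @return An undirected connected \code{igraph} graph.
#' @export
generate_er <- function(n_nodes, mean_degree, seed = NULL) {
  stopifnot(n_nodes >= 2)
  if (mean_degree <= 0 || mean_degree >= n_nodes)
    stop("mean_degree must lie in (0, n_nodes - 1]")
  p <- min(1, mean_degree / (n_nodes - 1))
  gen <- function() igraph::sample_gnp(n_nodes, p)
  g <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  n0 <- igraph::vcount(g)
  if (!igraph::is_connected(g)) {
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  g <- igraph::set_graph_attr(g, "discarded_fraction",
                              1 - igraph::vcount(g) / n0)
  g
}

#' Read an undirected graph from a plain edge-list file
#'
#' One edge per line, two whitespace-separated node labels; lines starting
#' with \code{#} or \code{\%} are ignored (covers konect-style headers).
#' Duplicate and reversed edges are collapsed, self-loops dropped. Labels are
#' mapped to vertex indices \code{1..N} (numerically sorted when all labels
#' are integers, lexicographically otherwise); originals are kept in the
#' \code{name} vertex attribute.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple \code{igraph} graph.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|%)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("empty edge list: ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 2)
  if (length(bad))
    stop("malformed edge-list line ", idx[bad[1]], " in ", path)
  from <- vapply(toks, `[`, "", 1L)
  to <- vapply(toks, `[`, "", 2L)
  labels <- unique(c(from, to))
  labels <- if (!anyNA(suppressWarnings(as.numeric(labels)))) {
    labels[order(as.numeric(labels))]
  } else sort(labels)
  ends <- rbind(match(from, labels), match(to, labels))
  g <- igraph::graph_from_edgelist(t(ends), directed = FALSE)
  if (igraph::vcount(g) < length(labels))
    g <- igraph::add_vertices(g, length(labels) - igraph::vcount(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::V(g)$name <- labels
  g
}

#' Write a graph as a plain edge list
#'
#' Inverse of \code{\link{read_edge_list}}: one edge per line, two
#' whitespace-separated vertex names.
#'
#' @param g An \code{igraph} graph.
#' @param path Output file path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Iteratively prune low-degree nodes
#'
#' Removes every node with degree below \code{min_degree}, repeating until
#' none remain: removal lowers neighbours' degrees, so a single pass is not
#' enough (the cascading konect-style reduction). Remaining vertices are
#' reindexed; original labels stay in the \code{name} attribute.
#'
#' @param g An \code{igraph} graph.
#' @param min_degree Minimum degree to survive (>= 1).
#' @return The pruned graph.
#' @export
prune_low_degree <- function(g, min_degree) {
  stopifnot(min_degree >= 1)
  repeat {
    low <- which(igraph::degree(g) < min_degree)
    if (length(low) == 0) break
    g <- igraph::delete_vertices(g, low)
    if (igraph::vcount(g) == 0) stop("graph eliminated by pruning")
  }
  g
}

#' Summary statistics of a graph
#'
#' @param g An \code{igraph} graph.
#' @return A list with \code{n} (nodes), \code{e} (edges), \code{mean_degree}
#'   (2E/N) and \code{connected}.
#' @export
graph_stats <- function(g) {
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  list(n = n, e = e, mean_degree = 2 * e / n,
       connected = igraph::is_connected(g))
}
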