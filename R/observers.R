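# Observer placement strategies: betweenness centrality (BC), greedy high
# coverage rate (HCR), high variance observers / path covering (HVO), and
# uniform random (RND). All strategies return exactly k distinct vertex
# indices; every tie is broken by ascending vertex index so placements are
# deterministic for a fixed graph indexing.

#' Place observers at the k most central nodes (BC)
#'
#' Ranks nodes by betweenness centrality (the summed fraction of shortest
#' paths between all other node pairs passing through a node) and returns the
#' top k. The set objective is separable per node, so the optimum is the
#' top-k ranking.
#'
#' @param g An \code{igraph} graph.
#' @param k Number of observers, 1 <= k < N.
#' @return Integer vector of k vertex indices, ordered by decreasing
#'   centrality (ties by ascending index).
#' @export
place_bc <- function(g, k) {
  n <- igraph::vcount(g)
  stopifnot(k >= 1, k < n)
  btw <- igraph::betweenness(g, directed = FALSE)
  order(-btw, seq_len(n))[seq_len(k)]
}

#' Coverage rate of an observer set
#'
#' The fraction of nodes adjacent to at least one observer (open
#' neighbourhoods: an observer does not cover itself, but is covered if it
#' neighbours another observer).
#'
#' @param g An \code{igraph} graph.
#' @param observers Distinct observer vertex indices.
#' @return A real in [0, 1].
#' @export
coverage_rate <- function(g, observers) {
  stopifnot(!anyDuplicated(observers))
  covered <- unique(unlist(igraph::as_adj_list(g)[observers]))
  length(covered) / igraph::vcount(g)
}

#' Greedy high-coverage-rate observer placement (HCR)
#'
#' Observers are chosen greedily, each new observer maximising the marginal
#' number of newly covered nodes. Once every node is covered (coverage rate
#' 1) the objective escalates to double-coverage (nodes with two observer
#' neighbours), then triple-coverage, and so on until k observers are placed.
#'
#' @param g An \code{igraph} graph.
#' @param k Number of observers, 1 <= k < N.
#' @return Integer vector of k vertex indices in selection order.
#' @export
place_hcr <- function(g, k) {
  n <- igraph::vcount(g)
  stopifnot(k >= 1, k < n)
  adj <- sorted_adj(g)
  cov <- integer(n)       # number of observer neighbours per node
  chosen <- integer(0)
  candidate <- rep(TRUE, n)
  tier <- 1L
  for (step in seq_len(k)) {
    while (all(cov >= tier)) tier <- tier + 1L
    gains <- vapply(seq_len(n), function(c) {
      if (!candidate[c]) return(-1L)
      sum(cov[adj[[c]]] == tier - 1L)
    }, integer(1))
    pick <- which.max(gains)  # first maximum = lowest index
    chosen <- c(chosen, pick)
    candidate[pick] <- FALSE
    cov[adj[[pick]]] <- cov[adj[[pick]]] + 1L
  }
  chosen
}

#' Greedy high-variance (path-covering) observer placement (HVO)
#'
#' Maximises the number of nodes lying on shortest paths of length at most
#' \code{max_len} between observer pairs. A node lying on at least m such
#' paths (counting path multiplicity across all observer pairs) is
#' m-path-covered. The initial pair is the exhaustive best over all node
#' pairs; each subsequent observer greedily maximises the number of
#' single-path-covered nodes until all nodes are covered, then
#' double-path-covered nodes, and so on.
#'
#' @param g An \code{igraph} graph.
#' @param k Number of observers, 2 <= k < N.
#' @param max_len Only shortest paths of length at most \code{max_len}
#'   between observer pairs count (default \code{Inf}: no restriction).
#' @return Integer vector of k vertex indices in selection order.
#' @export
place_hvo <- function(g, k, max_len = Inf) {
  n <- igraph::vcount(g)
  if (k < 2) stop("HVO needs at least 2 observers")
  stopifnot(k < n)
  D <- igraph::distances(g)
  adj <- sorted_adj(g)
  # sigma[u, v]: number of shortest u->v paths
  S <- matrix(0, n, n)
  for (u in seq_len(n)) S[u, ] <- sp_counts_from(adj, D[u, ])

  # path-cover multiplicity each node gains from observer pair (a, b)
  pair_cover <- function(a, b) {
    L <- D[a, b]
    if (!is.finite(L) || L > max_len) return(numeric(n))
    m <- S[a, ] * S[, b]
    m[D[a, ] + D[, b] != L] <- 0
    m
  }

  best_pair <- NULL
  best_val <- -1
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    val <- sum(pair_cover(a, b) >= 1)
    if (val > best_val) { best_val <- val; best_pair <- c(a, b) }
  }
  chosen <- best_pair
  cov <- pair_cover(best_pair[1], best_pair[2])
  candidate <- rep(TRUE, n)
  candidate[chosen] <- FALSE
  tier <- 1
  while (length(chosen) < k) {
    while (all(cov >= tier)) tier <- tier + 1
    best <- NA_integer_; best_gain <- -1
    for (c in which(candidate)) {
      add <- numeric(n)
      for (o in chosen) add <- add + pair_cover(o, c)
      gain <- sum(cov + add >= tier) - sum(cov >= tier)
      if (gain > best_gain) { best_gain <- gain; best <- c }
    }
    chosen <- c(chosen, best)
    candidate[best] <- FALSE
    for (o in chosen[-length(chosen)]) cov <- cov + pair_cover(o, best)
  }
  chosen
}

#' Random observer placement (RND)
#'
#' Uniform sample of k nodes without replacement; the null model against
#' which the informed strategies are compared.
#'
#' @param g An \code{igraph} graph.
#' @param k Number of observers, 1 <= k < N.
#' @param seed Optional integer seed.
#' @return Integer vector of k vertex indices.
#' @export
place_rnd <- function(g, k, seed = NULL) {
  n <- igraph::vcount(g)
  stopifnot(k >= 1, k < n)
  draw <- function() sample.int(n, k)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Place observers by a named strategy
#'
#' Dispatcher over the four placement strategies, parameterised by observer
#' density d = K/N as in reporting (K = max(1, round(d * N))).
#'
#' @param g An \code{igraph} graph.
#' @param strategy One of \code{"bc"}, \code{"hcr"}, \code{"hvo"},
#'   \code{"rnd"}.
#' @param k Observer budget; alternatively give \code{density}.
#' @param density Observer density d = K/N in (0, 1).
#' @param max_len HVO path-length cutoff L.
#' @param seed Seed for \code{"rnd"}.
#' @return Integer vector of k vertex indices.
#' @export
place_observers <- function(g, strategy = c("bc", "hcr", "hvo", "rnd"),
                            k = NULL, density = NULL, max_len = Inf,
                            seed = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(k)) {
    stopifnot(!is.null(density), density > 0, density < 1)
    k <- max(1L, round(density * igraph::vcount(g)))
  }
  switch(strategy,
         bc = place_bc(g, k),
         hcr = place_hcr(g, k),
         hvo = place_hvo(g, k, max_len = max_len),
         rnd = place_rnd(g, k, seed = seed))
}
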