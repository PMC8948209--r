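# Source localisation from observer arrival times. All five methods score
# every candidate node s by some F(s) (Eq.-style argmax rule): the estimated
# source is the argmax set. LPTV and EPL are reference-based (delays relative
# to the reference observer o_0); TRBS and PC use absolute times; GMLA is a
# hill-climbing restriction of LPTV.

ridge_default <- 1e-9

# Regularised symmetric solve: Lambda + eps*I with eps scaled to the
# diagonal; never forms an explicit inverse.
ridge_solve <- function(Lambda, rhs, ridge = ridge_default) {
  eps <- ridge * max(max(diag(Lambda), 0), 1)
  solve(Lambda + diag(eps, nrow(Lambda)), rhs)
}

check_obs <- function(g, obs, min_k = 2) {
  stopifnot(inherits(obs, "observer_set"))
  if (length(obs$nodes) < min_k)
    stop("at least ", min_k, " observers required")
  if (any(obs$nodes < 1 | obs$nodes > igraph::vcount(g)))
    stop("observer outside the graph")
}

# Per-candidate LPTV score factory over a fixed observer set. Returns a
# closure scoring one candidate via the BFS-tree approximation:
#   [mu_s]_k    = mu * (|P(s,o_k)| - |P(s,o_0)|)   (tree = graph distances)
#   [Lambda]_ki = sigma^2 * (shared edges of the tree paths o_0->o_k, o_0->o_i)
#   F(s)        = mu_s' Lambda^{-1} (d - mu_s/2),  d_k = t_k - t_0
# Shared tree-path edges are computed from tree distances:
# (d_T(o0,ok) + d_T(o0,oi) - d_T(ok,oi)) / 2.
lptv_scorer <- function(g, obs, dm, ridge = ridge_default) {
  adj <- sorted_adj(g)
  D <- igraph::distances(g)
  nodes <- obs$nodes
  K <- length(nodes)
  ref <- obs$reference
  oth <- setdiff(seq_len(K), ref)
  d <- obs$times[oth] - obs$times[ref]
  o0 <- nodes[ref]
  function(s) {
    tr <- bfs_tree_impl(adj, D[s, ], s)
    mu_s <- dm$mu * (tr$depth[nodes[oth]] - tr$depth[o0])
    dT0 <- vapply(nodes[oth], function(o)
      tree_distance(tr$parent, tr$depth, o0, o), 1)
    m <- length(oth)
    Lambda <- matrix(0, m, m)
    for (a in seq_len(m)) {
      Lambda[a, a] <- dT0[a]
      if (a < m) for (b in (a + 1):m) {
        dab <- tree_distance(tr$parent, tr$depth, nodes[oth[a]], nodes[oth[b]])
        Lambda[a, b] <- Lambda[b, a] <- (dT0[a] + dT0[b] - dab) / 2
      }
    }
    Lambda <- dm$sigma2 * Lambda
    sum(mu_s * ridge_solve(Lambda, d - mu_s / 2, ridge))
  }
}

#' Score candidates by the Pinto-Thiran-Vetterli estimator (LPTV)
#'
#' Maximum-likelihood source estimation under a Gaussian delay model on the
#' BFS-tree approximation of the graph (limited-information variant: only
#' arrival times are used, not the transmitting neighbour). Delays are taken
#' relative to the reference observer; the covariance of two observer delays
#' is sigma^2 times the number of tree edges their paths from the reference
#' observer share.
#'
#' @param g Connected undirected \code{igraph} graph.
#' @param obs An \code{observer_set} with K >= 2 observers.
#' @param dm A \code{\link{delay_model}}.
#' @param ridge Relative ridge added to a singular covariance before solving.
#' @return A \code{\link{score_table}} over all N candidates.
#' @export
score_lptv <- function(g, obs, dm, ridge = ridge_default) {
  check_obs(g, obs)
  sc <- lptv_scorer(g, obs, dm, ridge)
  n <- igraph::vcount(g)
  score_table(vapply(seq_len(n), sc, 1), "lptv")
}

#' Score candidates by time-reversal backwards spreading (TRBS)
#'
#' Backwards spreading compares observed absolute arrival times with
#' mu * (hop distance) from each candidate; the source estimate minimises the
#' variance of the residuals, so F(s) = -Var(d - mu_s). Invariant to adding
#' a constant to all observed times.
#'
#' @inheritParams score_lptv
#' @return A \code{\link{score_table}} over all N candidates.
#' @export
score_trbs <- function(g, obs, dm) {
  check_obs(g, obs)
  Dm <- igraph::distances(g, v = obs$nodes)     # K x N
  R <- obs$times - dm$mu * Dm                   # residuals per candidate col
  K <- length(obs$nodes)
  v <- (colSums(R^2) - colSums(R)^2 / K) / (K - 1)
  score_table(-pmax(v, 0), "trbs")
}

#' Score candidates by Pearson correlation of distance and time (PC)
#'
#' F(s) is the Pearson correlation between the hop distances from candidate
#' s to the observers and their arrival times. Scale-invariance of the
#' correlation makes the per-link delay mean irrelevant, so raw hop counts
#' are used. A candidate whose distance vector has zero variance is scored
#' with the sentinel -2 (below any valid correlation); if the observed times
#' themselves have zero variance every candidate is uninformative and the
#' table is flagged degenerate.
#'
#' @inheritParams score_lptv
#' @return A \code{\link{score_table}}; scores lie in [-1, 1] (or sentinels).
#' @export
score_pc <- function(g, obs) {
  check_obs(g, obs)
  Dm <- igraph::distances(g, v = obs$nodes)     # K x N
  t <- obs$times
  if (stats::var(t) == 0)
    return(score_table(rep(0, ncol(Dm)), "pc", degenerate = TRUE))
  scores <- suppressWarnings(as.vector(stats::cor(t, Dm)))
  scores[is.na(scores)] <- -2
  score_table(scores, "pc")
}

#' GMLA configuration
#'
#' @param k0 Number of nearest observers (smallest arrival times) used for
#'   scoring; default \code{max(5, ceiling(sqrt(N)))}, capped at K.
#' @return List of class \code{gmla_config}.
#' @export
gmla_config <- function(k0 = NULL) {
  if (!is.null(k0)) stopifnot(k0 >= 2)
  structure(list(k0 = k0), class = "gmla_config")
}

#' Score candidates by the gradient maximum-likelihood algorithm (GMLA)
#'
#' A hill-climbing restriction of LPTV: only the K0 observers with the
#' smallest arrival times are used, and scoring starts at the neighbours of
#' "observer one" (the observer with the smallest time), repeatedly moving
#' to an unvisited neighbour whose score is at least the current maximum,
#' until every neighbour scores lower. Only visited nodes are evaluated;
#' unevaluated nodes receive rank N downstream. Every evaluated score equals
#' the LPTV score of that candidate on the restricted observer set.
#'
#' @inheritParams score_lptv
#' @param cfg A \code{\link{gmla_config}}.
#' @return A \code{\link{score_table}} with \code{NA} outside the evaluated
#'   set.
#' @export
score_gmla <- function(g, obs, dm, cfg = gmla_config(),
                       ridge = ridge_default) {
  check_obs(g, obs)
  n <- igraph::vcount(g)
  K <- length(obs$nodes)
  k0 <- cfg$k0
  if (is.null(k0)) k0 <- max(5, ceiling(sqrt(n)))
  k0 <- max(2L, min(k0, K))
  keep <- order(obs$times, obs$nodes)[seq_len(k0)]
  obs_r <- observer_set(obs$nodes[keep], obs$times[keep])
  sc <- lptv_scorer(g, obs_r, dm, ridge)
  adj <- sorted_adj(g)
  o1 <- obs_r$nodes[obs_r$reference]
  scores <- rep(NA_real_, n)
  eval_node <- function(v) {
    if (is.na(scores[v])) scores[v] <<- sc(v)
    scores[v]
  }
  eval_node(o1)
  for (v in adj[[o1]]) eval_node(v)
  nb1 <- adj[[o1]]
  cur <- nb1[which.max(scores[nb1])]
  cur_max <- scores[cur]
  visited <- c(o1, cur)
  repeat {
    nb <- adj[[cur]]
    for (v in nb) eval_node(v)
    cand <- setdiff(nb[scores[nb] >= cur_max], visited)
    if (length(cand) == 0) break
    cur <- cand[which.max(scores[cand])]
    cur_max <- max(cur_max, scores[cur])
    visited <- c(visited, cur)
  }
  score_table(scores, "gmla")
}

# First moment (and, on request, variance) of the arrival delay from x to
# observer o under the equiprobable-links path model:
#   1 shortest path: N(L mu, L sigma^2)
#   2 shortest paths: min of two N(L mu, L sigma^2) with rho = shared/L
#   >2 (or cap exceeded): min of two independent such Gaussians (rho = 0)
epl_mean_var <- function(adj, d_o, sigma_o, x, o, dm, cap) {
  L <- d_o[x]
  if (L == 0) return(c(0, 0))
  np <- sigma_o[x]
  if (np <= 1) return(c(L * dm$mu, L * dm$sigma2))
  rho <- 0
  if (np == 2 && cap >= 2) {
    ps <- enum_paths_impl(adj, d_o, x, o, 2L)
    rho <- path_correlation(ps[[1]], ps[[2]])
  }
  s <- sqrt(L * dm$sigma2)
  mg <- min_gaussian_moments(L * dm$mu, L * dm$mu, s, s, rho)
  c(mg$ey, mg$variance)
}

#' Score candidates by the equiprobable-links estimator (EPL)
#'
#' Extends LPTV beyond the tree approximation by treating every shortest
#' path between a candidate and an observer as a Gaussian random traversal
#' time: with n parallel shortest paths of length L, the expected arrival is
#' the mean of the minimum of the path variables (two-path approximation for
#' n > 2, assuming two independent paths). The covariance between observers
#' i and j is the Jaccard index of the edge unions of their shortest-path
#' ensembles to the reference observer, times the geometric mean of the
#' ensembles' min-distribution variances; it does not depend on the
#' candidate and is computed once. The score is the LPTV quadratic form.
#'
#' @inheritParams score_lptv
#' @param cap Maximum number of paths materialised per node pair; beyond the
#'   cap the independent two-path branch is used (means are unaffected).
#' @return A \code{\link{score_table}} over all N candidates.
#' @export
score_epl <- function(g, obs, dm, cap = 64, ridge = ridge_default) {
  check_obs(g, obs)
  n <- igraph::vcount(g)
  adj <- sorted_adj(g)
  D <- igraph::distances(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  nodes <- obs$nodes
  K <- length(nodes)
  ref <- obs$reference
  oth <- setdiff(seq_len(K), ref)
  o0 <- nodes[ref]
  d_obs <- obs$times[oth] - obs$times[ref]

  sig <- lapply(nodes, function(o) sp_counts_from(adj, D[o, ]))

  # candidate-to-observer expected arrivals, N x K
  M <- matrix(0, n, K)
  for (j in seq_len(K)) {
    o <- nodes[j]
    L <- D[o, ]
    np <- sig[[j]]
    M[, j] <- L * dm$mu
    multi <- which(np >= 2 & L > 0)
    for (x in multi)
      M[x, j] <- epl_mean_var(adj, D[o, ], np, x, o, dm, cap)[1]
  }

  # source-independent covariance over the o_0 -> o_i path ensembles
  m <- length(oth)
  ens_var <- numeric(m)
  ens_edges <- vector("list", m)
  for (a in seq_len(m)) {
    oi <- nodes[oth[a]]
    ens_var[a] <- epl_mean_var(adj, D[o0, ], sig[[ref]], oi, o0, dm, cap)[2]
    ens_edges[[a]] <- edges_on_paths(el, D[o0, ], D[oi, ], D[o0, oi])
  }
  Lambda <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in a:m) {
    jac <- if (a == b) 1 else jaccard_edges(ens_edges[[a]], ens_edges[[b]])
    Lambda[a, b] <- Lambda[b, a] <- jac * sqrt(ens_var[a] * ens_var[b])
  }
  eps <- ridge_default_eps(Lambda, ridge)
  LU <- Lambda + diag(eps, m)

  scores <- vapply(seq_len(n), function(s) {
    mu_s <- M[s, oth] - M[s, ref]
    sum(mu_s * solve(LU, d_obs - mu_s / 2))
  }, 1)
  score_table(scores, "epl")
}

ridge_default_eps <- function(Lambda, ridge = ridge_default) {
  ridge * max(max(diag(Lambda), 0), 1)
}

#' Score candidates with a named localisation method
#'
#' @param g An \code{igraph} graph.
#' @param obs An \code{observer_set}.
#' @param method One of \code{"lptv"}, \code{"trbs"}, \code{"pc"},
#'   \code{"gmla"}, \code{"epl"}.
#' @param dm A \code{\link{delay_model}} (unused by \code{"pc"}).
#' @param ... Passed to the method (e.g. \code{cfg} for GMLA, \code{cap} for
#'   EPL).
#' @return A \code{\link{score_table}}.
#' @export
locate_source <- function(g, obs, method = c("lptv", "trbs", "pc", "gmla",
                                             "epl"),
                          dm = NULL, ...) {
  method <- match.arg(method)
  if (method != "pc" && is.null(dm))
    stop("method '", method, "' needs a delay_model")
  switch(method,
         lptv = score_lptv(g, obs, dm, ...),
         trbs = score_trbs(g, obs, dm),
         pc = score_pc(g, obs),
         gmla = score_gmla(g, obs, dm, ...),
         epl = score_epl(g, obs, dm, ...))
}
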