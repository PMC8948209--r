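#' Per-link delay model for the localisation estimators
#'
#' The localisers assume each link adds a random delay with mean \code{mu}
#' and variance \code{sigma2}. Under the synchronous SI process the
#' first-success delay across a single link is geometric with parameter
#' \code{beta}, so the defaults derived from the infection rate are
#' \code{mu = 1/beta} and \code{sigma2 = (1 - beta)/beta^2}. Both can be
#' overridden, e.g. for Gaussian-delay experiments.
#'
#' @param beta Infection rate in (0, 1]; used only for the defaults.
#' @param mu Per-link mean delay (> 0).
#' @param sigma2 Per-link delay variance (>= 0).
#' @return A list of class \code{delay_model} with fields \code{mu},
#'   \code{sigma2}.
#' @export
delay_model <- function(beta = NULL, mu = NULL, sigma2 = NULL) {
  if (is.null(mu)) {
    stopifnot(!is.null(beta), beta > 0, beta <= 1)
    mu <- 1 / beta
  }
  if (is.null(sigma2)) {
    stopifnot(!is.null(beta), beta > 0, beta <= 1)
    sigma2 <- (1 - beta) / beta^2
  }
  stopifnot(mu > 0, sigma2 >= 0)
  structure(list(mu = mu, sigma2 = sigma2), class = "delay_model")
}

#' Run one synchronous Susceptible-Infected realisation
#'
#' Agent-based SI dynamics: the source is infected at time 0; at every step
#' all infected nodes simultaneously try to infect each susceptible
#' neighbour with probability \code{beta}. A susceptible node with m infected
#' neighbours is infected this step with probability \code{1 - (1-beta)^m}
#' (equivalent to independent per-edge trials, order-free). The run stops
#' when every node is infected or \code{max_steps} is reached.
#'
#' At \code{beta = 1} infection times equal graph distances from the source.
#'
#' @param g Connected undirected \code{igraph} graph.
#' @param beta Infection rate in (0, 1].
#' @param source Source vertex index, or \code{"random"} for a uniform draw.
#' @param seed Optional integer seed (realisation reproducible in isolation).
#' @param max_steps Step cap; \code{Inf} (default) runs to completion.
#' @return An object of class \code{si_realisation}: list with \code{source},
#'   \code{times} (numeric vector over vertices, \code{Inf} = never
#'   infected), \code{beta}, \code{steps}.
#' @export
run_si <- function(g, beta, source = "random", seed = NULL, max_steps = Inf) {
  stopifnot(beta > 0, beta <= 1)
  n <- igraph::vcount(g)
  run <- function() {
    src <- if (identical(source, "random")) sample.int(n, 1L) else {
      s <- as.integer(source)
      if (is.na(s) || s < 1 || s > n) stop("unknown source node: ", source)
      s
    }
    adj <- igraph::as_adj_list(g)
    adj <- lapply(adj, as.integer)
    times <- rep(Inf, n)
    times[src] <- 0
    # inf_nb[v]: number of currently infected neighbours of susceptible v
    inf_nb <- integer(n)
    for (u in adj[[src]]) inf_nb[u] <- inf_nb[u] + 1L
    susceptible <- rep(TRUE, n)
    susceptible[src] <- FALSE
    t <- 0L
    n_inf <- 1L
    while (n_inf < n && t < max_steps) {
      t <- t + 1L
      at_risk <- which(susceptible & inf_nb > 0L)
      if (length(at_risk) == 0) break  # cannot happen on a connected graph
      p <- 1 - (1 - beta)^inf_nb[at_risk]
      hit <- at_risk[stats::runif(length(at_risk)) < p]
      if (length(hit)) {
        times[hit] <- t
        susceptible[hit] <- FALSE
        n_inf <- n_inf + length(hit)
        for (v in hit) for (u in adj[[v]]) inf_nb[u] <- inf_nb[u] + 1L
      }
    }
    structure(list(source = src, times = times, beta = beta, steps = t),
              class = "si_realisation")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Extract observer arrival times from a realisation
#'
#' Restricts a spread realisation to the observer nodes, preserving order,
#' and identifies the reference observer (smallest arrival time, ties broken
#' by vertex index) used by the reference-based localisers and by GMLA as
#' "observer one".
#'
#' @param r An \code{si_realisation}.
#' @param observers Vector of distinct observer vertex indices.
#' @param policy \code{"strict"} (default) errors if any observer was never
#'   infected; \code{"drop"} silently removes such observers.
#' @return An object of class \code{observer_set}: list with \code{nodes},
#'   \code{times} (parallel vectors) and \code{reference} (position in
#'   \code{nodes} of the reference observer).
#' @export
observe <- function(r, observers, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  stopifnot(inherits(r, "si_realisation"), length(observers) > 0,
            !anyDuplicated(observers))
  observers <- as.integer(observers)
  if (any(observers < 1 | observers > length(r$times)))
    stop("observer outside the graph")
  tk <- r$times[observers]
  if (any(!is.finite(tk))) {
    if (policy == "strict")
      stop("observer(s) never infected: ",
           paste(observers[!is.finite(tk)], collapse = ", "))
    observers <- observers[is.finite(tk)]
    tk <- tk[is.finite(tk)]
    if (length(observers) == 0) stop("no infected observers left")
  }
  observer_set(observers, tk)
}

#' Construct an observer set from nodes and arrival times
#'
#' @param nodes Distinct observer vertex indices (selection order preserved).
#' @param times Arrival times, parallel to \code{nodes}.
#' @return An \code{observer_set}; the reference observer is the one with the
#'   minimum time, ties broken by vertex index.
#' @export
observer_set <- function(nodes, times) {
  stopifnot(length(nodes) == length(times), !anyDuplicated(nodes))
  nodes <- as.integer(nodes)
  cand <- which(times == min(times))
  ref <- cand[which.min(nodes[cand])]
  structure(list(nodes = nodes, times = as.numeric(times), reference = ref),
            class = "observer_set")
}

#' Write a realisation as a tabular text file
#'
#' Columns \code{node}, \code{infection_time}; header comments carry the
#' source, beta and step count.
#'
#' @param r An \code{si_realisation}.
#' @param path Output path.
#' @export
write_realisation <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source=%d beta=%g steps=%d",
                     r$source, r$beta, r$steps), con)
  writeLines("node\tinfection_time", con)
  writeLines(sprintf("%d\t%s", seq_along(r$times),
                     ifelse(is.finite(r$times), r$times, "never")), con)
  invisible(path)
}
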