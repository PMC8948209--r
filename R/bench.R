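# Benchmarking layer: repeated simulate -> observe -> localise cycles,
# aggregated into precision and the credible set size CSS_alpha.

#' Precision of a single localisation
#'
#' 1/|argmax set| if the true source is among the top-scored nodes, else 0:
#' the ratio of true positives (0 or 1) to the number of sources the method
#' reports (at least 1, all tied at the maximum score).
#'
#' @param st A \code{\link{score_table}}.
#' @param true_source Vertex index of the true source.
#' @return A real in [0, 1].
#' @export
precision_single <- function(st, true_source) {
  stopifnot(inherits(st, "score_table"), length(st$argmax_set) > 0)
  if (true_source %in% st$argmax_set) 1 / length(st$argmax_set) else 0
}

#' Credible set size CSS_alpha
#'
#' The smallest k such that the true source ranked within the top k in at
#' least a fraction alpha of realisations: the size of the smallest set of
#' top-ranked nodes containing the true source with probability alpha, with
#' the hit probability estimated as the rate over realisations. Equals the
#' ceiling(alpha * n)-th order statistic of the ranks.
#'
#' @param ranks Integer ranks of the true source, each in [1, n_nodes].
#' @param alpha Confidence level in (0, 1); 0.95 in the benchmarks.
#' @param n_nodes Graph size N (upper bound for a rank).
#' @return Integer credible set size in [1, N].
#' @export
css <- function(ranks, alpha = 0.95, n_nodes = max(ranks)) {
  stopifnot(length(ranks) > 0, alpha > 0, alpha < 1,
            all(ranks >= 1), all(ranks <= n_nodes))
  sort(ranks)[ceiling(alpha * length(ranks))]
}

# Deterministic child seeds below 2^31, derived from a master seed.
child_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

#' Run one benchmark cell
#'
#' One parameter cell = (network, beta, observer density, placement
#' strategy, localisation method). For synthetic networks the graph is
#' regenerated per realisation block (\code{graphs_per_cell} graphs, the
#' realisations split evenly across them, mirroring "different origins, many
#' graph realisations"); a fixed graph can be supplied instead. Observers
#' are placed once per graph (RND re-drawn per graph). Each realisation
#' draws a random source, runs the SI process to completion, scores all
#' candidates and records the per-test precision and the pessimistic rank of
#' the true source.
#'
#' @param graph Either an \code{igraph} graph (used for every realisation)
#'   or a function \code{function(seed)} returning one (synthetic models).
#' @param beta Infection rate in (0, 1].
#' @param density Observer density d = K/N (K = max(1, round(d*N))); give
#'   either this or \code{k}.
#' @param k Observer budget K (overrides \code{density}); \code{k = N} means
#'   full observation (all nodes report).
#' @param placement Placement strategy: \code{"bc"}, \code{"hcr"},
#'   \code{"hvo"}, \code{"rnd"}.
#' @param method Localisation method: \code{"lptv"}, \code{"trbs"},
#'   \code{"pc"}, \code{"gmla"}, \code{"epl"}.
#' @param n_realisations Number of simulate-observe-localise cycles.
#' @param alpha CSS confidence level.
#' @param master_seed Integer seed; all randomness (graphs, placements,
#'   sources, spreads) derives from it deterministically.
#' @param graphs_per_cell Number of graph realisations when \code{graph} is
#'   a generator function (default 10).
#' @param dm Optional \code{\link{delay_model}} override; default derived
#'   from \code{beta} (geometric link-delay moments).
#' @param hvo_max_len HVO path-length cutoff L.
#' @param ... Extra arguments passed to the scorer (e.g. \code{cfg}, \code{cap}).
#' @return An object of class \code{eval_result}: list with
#'   \code{precision}, \code{css}, \code{n_realisations},
#'   \code{per_realisation_ranks}, \code{per_realisation_precision},
#'   \code{cell} (the configuration record).
#' @export
run_cell <- function(graph, beta, density = NULL, k = NULL,
                     placement = c("bc", "hcr", "hvo", "rnd"),
                     method = c("lptv", "trbs", "pc", "gmla", "epl"),
                     n_realisations = 100, alpha = 0.95, master_seed = 1,
                     graphs_per_cell = 10, dm = NULL, hvo_max_len = Inf,
                     ...) {
  placement <- match.arg(placement)
  method <- match.arg(method)
  if (is.null(dm)) dm <- delay_model(beta)
  fixed <- !is.function(graph)
  n_graphs <- if (fixed) 1L else graphs_per_cell
  per_graph <- diff(round(seq(0, n_realisations, length.out = n_graphs + 1)))
  seeds <- child_seeds(master_seed, 2L * n_graphs + n_realisations)
  gseeds <- seeds[seq_len(n_graphs)]
  pseeds <- seeds[n_graphs + seq_len(n_graphs)]
  rseeds <- seeds[2L * n_graphs + seq_len(n_realisations)]
  precisions <- numeric(n_realisations)
  ranks <- integer(n_realisations)
  n_nodes_max <- 0L
  i <- 0L
  for (gi in seq_len(n_graphs)) {
    g <- if (fixed) graph else graph(gseeds[gi])
    n <- igraph::vcount(g)
    n_nodes_max <- max(n_nodes_max, n)
    kk <- if (!is.null(k)) k else max(1L, round(density * n))
    # kk = N is full observation: every node reports its arrival time
    obs_nodes <- if (kk >= n) seq_len(n) else
      place_observers(g, placement, k = kk, max_len = hvo_max_len,
                      seed = pseeds[gi])
    for (r in seq_len(per_graph[gi])) {
      i <- i + 1L
      real <- run_si(g, beta, source = "random", seed = rseeds[i])
      ob <- observe(real, obs_nodes)
      st <- locate_source(g, ob, method, dm = dm, ...)
      precisions[i] <- precision_single(st, real$source)
      ranks[i] <- rank_of(st, real$source)
    }
  }
  structure(list(precision = mean(precisions),
                 css = css(ranks, alpha, n_nodes_max),
                 n_realisations = n_realisations,
                 per_realisation_ranks = ranks,
                 per_realisation_precision = precisions,
                 cell = list(beta = beta, density = density, k = k,
                             placement = placement, method = method,
                             alpha = alpha, master_seed = master_seed,
                             graphs_per_cell = n_graphs,
                             mu = dm$mu, sigma2 = dm$sigma2)),
            class = "eval_result")
}

#' Sweep a grid of benchmark cells
#'
#' Runs \code{\link{run_cell}} for every row of a cell grid and collects one
#' result row per cell. A failed cell is recorded with \code{NA} metrics and
#' the sweep continues. When \code{out_path} is given, the table is written
#' as tab-separated values with a JSON metadata sidecar
#' (\code{<out_path>.meta.json}) carrying the full configuration.
#'
#' @param grid Data frame with columns \code{beta}, \code{density},
#'   \code{placement}, \code{method} (and optionally \code{n_realisations},
#'   \code{master_seed}).
#' @param graph Graph or generator function, as in \code{\link{run_cell}}.
#' @param out_path Optional output TSV path.
#' @param ... Shared arguments forwarded to \code{\link{run_cell}}.
#' @return Data frame with one row per cell: the configuration plus
#'   \code{k}, \code{precision}, \code{css}, \code{failed}.
#' @export
sweep_grid <- function(grid, graph, out_path = NULL, ...) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0)
  fixed_args <- list(...)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- as.list(grid[i, , drop = FALSE])
    args <- c(list(graph = graph), cell, fixed_args)
    res <- tryCatch(do.call(run_cell, args), error = function(e) e)
    failed <- inherits(res, "error")
    if (failed)
      message("cell ", i, " failed: ", conditionMessage(res))
    data.frame(cell_id = i,
               beta = cell$beta,
               density = if (is.null(cell$density)) NA else cell$density,
               placement = cell$placement, method = cell$method,
               precision = if (failed) NA else res$precision,
               css = if (failed) NA else res$css,
               n_realisations = if (failed) NA else res$n_realisations,
               failed = failed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_path)) {
    utils::write.table(out, out_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(c(list(cells = nrow(out)), fixed_args),
                         paste0(out_path, ".meta.json"), auto_unbox = TRUE,
                         force = TRUE)
  }
  out
}
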