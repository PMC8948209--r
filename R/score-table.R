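#' Construct a score table
#'
#' Container for per-candidate source scores F(s). Localisers that score
#' every node leave no \code{NA}; GMLA scores only the nodes visited by its
#' hill climb, the rest stay \code{NA} and are treated as rank N.
#'
#' @param scores Numeric vector of length N; \code{NA} = not evaluated.
#' @param method Method name string.
#' @param degenerate Flag set when all scores are an uninformative sentinel
#'   (e.g. Pearson correlation with zero variance in the observed times).
#' @return An object of class \code{score_table}: list with \code{scores},
#'   \code{method}, \code{n_nodes}, \code{evaluated_set}, \code{argmax_set},
#'   \code{degenerate}.
#' @export
score_table <- function(scores, method, degenerate = FALSE) {
  evaluated <- which(!is.na(scores))
  argmax <- if (length(evaluated)) {
    top <- max(scores[evaluated])
    evaluated[scores[evaluated] == top]
  } else integer(0)
  structure(list(scores = scores, method = method,
                 n_nodes = length(scores),
                 evaluated_set = evaluated, argmax_set = argmax,
                 degenerate = degenerate),
            class = "score_table")
}

#' Pessimistic competition rank of a node in a score table
#'
#' Rank = 1 + (number of strictly better-scoring evaluated nodes) + (number
#' of evaluated ties other than the node itself): the node is placed last
#' among its ties, making downstream credible-set sizes conservative. A node
#' the method never evaluated gets the maximum rank N.
#'
#' @param st A \code{score_table}.
#' @param node Vertex index.
#' @return Integer rank in [1, N].
#' @export
rank_of <- function(st, node) {
  stopifnot(inherits(st, "score_table"))
  s0 <- st$scores[node]
  if (is.na(s0)) return(st$n_nodes)
  ev <- st$scores[st$evaluated_set]
  sum(ev > s0) + sum(ev == s0)
}

#' Write a score table as tabular text
#'
#' Columns node, score, rank; a comment header carries the method name and
#' any metadata supplied.
#'
#' @param st A \code{score_table}.
#' @param path Output path.
#' @param meta Optional named list echoed into the header.
#' @export
write_score_table <- function(st, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(method = st$method), meta)
  writeLines(paste0("# ", paste(names(meta), unlist(meta),
                                sep = "=", collapse = " ")), con)
  writeLines("node\tscore\trank", con)
  ranks <- vapply(seq_len(st$n_nodes), function(v) rank_of(st, v), 1)
  writeLines(sprintf("%d\t%s\t%d", seq_len(st$n_nodes),
                     ifelse(is.na(st$scores), "NA",
                            format(st$scores, digits = 10)),
                     as.integer(ranks)), con)
  invisible(path)
}
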