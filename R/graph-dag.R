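# The variant graph: alignment records are nodes, candidate variants (or
# null transitions) are edges, and the accepted callset is the minimum
# penalty SOURCE -> SINK path. The graph is acyclic by construction (every
# edge goes from a smaller qstart to a larger one), so the shortest path is
# solved by single-pass relaxation in topological order — the O(N + E)
# specialization of Bellman-Ford on DAGs.

#' Build the variant graph
#'
#' Nodes are the alignment records plus `SOURCE` and `SINK`; edges are the
#' candidate edges from [enumerate_candidates()] plus SOURCE/SINK
#' connections. A SOURCE (SINK) edge is a null transition for the record
#' with the smallest qstart (largest qend); starting later or ending earlier
#' forfeits explaining the skipped query bases and is penalised like an
#' insertion of that length. Nodes that cannot lie on a SOURCE -> SINK path
#' are pruned (count kept in attribute `pruned`).
#'
#' @param records trimmed alignment records sorted by `qstart`.
#' @param candidates candidate edge list from [enumerate_candidates()].
#' @param params [sv_params()] configuration.
#' @return list of class `variant_graph` with `nodes` (data frame) and
#'   `edges` (data frame with list-column `variants`).
#' @export
build_dag <- function(records, candidates, params = sv_params()) {
  n <- nrow(records)
  if (n == 0L) stop("no alignment records")
  # node ids: 0 = SOURCE, 1..n = records, n+1 = SINK
  nodes <- data.frame(
    node = 0:(n + 1L),
    label = c("SOURCE", sprintf("R%03d", seq_len(n)), "SINK"),
    qstart = c(-1L, records$qstart, max(records$qend) + 1L),
    stringsAsFactors = FALSE)
  lead_pen <- function(gap) {
    if (gap < params$min_sv) 0
    else unname(params$open[["INS"]] + params$size_coef * log2(1 + gap) +
                  params$unaligned_rate * gap)
  }
  min_q <- min(records$qstart); max_q <- max(records$qend)
  ed <- list()
  add <- function(from, to, penalty, variants, label) {
    ed[[length(ed) + 1L]] <<- list(from = from, to = to, penalty = penalty,
                                   variants = variants, label = label)
  }
  for (i in seq_len(n)) {
    lead <- records$qstart[i] - min_q
    if (lead <= params$max_join) {
      add(0L, i, lead_pen(lead), list(),
          if (lead < params$min_sv) "null" else "clip")
    }
    tail_gap <- max_q - records$qend[i]
    if (tail_gap <= params$max_join) {
      add(i, n + 1L, lead_pen(tail_gap), list(),
          if (tail_gap < params$min_sv) "null" else "clip")
    }
  }
  for (e in candidates) {
    stopifnot(e$from >= 1L, e$to <= n, e$from < e$to)
    lab <- if (length(e$variants)) {
      paste(vapply(e$variants, `[[`, character(1), "vclass"), collapse = "+")
    } else "null"
    add(e$from, e$to, e$penalty, e$variants, lab)
  }
  edges <- data.frame(
    from = vapply(ed, `[[`, integer(1), "from"),
    to = vapply(ed, `[[`, integer(1), "to"),
    penalty = vapply(ed, `[[`, numeric(1), "penalty"),
    label = vapply(ed, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  edges$variants <- lapply(ed, `[[`, "variants")
  if (any(edges$from >= edges$to)) stop("cycle: edge against query order")

  # prune nodes unreachable from SOURCE or not reaching SINK
  fwd <- reachable(edges, 0L, forward = TRUE, n_nodes = n + 2L)
  bwd <- reachable(edges, n + 1L, forward = FALSE, n_nodes = n + 2L)
  keep <- (fwd & bwd) | nodes$node %in% c(0L, n + 1L)
  pruned <- sum(!keep)
  if (pruned > 0L) {
    keep_ids <- nodes$node[keep]
    edges <- edges[edges$from %in% keep_ids & edges$to %in% keep_ids, ,
                   drop = FALSE]
    nodes <- nodes[keep, , drop = FALSE]
  }
  g <- structure(list(nodes = nodes, edges = edges, n_records = n),
                 class = "variant_graph")
  attr(g, "pruned") <- pruned
  g
}

reachable <- function(edges, start, forward = TRUE, n_nodes) {
  seen <- logical(n_nodes)
  seen[start + 1L] <- TRUE
  repeat {
    if (forward) {
      new <- edges$to[seen[edges$from + 1L]] + 1L
    } else {
      new <- edges$from[seen[edges$to + 1L]] + 1L
    }
    new <- new[!seen[new]]
    if (!length(new)) break
    seen[new] <- TRUE
  }
  seen
}

#' @export
print.variant_graph <- function(x, ...) {
  cat(sprintf("<variant_graph> %d nodes, %d edges (%d records)\n",
              nrow(x$nodes), nrow(x$edges), x$n_records))
  invisible(x)
}

#' Solve the optimal path through the variant graph
#'
#' Minimum total penalty SOURCE -> SINK path by relaxation in topological
#' (query) order; ties are broken by fewer edges, then by the
#' lexicographically smallest node id sequence, so the result is
#' deterministic.
#'
#' @param graph a `variant_graph` from [build_dag()].
#' @return list with `nodes` (node ids on the path), `edge_idx` (row indices
#'   into `graph$edges`), and `penalty`.
#' @export
solve_optimal_path <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  ids <- nodes$node
  idx <- setNames(seq_along(ids), ids)
  m <- length(ids)
  dist <- rep(Inf, m); nedge <- rep(Inf, m)
  pathkey <- rep("", m); pred_edge <- rep(NA_integer_, m)
  src <- idx[as.character(0L)]
  snk <- idx[as.character(max(ids))]
  dist[src] <- 0; nedge[src] <- 0; pathkey[src] <- "0000"
  eps <- 1e-9
  ord <- order(edges$from, edges$to)
  for (e in ord) {
    u <- idx[as.character(edges$from[e])]
    v <- idx[as.character(edges$to[e])]
    if (!is.finite(dist[u])) next
    cand_d <- dist[u] + edges$penalty[e]
    cand_n <- nedge[u] + 1
    cand_k <- paste(pathkey[u], sprintf("%04d", edges$to[e]), sep = ",")
    better <- cand_d < dist[v] - eps ||
      (abs(cand_d - dist[v]) <= eps &&
         (cand_n < nedge[v] ||
            (cand_n == nedge[v] && cand_k < pathkey[v])))
    if (better) {
      dist[v] <- cand_d; nedge[v] <- cand_n
      pathkey[v] <- cand_k; pred_edge[v] <- e
    }
  }
  if (!is.finite(dist[snk])) {
    reached <- ids[is.finite(dist)]
    stop("SINK unreachable; path breaks after query position ",
         max(nodes$qstart[nodes$node %in% reached]))
  }
  # reconstruct
  path_edges <- integer(0); v <- snk
  while (v != src) {
    e <- pred_edge[v]
    path_edges <- c(e, path_edges)
    v <- idx[as.character(edges$from[e])]
  }
  list(nodes = as.integer(strsplit(pathkey[snk], ",")[[1]]),
       edge_idx = path_edges,
       penalty = dist[snk])
}
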