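# Shared fixtures and independent oracles.

# small reference + single-op plan, resolved end to end
resolve_plan <- function(ref, plan, params = sv_params()) {
  sim <- apply_plan(ref, plan)
  res <- resolve_haplotype(ref, sim$hap, params = params)
  list(sim = sim, res = res)
}

# hand-built alignment record row (pure-match CIGAR unless given)
make_record <- function(qname = "q", qlen = 10000L, qstart, qend,
                        strand = "+", rname = "r", rlen = 10000L,
                        rstart, rend, cigar = NULL, score = NULL) {
  if (is.null(cigar)) {
    stopifnot(qend - qstart == rend - rstart)
    cigar <- paste0(qend - qstart, "=")
  }
  if (is.null(score)) score <- qend - qstart
  cc <- complexsv:::cigar_consumed(cigar)
  data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
             strand = strand, rname = rname, rlen = rlen,
             rstart = rstart, rend = rend, cigar = cigar, score = score,
             identity = if (cc$match + cc$mismatch + cc$gap > 0) {
               cc$match / (cc$match + cc$mismatch + cc$gap)
             } else 0,
             stringsAsFactors = FALSE)
}

# --- independent oracle: exhaustive SOURCE->SINK path enumeration ----------
brute_force_best_path <- function(graph) {
  edges <- graph$edges
  sink <- max(graph$nodes$node)
  best <- Inf
  recurse <- function(node, pen) {
    if (node == sink) {
      best <<- min(best, pen)
      return()
    }
    out <- which(edges$from == node)
    for (e in out) recurse(edges$to[e], pen + edges$penalty[e])
  }
  recurse(0L, 0)
  best
}

# random DAG in the variant_graph layout: n records, random forward edges
random_graph <- function(seed, max_nodes = 12L) {
  set.seed(seed)
  n <- sample(2:(max_nodes - 2L), 1L)
  ed <- list()
  add <- function(from, to, penalty) {
    ed[[length(ed) + 1L]] <<- data.frame(from = from, to = to,
                                         penalty = penalty, label = "null",
                                         stringsAsFactors = FALSE)
  }
  # backbone path keeps SINK reachable
  chain <- c(0L, seq_len(n), n + 1L)
  for (i in seq_len(length(chain) - 1L)) {
    add(chain[i], chain[i + 1L], round(runif(1, 0, 10), 3))
  }
  n_extra <- sample(0:(2L * n), 1L)
  for (i in seq_len(n_extra)) {
    from <- sample(0:n, 1L)
    to <- if (from + 1L >= n + 1L) n + 1L else
      sample((from + 1L):(n + 1L), 1L)
    add(from, to, round(runif(1, 0, 10), 3))
  }
  edges <- do.call(rbind, ed)
  edges$variants <- rep(list(list()), nrow(edges))
  nodes <- data.frame(node = 0:(n + 1L),
                      label = c("SOURCE", sprintf("R%03d", seq_len(n)),
                                "SINK"),
                      qstart = c(-1L, seq_len(n) * 100L, (n + 1L) * 100L),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, n_records = n),
            class = "variant_graph")
}

# --- independent oracle: transitive-closure clustering for the merge -------
closure_merge_oracle <- function(calls, ro_min = 0.5, ident_min = 0.8) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      a <- calls[i, ]; b <- calls[j, ]
      if (a$rname != b$rname || a$svtype != b$svtype) next
      ok <- if (a$end == a$pos || b$end == b$pos) {
        abs(a$pos - b$pos) <= 500 &&
          min(abs(a$svlen), abs(b$svlen)) /
            max(abs(a$svlen), abs(b$svlen), 1) >= 0.5
      } else {
        ov <- max(0, min(a$end, b$end) - max(a$pos, b$pos))
        min(ov / (a$end - a$pos), ov / (b$end - b$pos)) >= ro_min
      }
      adj[i, j] <- adj[j, i] <- ok
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# clustered random callsets with well-separated clusters (merge fixtures)
random_callset <- function(seed, n_calls = 30L, n_haps = 20L) {
  set.seed(seed)
  n_clusters <- sample(3:8, 1L)
  centers <- sort(sample(seq(10000L, 900000L, by = 25000L), n_clusters))
  rows <- list()
  left <- n_calls
  for (ci in seq_len(n_clusters)) {
    take <- if (ci == n_clusters) left else {
      min(left, sample(1:ceiling(n_calls / n_clusters * 2), 1L))
    }
    take <- min(take, n_haps)
    left <- left - take
    if (take <= 0L) next
    svtype <- sample(c("DEL", "DUP", "INV", "INS"), 1L)
    len <- sample(300:3000, 1L)
    carriers <- sample(n_haps, take)
    for (m in seq_len(take)) {
      jit <- sample(-20:20, 2L)
      pos <- centers[ci] + jit[1L]
      end <- if (svtype == "INS") pos else pos + len + jit[2L]
      svlen <- if (svtype == "DEL") -(end - pos) else
        if (svtype == "INS") len else end - pos
      row <- data.frame(
        sample = sprintf("S%02d", (carriers[m] + 1L) %/% 2L),
        hap = (carriers[m] - 1L) %% 2L + 1L,
        rname = "ref", pos = pos, end = end, svtype = svtype,
        signature = svtype, svlen = svlen, n_breakpoints = 2L,
        complex = FALSE, mimic = FALSE, qname = "q",
        qstart = pos, qend = pmax(end, pos + 1L),
        penalty = 0, stringsAsFactors = FALSE)
      row$segments <- list(data.frame(
        start = NA_integer_, end = NA_integer_, strand = "+",
        role = "insertion",
        seq = if (svtype == "INS") strrep("ACGT", len %/% 4L + 1L) else
          NA_character_, stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
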