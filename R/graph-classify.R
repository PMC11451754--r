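# Accepting variants on the optimal path and classifying composite
# rearrangement signatures. Maximal runs of accepted variants whose
# reference footprints lie within `merge_adjacent` bp collapse into one
# composite call (CSV) with a canonical signature such as "DEL-INV-DEL";
# isolated single-token events with at most two breakpoints keep their
# simple svtype.

empty_calls <- function() {
  out <- data.frame(sample = character(0), hap = integer(0),
                    rname = character(0), pos = integer(0), end = integer(0),
                    svtype = character(0), signature = character(0),
                    svlen = integer(0), n_breakpoints = integer(0),
                    complex = logical(0), mimic = logical(0),
                    qname = character(0), qstart = integer(0),
                    qend = integer(0), penalty = numeric(0))
  out$segments <- list()
  out
}

#' Accept variants on the optimal path and classify calls
#'
#' @param path result of [solve_optimal_path()].
#' @param graph the `variant_graph` the path was solved on.
#' @param records the alignment records underlying the graph.
#' @param ref,hap the aligned sequences.
#' @param params [sv_params()] configuration.
#' @param sample,hap_id identifiers stamped on the calls.
#' @return data frame of resolved calls; composite calls carry a hyphenated
#'   `signature` and `complex = TRUE` (more than two breakpoints). The
#'   `segments` list-column tiles each call's query span with reference
#'   intervals, strands, and roles, and is sufficient to reconstruct the
#'   haplotype allele.
#' @export
accept_and_classify <- function(path, graph, records, ref, hap,
                                params = sv_params(),
                                sample = "S1", hap_id = 1L) {
  rseq <- as_seq(ref); qseq <- as_seq(hap)
  path_nodes <- path$nodes
  rec_nodes <- path_nodes[path_nodes >= 1L & path_nodes <= graph$n_records]
  m <- length(rec_nodes)
  if (m == 0L) return(empty_calls())
  edges <- graph$edges[path$edge_idx, , drop = FALSE]
  # junction k sits between rec_nodes[k] and rec_nodes[k + 1]
  junctions <- vector("list", max(0L, m - 1L))
  for (e in seq_len(nrow(edges))) {
    if (edges$from[e] == 0L || edges$to[e] > graph$n_records) next
    k <- match(edges$from[e], rec_nodes)
    junctions[[k]] <- edges$variants[[e]]
  }
  has_var <- which(vapply(junctions, length, integer(1)) > 0L)
  if (!length(has_var)) {
    out <- empty_calls()
    attr(out, "path_records") <- rec_nodes
    return(out)
  }
  jfoot <- t(vapply(has_var, function(k) {
    vs <- junctions[[k]]
    c(min(vapply(vs, `[[`, integer(1), "rstart")),
      max(vapply(vs, `[[`, integer(1), "rend")))
  }, integer(2)))
  cl <- cluster_events(jfoot[, 1L], jfoot[, 2L], params$merge_adjacent)

  # junction index ranges per cluster, extended while an outer record is
  # strand-discordant so inverted copies stay interior to the call, then
  # merged where extension made ranges overlap
  ranges <- lapply(sort(unique(cl)), function(ci) {
    ks <- sort(has_var[cl == ci])
    k1 <- min(ks); k2 <- max(ks)
    while (k2 < m - 1L && records$strand[rec_nodes[k2 + 1L]] == "-") {
      k2 <- k2 + 1L
    }
    while (k1 > 1L && records$strand[rec_nodes[k1]] == "-") k1 <- k1 - 1L
    c(k1, k2)
  })
  ranges <- ranges[order(vapply(ranges, `[[`, numeric(1), 1L))]
  merged <- list(ranges[[1L]])
  for (r in ranges[-1L]) {
    last <- merged[[length(merged)]]
    if (r[1L] <= last[2L] + 0L) {
      merged[[length(merged)]] <- c(last[1L], max(last[2L], r[2L]))
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }

  calls <- list()
  for (rg in merged) {
    k1 <- rg[1L]; k2 <- rg[2L]
    vs <- unlist(lapply(k1:k2, function(k) junctions[[k]]),
                 recursive = FALSE)
    if (is.null(vs)) vs <- list()
    calls[[length(calls) + 1L]] <-
      classify_cluster(vs, k1, k2, rec_nodes, junctions, records,
                       rseq, qseq, params, sample, hap_id,
                       qname = records$qname[rec_nodes[1L]])
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$pos, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out$mimic <- flag_mimics(out, ref, params)
  attr(out, "path_records") <- rec_nodes
  out
}

classify_cluster <- function(vs, k1, k2, rec_nodes, junctions, records,
                             rseq, qseq, params, sample, hap_id, qname) {
  foot_s <- vapply(vs, `[[`, integer(1), "rstart")
  foot_e <- vapply(vs, `[[`, integer(1), "rend")
  pos <- min(foot_s); end <- max(foot_e)
  left0 <- records[rec_nodes[k1], ]
  right0 <- records[rec_nodes[k2 + 1L], ]
  # absorb sub-SV residual reference gaps at the outer junctions so the call
  # footprint meets the flanking alignments exactly
  if (left0$strand == "+" && left0$rend < pos) pos <- left0$rend
  if (right0$strand == "+" && right0$rstart > end) end <- right0$rstart
  ord <- order(foot_s, foot_e)
  vs_ref <- vs[ord]
  # collapse consecutive DUP edges over the same interval (up to junction
  # homology shifts bounded by the anchor k-mer size) into copy counts
  events <- list()
  for (v in vs_ref) {
    if (v$vclass == "DUP" && length(events)) {
      last <- events[[length(events)]]
      if (last$vclass == "DUP" &&
          abs(last$rstart - v$rstart) <= params$k &&
          abs(last$rend - v$rend) <= params$k) {
        last$copies <- last$copies + 1L
        events[[length(events)]] <- last
        next
      }
    }
    events[[length(events) + 1L]] <- v
  }
  toks <- unlist(lapply(events, function(v) {
    event_tokens(v$vclass, ref_len = v$rend - v$rstart,
                 copies = v$copies, min_sv = params$min_sv)
  }))
  bp <- count_breakpoints(lapply(events, function(v) {
    event_breakpoints(v$vclass, v$rstart, v$rend, copies = v$copies,
                      donor_start = v$donor_start, donor_end = v$donor_end)
  }))
  complex <- bp$n > 2L
  sig <- signature_string(toks)
  svtype <- if (!complex && length(toks) == 1L) toks else sig

  # segments tiling the query span between the outer anchor records
  left <- left0
  right <- right0
  segs <- list()
  add_seg <- function(start, end, strand, role, seq = NA_character_) {
    segs[[length(segs) + 1L]] <<- data.frame(
      start = start, end = end, strand = strand, role = role, seq = seq,
      stringsAsFactors = FALSE)
  }
  if (left$strand == "+" && left$rend > pos) {
    add_seg(pos, left$rend, "+", "flank-copy")
  }
  for (k in k1:k2) {
    alt_len <- 0L
    for (v in junctions[[k]]) {
      if (nzchar(v$alt_seq)) {
        alt_len <- alt_len + nchar(v$alt_seq)
        role <- if (v$vclass == "TEMPLATE_SWITCH") "donor" else "insertion"
        add_seg(v$donor_start, v$donor_end,
                if (is.na(v$donor_strand)) "+" else v$donor_strand,
                role, seq = v$alt_seq)
      }
    }
    # residual (sub-SV) query gap at this junction, kept as a segment so the
    # call remains a faithful tiling of the allele
    qgap <- records$qstart[rec_nodes[k + 1L]] - records$qend[rec_nodes[k]]
    if (qgap - alt_len > 0L) {
      add_seg(NA_integer_, NA_integer_, "+", "junction",
              seq = subseq0(qseq, records$qend[rec_nodes[k]] + alt_len,
                            records$qstart[rec_nodes[k + 1L]]))
    }
    if (k < k2) {
      inner <- records[rec_nodes[k + 1L], ]
      add_seg(inner$rstart, inner$rend, inner$strand,
              if (inner$strand == "-") "inverted" else "spacer")
    }
  }
  if (right$strand == "+" && right$rstart < end) {
    add_seg(right$rstart, end, "+", "flank-copy")
  }
  segdf <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               role = character(0), seq = character(0))
  content_len <- sum(vapply(seq_len(nrow(segdf)), function(i) {
    if (!is.na(segdf$seq[i])) nchar(segdf$seq[i])
    else segdf$end[i] - segdf$start[i]
  }, numeric(1)))
  svlen <- as.integer(content_len - (end - pos))

  # approximate query span of the allele (for cross-reference linking)
  qstart <- if (left$strand == "+") left$qend - max(0L, left$rend - pos)
            else left$qend
  qend <- if (right$strand == "+") {
    right$qstart + max(0L, end - right$rstart)
  } else right$qstart
  penalty <- sum(vapply(vs, score_variant, numeric(1), params = params))

  out <- data.frame(sample = sample, hap = hap_id, rname = left$rname,
                    pos = pos, end = end, svtype = svtype, signature = sig,
                    svlen = svlen, n_breakpoints = bp$n, complex = complex,
                    mimic = FALSE, qname = qname,
                    qstart = as.integer(qstart), qend = as.integer(qend),
                    penalty = penalty, stringsAsFactors = FALSE)
  out$segments <- list(segdf)
  out
}

#' Flag composite calls whose alignments mimic simple SVs
#'
#' A complex call mimics a simple deletion (net sequence loss) or duplication
#' (net gain) when a junction window of one of its interior inverted/donor
#' segments matches the reference in forward orientation — a paralogous
#' junction (typically an SD copy) that a naive aligner would absorb into the
#' flanking alignments, leaving an apparently simple event. Simple calls are
#' never mimics.
#'
#' @param calls resolved call data frame.
#' @param ref the reference sequence.
#' @param params [sv_params()] configuration (`mimic_window`, `mimic_cov`).
#' @return logical vector along the rows of `calls`.
#' @export
flag_mimics <- function(calls, ref, params = sv_params()) {
  if (!nrow(calls)) return(logical(0))
  rseq <- as_seq(ref)
  k <- params$k
  ref_kmers <- unique(kmer_set(rseq, k))
  vapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    if (!call$complex || call$svlen == 0L) return(FALSE)
    segs <- call$segments[[1L]]
    segs <- segs[segs$role %in% c("inverted", "donor", "insertion"), ,
                 drop = FALSE]
    if (!nrow(segs)) return(FALSE)
    for (j in seq_len(nrow(segs))) {
      seq <- if (!is.na(segs$seq[j])) segs$seq[j] else {
        s <- subseq0(rseq, segs$start[j], segs$end[j])
        if (segs$strand[j] == "-") revcomp(s) else s
      }
      w <- min(params$mimic_window, nchar(seq))
      if (w < k) next
      for (win in c(subseq0(seq, 0L, w),
                    subseq0(seq, nchar(seq) - w, nchar(seq)))) {
        km <- kmer_set(win, k)
        if (!length(km)) next
        cov <- mean(km %in% ref_kmers)
        if (cov >= params$mimic_cov) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

#' Reconstruct the haplotype implied by accepted calls
#'
#' Applies each call's segment tiling to the reference (right to left so
#' coordinates stay valid). On noise-free fixtures this reproduces the
#' aligned haplotype byte-identically.
#'
#' @param ref reference sequence.
#' @param calls resolved call data frame; calls must not overlap on the
#'   reference.
#' @param name name for the returned sequence.
#' @return a `genome_sequence`.
#' @export
reconstruct_haplotype <- function(ref, calls, name = "reconstructed") {
  rseq <- as_seq(ref)
  if (!nrow(calls)) return(genome_sequence(name, rseq))
  o <- order(calls$pos, calls$end)
  if (any(calls$pos[o][-1L] < calls$end[o][-length(o)])) {
    stop("calls overlap on the reference")
  }
  out <- rseq
  for (i in rev(o)) {
    segs <- calls$segments[[i]]
    content <- paste(vapply(seq_len(nrow(segs)), function(j) {
      if (!is.na(segs$seq[j])) return(segs$seq[j])
      s <- subseq0(rseq, segs$start[j], segs$end[j])
      if (segs$strand[j] == "-") revcomp(s) else s
    }, character(1)), collapse = "")
    out <- paste0(subseq0(out, 0L, calls$pos[i]), content,
                  subseq0(out, calls$end[i], nchar(out)))
  }
  genome_sequence(name, out)
}
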