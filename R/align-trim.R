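# Trimming of multiply-aligned query bases: after trimming, the query
# intervals of a contig's records are pairwise disjoint, so no haplotype base
# supports more than one alignment.

# Cut `n` query bases from the `side` of a record, where `side` is given in
# forward query space; the CIGAR is cut on the corresponding alignment side.
trim_record <- function(rec, n, side = c("left", "right")) {
  side <- match.arg(side)
  aln_side <- if (rec$strand == "+") side else setdiff(c("left", "right"), side)
  res <- cigar_cut_aln(cigar_parse(rec$cigar), n, aln_side)
  if (!nrow(res$tab)) return(NULL)
  if (aln_side == "left") rec$rstart <- rec$rstart + res$rcut
  else rec$rend <- rec$rend - res$rcut
  if (side == "left") rec$qstart <- rec$qstart + res$qcut
  else rec$qend <- rec$qend - res$qcut
  rec$cigar <- cigar_string(res$tab$len, res$tab$op)
  st <- record_stats(rec$cigar)
  rec$score <- st$score; rec$identity <- st$identity
  rec
}

#' Trim query-overlapping alignment records
#'
#' When two records of the same query overlap in query coordinates, the
#' lower-scoring record is trimmed at the overlap (its CIGAR re-cut); on
#' equal scores the record with the larger `qstart` is trimmed. Records
#' reduced below `min_keep` query bases are dropped. The operation is
#' idempotent and the output query intervals are pairwise disjoint.
#'
#' @param records alignment record data frame (one or more query names).
#' @param min_keep minimum surviving query length in bp.
#' @return trimmed record data frame with attribute `trim_log` (data frame of
#'   removed base counts and dropped records).
#' @export
trim_overlaps <- function(records, min_keep = 200L) {
  if (!nrow(records)) return(records)
  log <- data.frame(qname = character(0), action = character(0),
                    bases = integer(0), stringsAsFactors = FALSE)
  result <- list()
  for (qn in unique(records$qname)) {
    recs <- records[records$qname == qn, , drop = FALSE]
    recs <- recs[order(recs$qstart, recs$qend), , drop = FALSE]
    repeat {
      if (nrow(recs) < 2L) break
      ov_at <- NA_integer_
      for (i in seq_len(nrow(recs) - 1L)) {
        if (recs$qend[i] > recs$qstart[i + 1L]) { ov_at <- i; break }
      }
      if (is.na(ov_at)) break
      i <- ov_at; j <- ov_at + 1L
      ov <- recs$qend[i] - recs$qstart[j]
      loser <- if (recs$score[i] < recs$score[j]) i else j
      side <- if (loser == j) "left" else "right"
      trimmed <- trim_record(recs[loser, ], ov, side)
      log <- rbind(log, data.frame(qname = qn, action = "trim", bases = ov))
      if (is.null(trimmed) ||
          trimmed$qend - trimmed$qstart < min_keep) {
        log <- rbind(log, data.frame(qname = qn, action = "drop",
                                     bases = recs$qend[loser] -
                                       recs$qstart[loser]))
        recs <- recs[-loser, , drop = FALSE]
      } else {
        recs[loser, ] <- trimmed
      }
      recs <- recs[order(recs$qstart, recs$qend), , drop = FALSE]
    }
    result[[qn]] <- recs
  }
  out <- do.call(rbind, result)
  rownames(out) <- NULL
  attr(out, "trim_log") <- log
  out
}
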