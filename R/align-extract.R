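# Turning anchor chains into alignment records with full {=,X,I,D} CIGARs.
#
# Conventions: all coordinates 0-based half-open; query coordinates of
# minus-strand records are stored query-forward (PAF convention) while the
# CIGAR is stored in alignment orientation (reference forward, query
# reverse-complemented); reference intervals always satisfy rstart < rend.

empty_records <- function() {
  data.frame(qname = character(0), qlen = integer(0), qstart = integer(0),
             qend = integer(0), strand = character(0), rname = character(0),
             rlen = integer(0), rstart = integer(0), rend = integer(0),
             cigar = character(0), score = numeric(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

record_stats <- function(cigar) {
  cc <- cigar_consumed(cigar)
  list(score = cc$match - cc$mismatch - cc$gap,
       identity = if (cc$match + cc$mismatch + cc$gap > 0) {
         cc$match / (cc$match + cc$mismatch + cc$gap)
       } else 0)
}

# Internal: one finished record row from alignment-relative pieces.
finish_record <- function(qname, qlen, rname, rlen, strand,
                          qs, Lq, aln_q0, aln_q1, r0, r1, rows) {
  cigar <- cigar_string(vapply(rows, `[[`, numeric(1), "len"),
                        vapply(rows, `[[`, character(1), "op"))
  if (strand == "+") {
    qstart <- qs + aln_q0; qend <- qs + aln_q1
  } else {
    qstart <- qs + (Lq - aln_q1); qend <- qs + (Lq - aln_q0)
  }
  st <- record_stats(cigar)
  data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
             strand = strand, rname = rname, rlen = rlen,
             rstart = r0, rend = r1, cigar = cigar,
             score = st$score, identity = st$identity,
             stringsAsFactors = FALSE)
}

#' Extract alignment records from anchor chains
#'
#' Within each chain, same-diagonal anchor runs become match/mismatch blocks
#' by direct base comparison; inter-run gaps up to `band` bp are closed by
#' global edit alignment; larger gaps terminate the record.
#'
#' @param chains list from [chain_anchors()].
#' @param ref,hap the aligned sequences.
#' @param k anchor k-mer size used to build the chains.
#' @param band maximum gap closed within one record (bp).
#' @return alignment record data frame sorted by `qstart`.
#' @export
extract_records <- function(chains, ref, hap, k = 31L, band = 2000L) {
  rseq <- as_seq(ref); qseq_fwd <- as_seq(hap)
  rname <- seq_name(ref, "ref"); qname <- seq_name(hap, "hap")
  rlen <- nchar(rseq); qlen <- nchar(qseq_fwd)
  out <- list()
  for (ch in chains) {
    if (!nrow(ch)) next
    strand <- attr(ch, "strand")
    qs <- min(ch$qpos); qe <- max(ch$qpos) + k
    Lq <- qe - qs
    if (strand == "+") {
      qa <- ch$qpos - qs
      ra <- ch$rpos
      seg <- subseq0(qseq_fwd, qs, qe)
    } else {
      qa <- qe - ch$qpos - k
      ra <- ch$rpos
      o <- order(qa)
      qa <- qa[o]; ra <- ra[o]
      seg <- revcomp(subseq0(qseq_fwd, qs, qe))
    }
    # same-diagonal runs
    dg <- ra - qa
    r <- rle(dg)
    ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1L) + 1L)
    runs <- data.frame(q0 = qa[starts], q1 = qa[ends] + k,
                       r0 = ra[starts], r1 = ra[ends] + k)

    rows <- list(); aln_q0 <- runs$q0[1L]; r0 <- runs$r0[1L]
    prev_q <- aln_q0; prev_r <- r0
    flush <- function(i_next) {
      if (length(rows)) {
        out[[length(out) + 1L]] <<- finish_record(
          qname, qlen, rname, rlen, strand, qs, Lq,
          aln_q0, prev_q, r0, prev_r, rows)
      }
      rows <<- list()
      if (!is.na(i_next)) {
        aln_q0 <<- runs$q0[i_next]; r0 <<- runs$r0[i_next]
        prev_q <<- aln_q0; prev_r <<- r0
      }
    }
    emit_block <- function(q0, q1, rr0, rr1) {
      cmp <- cigar_compare(subseq0(seg, q0, q1), subseq0(rseq, rr0, rr1))
      for (ii in seq_len(nrow(cmp))) {
        rows[[length(rows) + 1L]] <<- list(len = cmp$len[ii], op = cmp$op[ii])
      }
      prev_q <<- q1; prev_r <<- rr1
    }
    trim_back <- function(n) {
      # previous emission ends in =/X blocks; shrink by n bases (both q and r)
      left <- n
      while (left > 0L && length(rows)) {
        tailrow <- rows[[length(rows)]]
        take <- min(tailrow$len, left)
        tailrow$len <- tailrow$len - take
        left <- left - take
        if (tailrow$len == 0L) {
          rows[[length(rows)]] <<- NULL
        } else {
          rows[[length(rows)]] <<- tailrow
        }
      }
      prev_q <<- prev_q - n; prev_r <<- prev_r - n
    }

    for (i in seq_len(nrow(runs))) {
      if (i > 1L) {
        ot <- max(0L, prev_q - runs$q0[i], prev_r - runs$r0[i])
        if (ot > 0L) trim_back(ot)
        qgap <- runs$q0[i] - prev_q
        rgap <- runs$r0[i] - prev_r
        if (max(qgap, rgap) > band) {
          flush(i)
        } else if (qgap > 0L && rgap > 0L) {
          aln <- nw_align(subseq0(seg, prev_q, runs$q0[i]),
                          subseq0(rseq, prev_r, runs$r0[i]))
          for (ii in seq_len(nrow(aln$tab))) {
            rows[[length(rows) + 1L]] <-
              list(len = aln$tab$len[ii], op = aln$tab$op[ii])
          }
          prev_q <- runs$q0[i]; prev_r <- runs$r0[i]
        } else if (rgap > 0L) {
          rows[[length(rows) + 1L]] <- list(len = rgap, op = "D")
          prev_r <- runs$r0[i]
        } else if (qgap > 0L) {
          rows[[length(rows) + 1L]] <- list(len = qgap, op = "I")
          prev_q <- runs$q0[i]
        }
      }
      emit_block(runs$q0[i], runs$q1[i], runs$r0[i], runs$r1[i])
    }
    flush(NA)
  }
  recs <- if (length(out)) do.call(rbind, out) else empty_records()
  recs <- recs[order(recs$qstart, recs$qend), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Split records at large internal indels
#'
#' Internal CIGAR `I`/`D` runs of at least `min_indel` bp split the record so
#' that every SV-scale event is represented between records and can enter the
#' variant graph.
#'
#' @param records alignment record data frame.
#' @param min_indel split threshold in bp.
#' @return record data frame sorted by `qstart`.
#' @export
split_records <- function(records, min_indel = 50L) {
  if (!nrow(records)) return(records)
  out <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    tab <- cigar_parse(rec$cigar)
    big <- which(tab$op %in% c("I", "D") & tab$len >= min_indel)
    if (!length(big)) {
      out[[length(out) + 1L]] <- rec
      next
    }
    qoff <- cumsum(c(0L, ifelse(tab$op %in% QUERY_OPS, tab$len, 0L)))
    roff <- cumsum(c(0L, ifelse(tab$op %in% REF_OPS, tab$len, 0L)))
    bounds <- rbind(c(0L, big), c(big, nrow(tab) + 1L))
    for (p in seq_len(ncol(bounds))) {
      lo <- bounds[1L, p] + 1L; hi <- bounds[2L, p] - 1L
      if (lo > hi) next
      piece <- tab[lo:hi, , drop = FALSE]
      qa <- qoff[lo]; qb <- qoff[hi + 1L]
      ra <- roff[lo]; rb <- roff[hi + 1L]
      if (qb == qa && rb == ra) next
      if (rec$strand == "+") {
        qstart <- rec$qstart + qa; qend <- rec$qstart + qb
      } else {
        qstart <- rec$qend - qb; qend <- rec$qend - qa
      }
      st <- record_stats(cigar_string(piece$len, piece$op))
      out[[length(out) + 1L]] <- data.frame(
        qname = rec$qname, qlen = rec$qlen, qstart = qstart, qend = qend,
        strand = rec$strand, rname = rec$rname, rlen = rec$rlen,
        rstart = rec$rstart + ra, rend = rec$rstart + rb,
        cigar = cigar_string(piece$len, piece$op),
        score = st$score, identity = st$identity, stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, out)
  recs <- recs[order(recs$qstart, recs$qend), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Validate alignment record invariants
#'
#' Checks the CIGAR consumption identities (query bases consumed equal
#' `qend - qstart`, reference bases consumed equal `rend - rstart`) and
#' coordinate sanity for every record.
#'
#' @param records alignment record data frame.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_records <- function(records) {
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    cc <- cigar_consumed(rec$cigar)
    if (cc$q != rec$qend - rec$qstart) {
      stop("record ", i, ": CIGAR query consumption ", cc$q,
           " != qend - qstart = ", rec$qend - rec$qstart)
    }
    if (cc$r != rec$rend - rec$rstart) {
      stop("record ", i, ": CIGAR reference consumption ", cc$r,
           " != rend - rstart = ", rec$rend - rec$rstart)
    }
    if (rec$qstart < 0 || rec$qstart >= rec$qend || rec$qend > rec$qlen ||
        rec$rstart < 0 || rec$rstart >= rec$rend || rec$rend > rec$rlen) {
      stop("record ", i, ": coordinates out of bounds")
    }
  }
  invisible(TRUE)
}
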