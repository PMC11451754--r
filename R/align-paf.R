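# PAF interchange: records carry their CIGAR in the cg:Z tag. Query
# coordinates of minus-strand lines are already query-forward per the PAF
# convention, matching the internal representation.

#' Write alignment records as PAF
#'
#' @param records alignment record data frame.
#' @param path output path.
#' @export
write_paf <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    cc <- cigar_consumed(rec$cigar)
    paste(rec$qname, rec$qlen, rec$qstart, rec$qend, rec$strand,
          rec$rname, rec$rlen, rec$rstart, rec$rend,
          cc$match, cc$match + cc$mismatch + cc$gap, 60L,
          paste0("cg:Z:", rec$cigar), sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read alignment records from PAF
#'
#' Lines must carry a `cg:Z` CIGAR tag. CIGARs using `M` are converted to
#' `=`/`X` by sequence lookup when both sequences are supplied, otherwise the
#' record is rejected. Malformed lines are skipped; counts of rejected lines
#' are attached as attribute `rejected`.
#'
#' @param path PAF file path.
#' @param ref,hap optional sequences (named lists or `genome_sequence`) for
#'   `M`-op resolution.
#' @return alignment record data frame.
#' @export
read_paf <- function(path, ref = NULL, hap = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rejected <- 0L
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) { rejected <- rejected + 1L; next }
    cg <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (!length(cg)) { rejected <- rejected + 1L; next }
    cigar <- sub("^cg:Z:", "", cg[1L])
    nums <- suppressWarnings(as.numeric(f[c(2:4, 7:9)]))
    if (anyNA(nums) || !f[5] %in% c("+", "-")) {
      rejected <- rejected + 1L; next
    }
    if (any(nums > .Machine$integer.max)) {
      stop("coordinate overflow in PAF line")
    }
    if (grepl("M", cigar, fixed = TRUE)) {
      resolved <- resolve_m_ops(cigar, f, ref, hap)
      if (is.null(resolved)) { rejected <- rejected + 1L; next }
      cigar <- resolved
    }
    st <- record_stats(cigar)
    out[[length(out) + 1L]] <- data.frame(
      qname = f[1], qlen = as.integer(f[2]), qstart = as.integer(f[3]),
      qend = as.integer(f[4]), strand = f[5], rname = f[6],
      rlen = as.integer(f[7]), rstart = as.integer(f[8]),
      rend = as.integer(f[9]), cigar = cigar,
      score = st$score, identity = st$identity, stringsAsFactors = FALSE)
  }
  recs <- if (length(out)) do.call(rbind, out) else empty_records()
  attr(recs, "rejected") <- rejected
  recs
}

# Convert M runs to =/X by comparing the aligned substrings; returns NULL
# when sequences are unavailable.
resolve_m_ops <- function(cigar, f, ref, hap) {
  get_seq <- function(pool, nm) {
    if (is.null(pool)) return(NULL)
    if (inherits(pool, "genome_sequence")) {
      if (pool$name == nm) return(pool$seq) else return(NULL)
    }
    if (!is.null(pool[[nm]])) return(as_seq(pool[[nm]])) else NULL
  }
  rseq <- get_seq(ref, f[6]); qseq <- get_seq(hap, f[1])
  if (is.null(rseq) || is.null(qseq)) return(NULL)
  qstart <- as.integer(f[3]); qend <- as.integer(f[4])
  rstart <- as.integer(f[8])
  strand <- f[5]
  qa <- if (strand == "+") subseq0(qseq, qstart, qend)
        else revcomp(subseq0(qseq, qstart, qend))
  tab <- cigar_parse(cigar)
  qoff <- 0L; roff <- 0L
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    op <- tab$op[i]; len <- tab$len[i]
    if (op == "M") {
      cmp <- cigar_compare(subseq0(qa, qoff, qoff + len),
                           subseq0(rseq, rstart + roff, rstart + roff + len))
      for (j in seq_len(nrow(cmp))) {
        rows[[length(rows) + 1L]] <- list(len = cmp$len[j], op = cmp$op[j])
      }
      qoff <- qoff + len; roff <- roff + len
    } else {
      rows[[length(rows) + 1L]] <- list(len = len, op = op)
      if (op %in% QUERY_OPS) qoff <- qoff + len
      if (op %in% REF_OPS) roff <- roff + len
    }
  }
  cigar_string(vapply(rows, `[[`, numeric(1), "len"),
               vapply(rows, `[[`, character(1), "op"))
}
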