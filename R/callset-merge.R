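# Cross-sample nonredundant merging: 50% reciprocal overlap and 80% sequence
# identity, with breakpoint-proximity matching for insertions whose
# reference footprint is empty.

#' Reciprocal overlap of two half-open intervals
#'
#' `min(overlap/|a|, overlap/|b|)`; 0 when disjoint.
#'
#' @param a_start,a_end,b_start,b_end 0-based half-open interval bounds.
#' @return fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  la <- a_end - a_start; lb <- b_end - b_start
  if (any(la <= 0) || any(lb <= 0)) stop("zero-length interval")
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  pmin(ov / la, ov / lb)
}

#' Global sequence identity
#'
#' Matches divided by alignment columns of a global alignment with unit
#' match and -1 mismatch/gap scores. Symmetric in its arguments.
#'
#' @param a_seq,b_seq nonempty DNA strings.
#' @param max_len sequences longer than this are compared through their
#'   first and last `max_len/2` bases (guards the quadratic alignment).
#' @return fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a_seq, b_seq, max_len = 6000L) {
  if (!nzchar(a_seq) || !nzchar(b_seq)) stop("empty sequence")
  if (a_seq == b_seq) return(1.0)
  if (nchar(a_seq) > max_len || nchar(b_seq) > max_len) {
    h <- max_len %/% 2L
    clip <- function(s) {
      if (nchar(s) <= max_len) s
      else paste0(subseq0(s, 0L, h), subseq0(s, nchar(s) - h, nchar(s)))
    }
    a_seq <- clip(a_seq); b_seq <- clip(b_seq)
  }
  aln <- nw_align(a_seq, b_seq, match = 1L, mismatch = -1L, gap = -1L)
  cols <- sum(aln$tab$len)
  sum(aln$tab$len[aln$tab$op == "="]) / cols
}

# do calls a and b (single rows) satisfy the merge criteria?
calls_mergeable <- function(a, b, ro_min, ident_min, ins_bp = 500L,
                            ins_len_ratio = 0.5) {
  if (a$rname != b$rname || a$svtype != b$svtype) return(FALSE)
  seqful <- function(x) {
    if (is.null(x$segments)) return(FALSE)
    segs <- x$segments[[1L]]
    !is.null(segs) && nrow(segs) > 0 && any(!is.na(segs$seq))
  }
  get_seq <- function(x) {
    segs <- x$segments[[1L]]
    paste(segs$seq[!is.na(segs$seq)], collapse = "")
  }
  if (a$end == a$pos || b$end == b$pos) {
    # insertion-like: breakpoint proximity + length ratio gate, then identity
    if (abs(a$pos - b$pos) > ins_bp) return(FALSE)
    la <- max(1L, abs(a$svlen)); lb <- max(1L, abs(b$svlen))
    if (min(la, lb) / max(la, lb) < ins_len_ratio) return(FALSE)
  } else {
    ro <- reciprocal_overlap(a$pos, a$end, b$pos, b$end)
    if (ro < ro_min) return(FALSE)
  }
  if (seqful(a) && seqful(b)) {
    sa <- get_seq(a); sb <- get_seq(b)
    if (nzchar(sa) && nzchar(sb)) {
      # identity is bounded by the length ratio; skip the alignment when the
      # bound alone rules the pair out
      ratio <- min(nchar(sa), nchar(sb)) / max(nchar(sa), nchar(sb))
      if (ratio < ident_min) return(FALSE)
      if (sequence_identity(sa, sb) < ident_min) return(FALSE)
    }
  }
  TRUE
}

#' Merge per-haplotype callsets into a nonredundant population callset
#'
#' Greedy lead-first merge: candidates are sorted by descending current
#' support, then position, then sample id; a call joins an existing merged
#' variant iff it satisfies reciprocal overlap >= `ro_min` against the lead
#' (insertions: breakpoint proximity <= 500 bp and length ratio >= 0.5) and,
#' when both calls carry sequence, identity >= `ident_min`. Exact duplicate
#' (sample, hap, coordinates) records are deduplicated with a warning.
#'
#' @param calls data frame of resolved calls across haplotypes (rows carry
#'   `sample` and `hap`).
#' @param ro_min minimum reciprocal overlap (default 0.50).
#' @param ident_min minimum sequence identity (default 0.80).
#' @return data frame of merged variants: the lead call's columns plus
#'   `allele_count` and a `carriers` list-column of `sample#hap` ids.
#' @export
merge_nonredundant <- function(calls, ro_min = 0.50, ident_min = 0.80) {
  if (!nrow(calls)) {
    out <- calls
    out$allele_count <- integer(0)
    out$carriers <- list()
    return(out)
  }
  key <- paste(calls$sample, calls$hap, calls$rname, calls$pos, calls$end,
               calls$svtype)
  if (anyDuplicated(key)) {
    warning("duplicate (sample, hap, coordinates) calls deduplicated")
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  calls <- calls[order(calls$rname, calls$pos, calls$end, calls$sample,
                       calls$hap), , drop = FALSE]
  rownames(calls) <- NULL
  n <- nrow(calls)
  assigned <- rep(NA_integer_, n)
  leads <- integer(0)
  # iterative lead selection by (support, position, sample); with all
  # supports starting at 1 this is position order, re-sorted as groups grow
  repeat {
    todo <- which(is.na(assigned))
    if (!length(todo)) break
    lead <- todo[1L]
    leads <- c(leads, lead)
    assigned[lead] <- lead
    for (i in todo[-1L]) {
      if (calls_mergeable(calls[lead, ], calls[i, ], ro_min, ident_min)) {
        assigned[i] <- lead
      }
    }
  }
  out <- lapply(leads, function(ld) {
    members <- which(assigned == ld)
    row <- calls[ld, , drop = FALSE]
    row$allele_count <- length(members)
    row$carriers <- list(sprintf("%s#%d", calls$sample[members],
                                 calls$hap[members]))
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$rname, out$pos, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allele frequencies of merged variants
#'
#' `af = carriers / counted haplotypes`, with excluded samples (for example
#' trio children) removed from both numerator and denominator.
#'
#' @param merged merged variant data frame from [merge_nonredundant()].
#' @param n_haplotypes total haplotypes in the cohort before exclusion.
#' @param haplotypes_per_sample haplotypes each excluded sample contributes
#'   (2 for diploid samples).
#' @param excluded_samples character vector of sample ids to exclude.
#' @return `merged` with columns `allele_count` (post-exclusion) and `af`.
#' @export
allele_frequency <- function(merged, n_haplotypes,
                             excluded_samples = character(0),
                             haplotypes_per_sample = 2L) {
  denom <- n_haplotypes - length(excluded_samples) * haplotypes_per_sample
  if (denom <= 0) stop("no haplotypes left after exclusion")
  merged$allele_count <- vapply(merged$carriers, function(cc) {
    smp <- sub("#.*$", "", cc)
    sum(!smp %in% excluded_samples)
  }, integer(1))
  merged$af <- merged$allele_count / denom
  merged
}
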