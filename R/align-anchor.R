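# Anchor seeding and colinear chaining. Anchors are exact k-mer matches
# between haplotype and reference, restricted to k-mers that are unique in
# the reference under canonical (strand-collapsed) counting, so repeated
# sequence (e.g. both copies of a high-identity SD stretch) never anchors.

#' Find unique k-mer anchors between a haplotype and a reference
#'
#' @param ref,hap `genome_sequence` objects or plain strings.
#' @param k odd k-mer size; default 31.
#' @return data frame with 0-based columns `qpos`, `rpos`, `strand`, sorted
#'   by `qpos`. Every anchor is an exact match of `hap[qpos, qpos+k)` to
#'   `ref[rpos, rpos+k)` (`+`) or to its reverse complement (`-`). Empty when
#'   either sequence is shorter than `k`.
#' @export
index_and_anchor <- function(ref, hap, k = 31L) {
  if (k %% 2L == 0L) stop("k must be odd")
  rseq <- as_seq(ref); qseq <- as_seq(hap)
  empty <- data.frame(qpos = integer(0), rpos = integer(0),
                      strand = character(0))
  if (nchar(rseq) < k || nchar(qseq) < k) return(empty)
  rk <- kmer_set(rseq, k)
  # k-mers of the reverse-complemented sequence, mirrored back into forward
  # coordinates (cheaper than reverse-complementing each k-mer)
  rk_rc <- rev(kmer_set(revcomp(rseq), k))
  rcanon <- pmin(rk, rk_rc)
  # N never matches; palindromic k-mers are strand-ambiguous (k odd makes
  # exact palindromes impossible for ACGT, but N-containing ones are dropped)
  valid <- !grepl("N", rk, fixed = TRUE)
  dup <- duplicated(rcanon) | duplicated(rcanon, fromLast = TRUE)
  keep <- valid & !dup
  canon_keep <- rcanon[keep]
  pos_keep <- which(keep)  # 1-based start positions

  qk <- kmer_set(qseq, k)
  qk_rc <- rev(kmer_set(revcomp(qseq), k))
  qcanon <- pmin(qk, qk_rc)
  idx <- match(qcanon, canon_keep)
  hit <- which(!is.na(idx) & !grepl("N", qk, fixed = TRUE))
  if (!length(hit)) return(empty)
  rpos1 <- pos_keep[idx[hit]]
  fwd <- qk[hit] == rk[rpos1]
  data.frame(qpos = hit - 1L, rpos = rpos1 - 1L,
             strand = ifelse(fwd, "+", "-"), stringsAsFactors = FALSE)
}

#' Chain anchors into maximal colinear runs
#'
#' Walking anchors in query order, a chain breaks on strand change, on loss
#' of reference monotonicity (increasing on `+`, decreasing on `-`), or when
#' the diagonal shift between consecutive anchors exceeds `max_gap`.
#'
#' @param anchors anchor data frame from [index_and_anchor()].
#' @param max_gap maximum diagonal shift in bp (default 10 kbp).
#' @param min_anchors chains with fewer anchors are dropped.
#' @return list of chains; each chain is a data frame of its anchors with an
#'   attribute `strand`.
#' @export
chain_anchors <- function(anchors, max_gap = 10000L, min_anchors = 2L) {
  n <- nrow(anchors)
  if (!n) return(list())
  a <- anchors[order(anchors$qpos), , drop = FALSE]
  diag <- ifelse(a$strand == "+", a$rpos - a$qpos, a$rpos + a$qpos)
  if (n == 1L) {
    brk <- logical(0)
  } else {
    prev <- seq_len(n - 1L); cur <- prev + 1L
    strand_chg <- a$strand[cur] != a$strand[prev]
    mono_bad <- ifelse(a$strand[cur] == "+",
                       a$rpos[cur] <= a$rpos[prev],
                       a$rpos[cur] >= a$rpos[prev])
    diag_jump <- abs(diag[cur] - diag[prev]) > max_gap
    brk <- strand_chg | mono_bad | diag_jump
  }
  id <- cumsum(c(1L, as.integer(brk)))
  chains <- split(a, id)
  chains <- Filter(function(ch) nrow(ch) >= min_anchors, chains)
  lapply(chains, function(ch) {
    attr(ch, "strand") <- ch$strand[1L]
    ch
  })
}
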