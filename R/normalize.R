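# Canonical breakpoint normalization. Breakpoints of deletions, insertions
# and inversions are ambiguous under junction homology (the same haplotype
# admits several equivalent placements); these helpers map any equivalent
# placement to a canonical one so that placements can be compared exactly.

#' Canonical (left-aligned) deletion placement
#'
#' Shifts a deletion left while the base preceding the interval equals the
#' last deleted base, the standard VCF-style normalization.
#'
#' @param ref reference sequence.
#' @param start,end 0-based half-open deleted interval.
#' @return integer vector `c(start, end)` of the canonical placement.
#' @export
normalize_del <- function(ref, start, end) {
  rseq <- as_seq(ref)
  while (start > 0L &&
         substr(rseq, start, start) == substr(rseq, end, end)) {
    start <- start - 1L; end <- end - 1L
  }
  c(start, end)
}

#' Canonical (left-rotated) insertion placement
#'
#' Rotates the inserted sequence left while its last base equals the
#' reference base preceding the insertion point.
#'
#' @param ref reference sequence.
#' @param pos 0-based insertion point.
#' @param alt inserted sequence.
#' @return list with `pos` and `alt` of the canonical placement.
#' @export
normalize_ins <- function(ref, pos, alt) {
  rseq <- as_seq(ref)
  n <- nchar(alt)
  while (pos > 0L && n > 0L &&
         substr(rseq, pos, pos) == substr(alt, n, n)) {
    alt <- paste0(substr(alt, n, n), substr(alt, 1L, n - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, alt = alt)
}

#' Canonical (maximally expanded) inversion placement
#'
#' Expands an inversion symmetrically while the base before the interval is
#' the complement of the base just past it — the condition under which the
#' one-larger inversion produces the same haplotype.
#'
#' @param ref reference sequence.
#' @param start,end 0-based half-open inverted interval.
#' @return integer vector `c(start, end)` of the canonical placement.
#' @export
normalize_inv <- function(ref, start, end) {
  rseq <- as_seq(ref)
  L <- nchar(rseq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  while (start > 0L && end < L &&
         substr(rseq, start, start) ==
           comp[[substr(rseq, end + 1L, end + 1L)]]) {
    start <- start - 1L; end <- end + 1L
  }
  c(start, end)
}
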