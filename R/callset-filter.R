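# Region masking (e.g. centromeric satellite annotations) and
# cross-reference linking through assembly coordinates.

#' Read a BED mask
#'
#' @param path BED3(+) file; 0-based half-open.
#' @return a `region_mask`: named list of sorted, merged interval data
#'   frames per reference name.
#' @export
read_mask <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  region_mask(bed[[1]], bed[[2]], bed[[3]])
}

#' @param chrom,start,end vectors defining mask intervals.
#' @rdname read_mask
#' @export
region_mask <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  out <- lapply(split(data.frame(start = start, end = end), chrom),
                function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
    data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  structure(out, class = "region_mask")
}

#' Filter calls against a region mask
#'
#' `mode = "any-overlap"` removes a call touching a masked base (the rule
#' applied to complex calls over centromeric repeats); `mode = "contained"`
#' removes only calls fully inside the mask.
#'
#' @param calls resolved or merged call data frame.
#' @param mask a `region_mask`.
#' @param mode `"any-overlap"` or `"contained"`.
#' @return filtered calls; removal count in attribute `removed`.
#' @export
filter_mask <- function(calls, mask, mode = c("any-overlap", "contained")) {
  mode <- match.arg(mode)
  if (!nrow(calls) || !length(mask)) {
    attr(calls, "removed") <- 0L
    return(calls)
  }
  drop <- vapply(seq_len(nrow(calls)), function(i) {
    iv <- mask[[calls$rname[i]]]
    if (is.null(iv)) return(FALSE)
    s <- calls$pos[i]; e <- max(calls$end[i], calls$pos[i] + 1L)
    ov <- pmax(0L, pmin(e, iv$end) - pmax(s, iv$start))
    if (mode == "any-overlap") any(ov > 0L) else sum(ov) >= (e - s)
  }, logical(1))
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(drop)
  out
}

#' Link variants across two references through assembly coordinates
#'
#' Calls from the same haplotype contig are linked when their query
#' (assembly) intervals overlap reciprocally by at least `ro_min` and the
#' variant class matches. Symmetric: linking A to B mirrors B to A.
#'
#' @param callset_a,callset_b call data frames against two references, both
#'   retaining `qname`, `qstart`, `qend`.
#' @param ro_min minimum reciprocal query overlap.
#' @return data frame of linked index pairs (`idx_a`, `idx_b`) with the
#'   query overlap fraction; skipped calls (missing query coordinates)
#'   counted in attribute `skipped`.
#' @export
link_across_references <- function(callset_a, callset_b, ro_min = 0.5) {
  skipped <- 0L
  usable <- function(df) {
    ok <- !is.na(df$qstart) & !is.na(df$qend) & df$qend >= df$qstart
    skipped <<- skipped + sum(!ok)
    ok
  }
  ok_a <- usable(callset_a); ok_b <- usable(callset_b)
  pairs <- list()
  for (i in which(ok_a)) {
    for (j in which(ok_b)) {
      a <- callset_a[i, ]; b <- callset_b[j, ]
      if (a$sample != b$sample || a$hap != b$hap || a$qname != b$qname) next
      if (a$svtype != b$svtype) next
      # breakpoint-only calls (e.g. deletions) occupy a single query base
      ro <- reciprocal_overlap(a$qstart, max(a$qend, a$qstart + 1L),
                               b$qstart, max(b$qend, b$qstart + 1L))
      if (ro >= ro_min) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(idx_a = i, idx_b = j, query_ro = ro)
      }
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(idx_a = integer(0), idx_b = integer(0), query_ro = numeric(0))
  attr(out, "skipped") <- skipped
  out
}
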