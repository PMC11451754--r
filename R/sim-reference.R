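# Simulated references with segmental duplication (SD) structure. SDs follow
# the standard definition used for human assemblies: paired intervals >1 kbp
# with >90% sequence identity, in direct or inverted orientation.

#' Specify a segmental duplication pair
#'
#' @param start_a,end_a 0-based half-open interval of the first copy.
#' @param start_b,end_b interval of the second copy; must be the same length
#'   and disjoint from the first.
#' @param orientation `"direct"` or `"inverted"`.
#' @param identity_pct pairwise identity of the two copies, in (90, 100].
#' @return a list of class `sd_spec`.
#' @export
sd_spec <- function(start_a, end_a, start_b, end_b,
                    orientation = c("direct", "inverted"),
                    identity_pct = 98) {
  orientation <- match.arg(orientation)
  stopifnot(end_a > start_a, end_b > start_b, start_a >= 0, start_b >= 0)
  if ((end_a - start_a) != (end_b - start_b)) {
    stop("SD copies must have equal length")
  }
  if ((end_a - start_a) <= 1000L) {
    stop("SD copies must be longer than 1 kbp")
  }
  if (identity_pct <= 90 || identity_pct > 100) {
    stop("SD identity must be in (90, 100] percent")
  }
  if (max(start_a, start_b) < min(end_a, end_b)) {
    stop("SD intervals overlap")
  }
  structure(list(start_a = as.integer(start_a), end_a = as.integer(end_a),
                 start_b = as.integer(start_b), end_b = as.integer(end_b),
                 orientation = orientation, identity_pct = identity_pct),
            class = "sd_spec")
}

#' Simulate a reference sequence with SD pairs
#'
#' Generates an i.i.d. random base sequence, then implants each SD pair by
#' copying interval A into interval B (reverse-complemented for inverted
#' pairs) and substituting bases at rate `100 - identity_pct` percent, so the
#' two copies diverge by point substitutions only. Deterministic for a fixed
#' seed.
#'
#' @param seed integer RNG seed.
#' @param length reference length in bp; at least 10 kbp.
#' @param sd_specs list of [sd_spec()] objects; intervals must be pairwise
#'   disjoint and fit within `length`.
#' @param name reference sequence name.
#' @param gc GC content passed to [random_dna()].
#' @return a `genome_sequence` with attribute `sd_table` (data frame of SD
#'   intervals, orientation, and identity).
#' @export
make_reference <- function(seed, length, sd_specs = list(), name = "ref",
                           gc = 0.5) {
  stopifnot(length >= 10000L)
  ivs <- do.call(rbind, lapply(sd_specs, function(s) {
    data.frame(start = c(s$start_a, s$start_b), end = c(s$end_a, s$end_b))
  }))
  if (!is.null(ivs)) {
    if (max(ivs$end) > length) stop("SD intervals do not fit in reference")
    o <- order(ivs$start)
    if (any(ivs$start[o][-1L] < ivs$end[o][-nrow(ivs)])) {
      stop("SD intervals overlap")
    }
  }
  with_seed(seed, {
    seq <- random_dna(length, gc = gc)
    for (s in sd_specs) {
      copy <- subseq0(seq, s$start_a, s$end_a)
      if (s$orientation == "inverted") copy <- revcomp(copy)
      rate <- (100 - s$identity_pct) / 100
      if (rate > 0) copy <- substitute_bases(copy, rate)
      substr(seq, s$start_b + 1L, s$end_b) <- copy
    }
    ref <- genome_sequence(name, seq)
    attr(ref, "sd_table") <- if (length(sd_specs)) {
      do.call(rbind, lapply(seq_along(sd_specs), function(i) {
        s <- sd_specs[[i]]
        data.frame(sd = i, start_a = s$start_a, end_a = s$end_a,
                   start_b = s$start_b, end_b = s$end_b,
                   orientation = s$orientation,
                   identity_pct = s$identity_pct)
      }))
    } else {
      data.frame()
    }
    ref
  })
}

# Substitute a fraction `rate` of positions, always to a different base.
substitute_bases <- function(seq, rate) {
  n <- nchar(seq)
  k <- round(rate * n)
  if (k == 0) return(seq)
  pos <- sort(sample.int(n, k))
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  alt <- vapply(bases[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1))
  bases[pos] <- alt
  paste(bases, collapse = "")
}
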