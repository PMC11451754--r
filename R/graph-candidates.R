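# Candidate variant enumeration between trimmed alignment records, and the
# penalty model used to weight them in the variant graph.

new_candidate <- function(vclass, rstart, rend, alt_seq = "",
                          donor_start = NA_integer_, donor_end = NA_integer_,
                          donor_strand = NA_character_, copies = 2L,
                          align_frac = 0) {
  stopifnot(vclass %in% c("DEL", "INS", "INV", "DUP", "INVDUP",
                          "TEMPLATE_SWITCH"))
  if (vclass == "DEL" && nzchar(alt_seq)) stop("DEL carries no sequence")
  if (vclass == "INS" && rend != rstart) stop("INS has an empty ref interval")
  list(vclass = vclass, rstart = as.integer(rstart), rend = as.integer(rend),
       alt_seq = alt_seq, donor_start = as.integer(donor_start),
       donor_end = as.integer(donor_end), donor_strand = donor_strand,
       copies = as.integer(copies), align_frac = align_frac)
}

#' Penalty of a candidate variant
#'
#' The base penalty is `open(class) + size_coef * log2(1 + span)`, the span
#' being the larger of the reference footprint and the inserted sequence
#' length; null transitions carry penalty 0. Two surcharges keep the model
#' parsimonious: insertion content alignable to the reference costs
#' `unaligned_rate` per alignable base (re-using an alignment is then always
#' cheaper than deleting and reinserting it, while a template switch, which
#' names its donor, pays no such surcharge), and a deletion/duplication whose
#' span exceeds `switch_dist` pays `jump_open` (a reference jump that far is
#' better explained as a template switch).
#'
#' @param candidate a candidate variant (internal list).
#' @param params [sv_params()] configuration.
#' @return non-negative penalty.
#' @export
score_variant <- function(candidate, params = sv_params()) {
  cls <- candidate$vclass
  open_cls <- if (cls == "INVDUP") "DUP" else cls
  span <- max(candidate$rend - candidate$rstart, nchar(candidate$alt_seq))
  pen <- unname(params$open[[open_cls]] + params$size_coef * log2(1 + span))
  if (cls == "INS" && !is.null(candidate$align_frac)) {
    pen <- pen + params$unaligned_rate * candidate$align_frac *
      nchar(candidate$alt_seq)
  }
  if (cls %in% c("DEL", "DUP") &&
      candidate$rend - candidate$rstart > params$switch_dist) {
    pen <- pen + params$jump_open
  }
  pen
}

# Probe-scan an unaligned query gap against the full reference (repeats
# allowed, both strands). Probes are exact k-mers sampled along the gap and
# located by hashing the reference k-mer vector against them. Returns the
# overall alignable probe fraction plus the best-supported distal donor
# (NULL when none exists).
scan_gap <- function(gapseq, ref_kmers, junction_lo, junction_hi, params) {
  k <- params$k
  glen <- nchar(gapseq)
  if (glen < k) return(list(donor = NULL, align_frac = 0))
  stride <- max(k, ceiling(glen / 40))
  starts <- seq(0L, glen - k, by = stride)
  probes <- substring(gapseq, starts + 1L, starts + k)
  keep <- !grepl("N", probes, fixed = TRUE)
  probes <- probes[keep]; starts <- starts[keep]
  n_probe <- length(probes)
  if (!n_probe) return(list(donor = NULL, align_frac = 0))
  mf <- match(ref_kmers, probes)
  mr <- match(ref_kmers, revcomp(probes))
  hf <- which(!is.na(mf)); hr <- which(!is.na(mr))
  h <- rbind(
    if (length(hf)) data.frame(q = starts[mf[hf]], r = hf - 1L,
                               strand = "+", stringsAsFactors = FALSE),
    if (length(hr)) data.frame(q = starts[mr[hr]], r = hr - 1L,
                               strand = "-", stringsAsFactors = FALSE))
  probe_hit <- unique(c(mf[hf], mr[hr]))
  align_frac <- length(probe_hit) / n_probe
  if (is.null(h) || !nrow(h)) {
    return(list(donor = NULL, align_frac = align_frac))
  }
  h$diag <- ifelse(h$strand == "+", h$r - h$q, h$r + h$q)
  h$cluster <- paste(h$strand, round(h$diag / 200))
  support <- table(h$cluster)
  best <- max(support)
  ok <- names(support)[support >= max(2L, best * 0.5)]
  cands <- lapply(ok, function(cl) {
    hh <- h[h$cluster == cl, , drop = FALSE]
    d0 <- min(hh$r); d1 <- max(hh$r) + k
    dist <- max(0L, junction_lo - d1, d0 - junction_hi)
    list(donor_start = d0, donor_end = d1, donor_strand = hh$strand[1L],
         support = nrow(hh), dist = dist)
  })
  distal <- Filter(function(x) x$dist > params$switch_dist &&
                     x$support >= params$ts_min_support * n_probe, cands)
  donor <- if (length(distal)) {
    sup <- vapply(distal, `[[`, numeric(1), "support")
    st <- vapply(distal, `[[`, numeric(1), "donor_start")
    distal[[order(-sup, st)[1L]]]
  } else NULL
  list(donor = donor, align_frac = align_frac)
}

#' Enumerate candidate variants between alignment records
#'
#' For each ordered record pair within `max_join` query distance, emits
#' deletion/insertion candidates from reference/query gap imbalance,
#' inversion candidates on strand change, duplication candidates on
#' reference back-steps, inverted duplications on strand change with
#' reference overlap, and template switches when the unaligned query gap
#' seeds to a distal donor (farther than `switch_dist`, or another
#' reference sequence). Each element of the returned list is one possible
#' graph edge: `list(from, to, variants, penalty)`; alternative structural
#' explanations of the same junction yield parallel edges.
#'
#' @param records trimmed alignment records of one query, sorted by `qstart`.
#' @param ref,hap the aligned sequences.
#' @param params [sv_params()] configuration.
#' @return list of candidate edges (possibly empty variant lists are null
#'   transitions between adjacent compatible records).
#' @export
enumerate_candidates <- function(records, ref, hap, params = sv_params()) {
  n <- nrow(records)
  edges <- list()
  if (n < 1L) return(edges)
  rseq <- as_seq(ref); qseq <- as_seq(hap)
  ref_kmers <- kmer_set(rseq, params$k)
  min_sv <- params$min_sv
  add_edge <- function(i, j, variants) {
    pen <- if (length(variants)) {
      sum(vapply(variants, score_variant, numeric(1), params = params))
    } else 0
    edges[[length(edges) + 1L]] <<- list(from = i, to = j,
                                         variants = variants, penalty = pen)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      qgap <- records$qstart[j] - records$qend[i]
      if (qgap < 0L || qgap > params$max_join) next
      si <- records$strand[i]; sj <- records$strand[j]
      both_minus <- si == "-" && sj == "-"
      rgap <- if (both_minus) records$rstart[i] - records$rend[j]
              else records$rstart[j] - records$rend[i]
      gapseq <- subseq0(qseq, records$qend[i], records$qstart[j])
      # junction interval on the reference, for donor distal checks
      jlo <- min(records$rend[i], records$rstart[j])
      jhi <- max(records$rend[i], records$rstart[j])
      del_iv <- if (both_minus) c(records$rend[j], records$rstart[i])
                else c(records$rend[i], records$rstart[j])
      dup_iv <- rev(del_iv)
      ins_pos <- del_iv[2L]

      variants <- list()
      scan <- if (qgap >= min_sv) {
        scan_gap(gapseq, ref_kmers, jlo, jhi, params)
      } else list(donor = NULL, align_frac = 0)
      if (si == sj) {
        if (rgap >= min_sv) {
          variants[[length(variants) + 1L]] <-
            new_candidate("DEL", del_iv[1L], del_iv[2L])
        } else if (rgap <= -min_sv) {
          variants[[length(variants) + 1L]] <-
            new_candidate("DUP", dup_iv[1L], dup_iv[2L])
        }
        if (qgap >= min_sv) {
          variants[[length(variants) + 1L]] <-
            new_candidate("INS", ins_pos, ins_pos, alt_seq = gapseq,
                          align_frac = scan$align_frac)
        }
      } else if (si == "+" && sj == "-") {
        # entering an inverted record
        overlap <- records$rend[i] - records$rstart[j]
        if (overlap >= min_sv) {
          variants[[length(variants) + 1L]] <- new_candidate(
            "INVDUP", records$rstart[j],
            min(records$rend[i], records$rend[j]))
        } else {
          if (rgap >= min_sv) {
            variants[[length(variants) + 1L]] <-
              new_candidate("DEL", records$rend[i], records$rstart[j])
          }
          variants[[length(variants) + 1L]] <-
            new_candidate("INV", records$rstart[j], records$rend[j])
        }
        if (qgap >= min_sv) {
          variants[[length(variants) + 1L]] <-
            new_candidate("INS", records$rstart[j], records$rstart[j],
                          alt_seq = gapseq, align_frac = scan$align_frac)
        }
      } else {
        # leaving an inverted record (or entering one from a minus flank):
        # the inversion itself is carried by the entering edge
        if (rgap >= min_sv) {
          variants[[length(variants) + 1L]] <-
            new_candidate("DEL", records$rend[i], records$rstart[j])
        } else if (rgap <= -min_sv) {
          variants[[length(variants) + 1L]] <-
            new_candidate("DUP", records$rstart[j], records$rend[i])
        }
        if (qgap >= min_sv) {
          variants[[length(variants) + 1L]] <-
            new_candidate("INS", records$rstart[j], records$rstart[j],
                          alt_seq = gapseq, align_frac = scan$align_frac)
        }
      }
      add_edge(i, j, variants)
      # parallel edge: the unaligned gap explained as a template switch from
      # a distal donor (replacing the INS, folding in any co-located DEL)
      if (!is.null(scan$donor)) {
        ins_at <- which(vapply(variants, `[[`, character(1), "vclass") ==
                          "INS")
        if (length(ins_at)) {
          del_at <- which(vapply(variants, `[[`, character(1), "vclass") ==
                            "DEL")
          target <- if (length(del_at)) {
            v <- variants[[del_at[1L]]]
            c(v$rstart, v$rend)
          } else {
            v <- variants[[ins_at[1L]]]
            c(v$rstart, v$rend)
          }
          ts <- new_candidate(
            "TEMPLATE_SWITCH", target[1L], target[2L], alt_seq = gapseq,
            donor_start = scan$donor$donor_start,
            donor_end = scan$donor$donor_end,
            donor_strand = scan$donor$donor_strand)
          ts_vars <- variants[-c(ins_at[1L], del_at)]
          ts_vars[[length(ts_vars) + 1L]] <- ts
          add_edge(i, j, ts_vars)
        }
      }
    }
  }
  edges
}
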