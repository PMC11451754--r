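# Rearrangement plans: ordered edit operations applied to a reference to
# produce a haplotype with machine-readable truth.

OP_KINDS <- c("DEL", "INS", "INV", "TANDEM_DUP", "INV_DUP", "DISTAL_SWITCH")

#' Construct a rearrangement operation
#'
#' @param kind one of `DEL`, `INS`, `INV`, `TANDEM_DUP`, `INV_DUP`,
#'   `DISTAL_SWITCH`.
#' @param start,end 0-based half-open target interval on the reference
#'   (`start == end` for insertions).
#' @param donor_start,donor_end donor interval (required for
#'   `DISTAL_SWITCH` only).
#' @param donor_strand `"+"` or `"-"` orientation of the donor copy.
#' @param copies number of tandem copies (duplications; at least 2).
#' @param payload_seed RNG seed for the inserted sequence (`INS`).
#' @param payload_len length of the inserted sequence (`INS`).
#' @return a list of class `rearrangement_op`.
#' @export
rearrangement_op <- function(kind, start, end,
                             donor_start = NA_integer_,
                             donor_end = NA_integer_,
                             donor_strand = "+",
                             copies = 2L,
                             payload_seed = 1L,
                             payload_len = 0L) {
  kind <- match.arg(kind, OP_KINDS)
  stopifnot(start >= 0, end >= start)
  if (kind == "INS") {
    if (end != start) stop("INS target must be zero-length")
    if (payload_len <= 0) stop("INS requires payload_len > 0")
  } else if (end == start) {
    stop(kind, " target must be nonempty")
  }
  if (kind %in% c("TANDEM_DUP", "INV_DUP") && copies < 2L) {
    stop("duplications require copies >= 2")
  }
  if (kind == "DISTAL_SWITCH") {
    if (is.na(donor_start) || is.na(donor_end) || donor_end <= donor_start) {
      stop("DISTAL_SWITCH requires a nonempty donor interval")
    }
    stopifnot(donor_strand %in% c("+", "-"))
  } else if (!is.na(donor_start)) {
    stop("donor interval is only valid for DISTAL_SWITCH")
  }
  structure(list(kind = kind, start = as.integer(start),
                 end = as.integer(end),
                 donor_start = as.integer(donor_start),
                 donor_end = as.integer(donor_end),
                 donor_strand = donor_strand,
                 copies = as.integer(copies),
                 payload_seed = as.integer(payload_seed),
                 payload_len = as.integer(payload_len)),
            class = "rearrangement_op")
}

op_delta <- function(op) {
  len <- op$end - op$start
  switch(op$kind,
    DEL = -len,
    INS = op$payload_len,
    INV = 0L,
    TANDEM_DUP = (op$copies - 1L) * len,
    INV_DUP = len,
    DISTAL_SWITCH = (op$donor_end - op$donor_start) - len)
}

ops_table <- function(plan) {
  do.call(rbind, lapply(plan, function(op) {
    data.frame(kind = op$kind, start = op$start, end = op$end,
               donor_start = op$donor_start, donor_end = op$donor_end,
               donor_strand = op$donor_strand, copies = op$copies,
               payload_seed = op$payload_seed, payload_len = op$payload_len,
               delta = op_delta(op), stringsAsFactors = FALSE)
  }))
}

#' Apply a rearrangement plan to a reference
#'
#' Operations are sorted by reference start and applied right to left so that
#' reference-native coordinates stay valid throughout. Donor sequence for
#' template switches is always taken from the unmodified reference. Truth
#' records are emitted per event cluster: operations whose reference
#' footprints lie within `merge_adjacent` bp collapse into a single expected
#' composite signature, mirroring the classifier's convention.
#'
#' @param ref a `genome_sequence` (or plain string) reference.
#' @param plan list of [rearrangement_op()] objects; targets (and donors) must
#'   be pairwise disjoint on the reference.
#' @param sample,hap sample id and haplotype index recorded in the truth.
#' @param merge_adjacent clustering window in bp for composite truth records.
#' @param min_sv minimum SV size used by the signature grammar.
#' @return list with `hap` (a `genome_sequence` named `SAMPLE#HAP#CONTIG`),
#'   `truth` (data frame: one row per event cluster with expected signature,
#'   signed length delta, breakpoints, and complexity flag) and `ops` (the
#'   plan as a data frame).
#' @export
apply_plan <- function(ref, plan, sample = "S1", hap = 1L,
                       merge_adjacent = 1000L, min_sv = 50L) {
  seq <- as_seq(ref)
  L <- nchar(seq)
  if (length(plan)) {
    stopifnot(all(vapply(plan, inherits, logical(1), "rearrangement_op")))
    tab <- ops_table(plan)
    if (any(tab$end > L)) stop("op target outside reference bounds")
    if (any(!is.na(tab$donor_end) & tab$donor_end > L)) {
      stop("donor interval outside reference bounds")
    }
    o <- order(tab$start, tab$end)
    plan <- plan[o]; tab <- tab[o, , drop = FALSE]
    # reject overlapping footprints (targets and donors): ambiguous truth
    fs <- c(tab$start, tab$donor_start[!is.na(tab$donor_start)])
    fe <- c(pmax(tab$end, tab$start + 1L),
            tab$donor_end[!is.na(tab$donor_start)])
    oo <- order(fs, fe)
    if (any(fs[oo][-1L] < fe[oo][-length(fe)])) {
      stop("rearrangement ops overlap on the reference")
    }
  } else {
    tab <- ops_table(list())
  }

  hap_seq <- seq
  for (op in rev(plan)) {
    left <- subseq0(hap_seq, 0L, op$start)
    right <- subseq0(hap_seq, op$end, nchar(hap_seq))
    target <- subseq0(seq, op$start, op$end)
    mid <- switch(op$kind,
      DEL = "",
      INS = with_seed(op$payload_seed, random_dna(op$payload_len)),
      INV = revcomp(target),
      TANDEM_DUP = strrep(target, op$copies),
      INV_DUP = paste0(target, revcomp(target)),
      DISTAL_SWITCH = {
        donor <- subseq0(seq, op$donor_start, op$donor_end)
        if (op$donor_strand == "-") revcomp(donor) else donor
      })
    hap_seq <- paste0(left, mid, right)
  }

  truth <- truth_from_plan(plan, chrom = seq_name(ref), sample = sample,
                           hap = hap, merge_adjacent = merge_adjacent,
                           min_sv = min_sv)
  delta <- if (length(plan)) sum(vapply(plan, op_delta, integer(1))) else 0L
  stopifnot(nchar(hap_seq) == L + delta)
  hname <- sprintf("%s#%d#%s", sample, hap, seq_name(ref))
  list(hap = genome_sequence(hname, hap_seq), truth = truth, ops = tab)
}

truth_from_plan <- function(plan, chrom, sample, hap,
                            merge_adjacent = 1000L, min_sv = 50L) {
  empty <- data.frame(sample = character(0), hap = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), signature = character(0),
                      svlen = integer(0), n_breakpoints = integer(0),
                      complex = logical(0), n_ops = integer(0))
  if (!length(plan)) return(empty)
  starts <- vapply(plan, `[[`, integer(1), "start")
  ends <- pmax(vapply(plan, `[[`, integer(1), "end"), starts)
  cl <- cluster_events(starts, ends, merge_adjacent)
  rows <- lapply(sort(unique(cl)), function(ci) {
    ops <- plan[cl == ci]
    ord <- order(vapply(ops, `[[`, integer(1), "start"))
    ops <- ops[ord]
    toks <- unlist(lapply(ops, function(op) {
      event_tokens(op$kind, ref_len = op$end - op$start,
                   copies = op$copies, min_sv = min_sv)
    }))
    bp <- count_breakpoints(lapply(ops, function(op) {
      event_breakpoints(op$kind, op$start, op$end, copies = op$copies,
                        donor_start = op$donor_start,
                        donor_end = op$donor_end)
    }))
    data.frame(sample = sample, hap = hap, chrom = chrom,
               start = min(starts[cl == ci]), end = max(ends[cl == ci]),
               signature = signature_string(toks),
               svlen = sum(vapply(ops, op_delta, integer(1))),
               n_breakpoints = bp$n,
               complex = bp$n > 2L,
               n_ops = length(ops), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "breakpoints") <- lapply(sort(unique(cl)), function(ci) {
    sort(unlist(lapply(plan[cl == ci], function(op) {
      event_breakpoints(op$kind, op$start, op$end, copies = op$copies,
                        donor_start = op$donor_start,
                        donor_end = op$donor_end)
    })))
  })
  out
}

#' Default configuration for random rearrangement plans
#'
#' @param weights named non-negative event-class weights.
#' @param n_ops number of operations per plan.
#' @param size_range bp size range for DEL/INV/DUP/INVDUP/switch targets.
#' @param ins_range bp size range for insertion payloads.
#' @param copies_range tandem copy-number range for duplications.
#' @param spacing minimum bp between operation footprints (default 500 so
#'   anchors exist between events; set 0 for stress tests).
#' @param donor_min_dist minimum distance between a template-switch target and
#'   its donor, making the donor distal.
#' @param margin bp kept free of events at both reference ends.
#' @return a list used by [random_plan()].
#' @export
plan_config <- function(weights = c(DEL = 1, INS = 1, INV = 1,
                                    TANDEM_DUP = 1, INV_DUP = 1,
                                    DISTAL_SWITCH = 1),
                        n_ops = 5L,
                        size_range = c(200L, 5000L),
                        ins_range = c(100L, 1000L),
                        copies_range = c(2L, 4L),
                        spacing = 500L,
                        donor_min_dist = 60000L,
                        margin = 2000L) {
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative and not all zero")
  }
  if (!all(names(weights) %in% OP_KINDS)) stop("unknown event class in weights")
  list(weights = weights, n_ops = as.integer(n_ops),
       size_range = as.integer(size_range), ins_range = as.integer(ins_range),
       copies_range = as.integer(copies_range), spacing = as.integer(spacing),
       donor_min_dist = as.integer(donor_min_dist),
       margin = as.integer(margin))
}

#' Draw a random rearrangement plan
#'
#' Event classes are drawn from the configured weights and placed uniformly at
#' random subject to the minimum spacing between footprints (donors included).
#' Deterministic per seed.
#'
#' @param seed integer RNG seed.
#' @param ref_len reference length the plan must fit into.
#' @param config a [plan_config()] list.
#' @return list of [rearrangement_op()] sorted by reference start.
#' @export
random_plan <- function(seed, ref_len, config = plan_config()) {
  cfg <- config
  if (cfg$size_range[2] + 2L * cfg$spacing + 2L * cfg$margin > ref_len) {
    stop("size range infeasible for reference length ", ref_len)
  }
  with_seed(seed, {
    kinds <- sample(names(cfg$weights), cfg$n_ops, replace = TRUE,
                    prob = cfg$weights)
    occupied <- data.frame(start = integer(0), end = integer(0))
    place <- function(len, distal_from = NULL) {
      for (try in seq_len(500L)) {
        s <- sample.int(ref_len - len - 2L * cfg$margin, 1L) + cfg$margin
        e <- s + len
        pad_s <- s - cfg$spacing; pad_e <- e + cfg$spacing
        clash <- nrow(occupied) &&
          any(pmax(occupied$start, pad_s) < pmin(occupied$end, pad_e))
        if (clash) next
        if (!is.null(distal_from) &&
            min(abs(c(s, e) - distal_from)) < cfg$donor_min_dist) next
        occupied <<- rbind(occupied, data.frame(start = s, end = e))
        return(c(s, e))
      }
      stop("could not place event of ", len,
           " bp: reference too small for config")
    }
    plan <- lapply(kinds, function(kind) {
      if (kind == "INS") {
        len <- sample(cfg$ins_range[1]:cfg$ins_range[2], 1L)
        iv <- place(1L)  # reserve a point with spacing
        rearrangement_op("INS", iv[1], iv[1],
                         payload_seed = sample.int(1e6, 1L),
                         payload_len = len)
      } else if (kind == "DISTAL_SWITCH") {
        len <- sample(cfg$size_range[1]:cfg$size_range[2], 1L)
        iv <- place(len)
        dlen <- sample(cfg$size_range[1]:cfg$size_range[2], 1L)
        dv <- place(dlen, distal_from = mean(iv))
        rearrangement_op("DISTAL_SWITCH", iv[1], iv[2],
                         donor_start = dv[1], donor_end = dv[2],
                         donor_strand = sample(c("+", "-"), 1L))
      } else {
        len <- sample(cfg$size_range[1]:cfg$size_range[2], 1L)
        iv <- place(len)
        copies <- if (kind == "TANDEM_DUP") {
          sample(cfg$copies_range[1]:cfg$copies_range[2], 1L)
        } else 2L
        rearrangement_op(kind, iv[1], iv[2], copies = copies)
      }
    })
    plan[order(vapply(plan, `[[`, integer(1), "start"))]
  })
}
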