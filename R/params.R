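#' Pipeline parameters
#'
#' Tunable parameters for anchoring, record extraction, trimming, candidate
#' enumeration, scoring, and classification. Defaults follow the package's
#' documented conventions; see the methods vignette for rationale.
#'
#' @param k odd anchor k-mer size (bp).
#' @param max_gap maximum anchor diagonal shift within one chain (bp).
#' @param min_anchors minimum anchors per chain.
#' @param band maximum inter-anchor gap closed by global alignment inside one
#'   record (bp); larger gaps terminate the record.
#' @param split_indel internal CIGAR indel runs at least this long (bp) split
#'   a record so the event surfaces as an inter-record candidate.
#' @param min_keep records trimmed below this query length (bp) are dropped.
#' @param min_sv minimum SV size (bp) for candidate emission.
#' @param max_join maximum query distance between records joined by an edge.
#' @param switch_dist minimum donor distance (bp) for a template switch; a
#'   donor on another reference sequence is always distal.
#' @param merge_adjacent reference adjacency window (bp) collapsing accepted
#'   calls into one composite variant.
#' @param open named per-class penalty opening costs.
#' @param size_coef coefficient of the `log2(1 + span)` size term.
#' @param unaligned_rate per-base surcharge for insertion content that is
#'   alignable to the reference (scaled by the alignable fraction), and for
#'   query bases clipped at SOURCE/SINK; makes re-aligning a segment always
#'   cheaper than deleting-and-reinserting it.
#' @param jump_open extra opening cost for deletion/duplication candidates
#'   spanning more than `switch_dist` (a reference jump better explained by
#'   a template switch).
#' @param ts_min_support minimum fraction of gap probes a distal donor must
#'   explain before a template switch is proposed.
#' @param mimic_window junction window (bp) inspected by [flag_mimics()].
#' @param mimic_cov forward k-mer coverage above which a junction counts as
#'   paralogous in [flag_mimics()].
#' @return a list of class `sv_params`.
#' @export
sv_params <- function(k = 31L,
                      max_gap = 10000L,
                      min_anchors = 2L,
                      band = 2000L,
                      split_indel = 50L,
                      min_keep = 200L,
                      min_sv = 50L,
                      max_join = 1000000L,
                      switch_dist = 50000L,
                      merge_adjacent = 1000L,
                      open = c(INS = 2, DEL = 2, INV = 3, DUP = 3,
                               TEMPLATE_SWITCH = 4),
                      size_coef = 0.5,
                      unaligned_rate = 0.02,
                      jump_open = 8,
                      ts_min_support = 0.8,
                      mimic_window = 1000L,
                      mimic_cov = 0.3) {
  if (k %% 2L == 0L) stop("k must be odd")
  if (any(open < 0) || size_coef < 0) stop("penalties must be non-negative")
  need <- c("INS", "DEL", "INV", "DUP", "TEMPLATE_SWITCH")
  if (!all(need %in% names(open))) {
    stop("open penalties required for: ", paste(need, collapse = ", "))
  }
  structure(list(k = as.integer(k), max_gap = as.integer(max_gap),
                 min_anchors = as.integer(min_anchors),
                 band = as.integer(band),
                 split_indel = as.integer(split_indel),
                 min_keep = as.integer(min_keep),
                 min_sv = as.integer(min_sv),
                 max_join = as.integer(max_join),
                 switch_dist = as.integer(switch_dist),
                 merge_adjacent = as.integer(merge_adjacent),
                 open = open, size_coef = size_coef,
                 unaligned_rate = unaligned_rate, jump_open = jump_open,
                 ts_min_support = ts_min_support,
                 mimic_window = as.integer(mimic_window),
                 mimic_cov = mimic_cov),
            class = "sv_params")
}
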