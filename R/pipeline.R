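# End-to-end drivers: haplotype -> alignment records -> variant graph ->
# resolved calls.

#' Align a haplotype against a reference
#'
#' Anchor seeding on reference-unique k-mers, colinear chaining, record
#' extraction with banded gap closing, splitting at SV-scale internal
#' indels, and query-overlap trimming.
#'
#' @param ref,hap `genome_sequence` objects or plain strings.
#' @param params [sv_params()] configuration.
#' @return trimmed alignment record data frame sorted by `qstart`.
#' @export
align_assembly <- function(ref, hap, params = sv_params()) {
  anchors <- index_and_anchor(ref, hap, k = params$k)
  chains <- chain_anchors(anchors, max_gap = params$max_gap,
                          min_anchors = params$min_anchors)
  recs <- extract_records(chains, ref, hap, k = params$k, band = params$band)
  if (nrow(recs)) recs <- split_records(recs, min_indel = params$split_indel)
  if (nrow(recs)) recs <- trim_overlaps(recs, min_keep = params$min_keep)
  recs
}

#' Resolve structural variants of one haplotype
#'
#' Runs the full resolution pipeline: alignment (or externally supplied
#' records), candidate enumeration, variant graph construction, optimal-path
#' solving, and classification.
#'
#' @param ref,hap the sequences.
#' @param records optional pre-computed (e.g. PAF-imported) trimmed records;
#'   aligned internally when `NULL`.
#' @param params [sv_params()] configuration.
#' @param sample,hap_id identifiers stamped on calls.
#' @return list with `calls`, `records`, `graph`, `path`.
#' @export
resolve_haplotype <- function(ref, hap, records = NULL,
                              params = sv_params(),
                              sample = "S1", hap_id = 1L) {
  if (is.null(records)) records <- align_assembly(ref, hap, params)
  if (!nrow(records)) {
    return(list(calls = empty_calls(), records = records,
                graph = NULL, path = NULL))
  }
  validate_records(records)
  cands <- enumerate_candidates(records, ref, hap, params)
  graph <- build_dag(records, cands, params)
  path <- solve_optimal_path(graph)
  calls <- accept_and_classify(path, graph, records, ref, hap, params,
                               sample = sample, hap_id = hap_id)
  list(calls = calls, records = records, graph = graph, path = path)
}

#' Resolve a whole simulated cohort
#'
#' @param ref reference `genome_sequence`.
#' @param haplotypes named list of haplotype `genome_sequence`s
#'   (`SAMPLE#HAP` names, as produced by [simulate_cohort()]).
#' @param params [sv_params()] configuration.
#' @return single data frame of calls across all haplotypes.
#' @export
resolve_cohort <- function(ref, haplotypes, params = sv_params()) {
  out <- lapply(names(haplotypes), function(nm) {
    parts <- strsplit(nm, "#", fixed = TRUE)[[1]]
    res <- resolve_haplotype(ref, haplotypes[[nm]], params = params,
                             sample = parts[1], hap_id = as.integer(parts[2]))
    res$calls
  })
  do.call(rbind, out)
}
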