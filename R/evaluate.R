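# Benchmarking the resolver against simulator truth: signature recovery,
# exact breakpoint recovery for simple events, and haplotype round trips.

#' Match resolved calls against a truth table
#'
#' A truth cluster is signature-recovered when a call with the same
#' signature starts within `tol` bp. Simple deletions, insertions and
#' inversions are additionally checked for exact breakpoints after canonical
#' normalization ([normalize_del()], [normalize_ins()], [normalize_inv()]),
#' since junction homology makes equivalent placements interchangeable.
#'
#' @param calls resolved calls for one haplotype.
#' @param truth truth table from [apply_plan()].
#' @param ref the reference sequence.
#' @param ops the plan's ops table (from [apply_plan()]); needed to
#'   regenerate insertion payloads for exactness checks.
#' @param tol position tolerance in bp for signature matching.
#' @return `truth` with logical columns `sig_recovered` and `bp_exact`
#'   (`NA` for clusters where exactness is not assessed).
#' @export
match_truth <- function(calls, truth, ref, ops = NULL, tol = 2000L) {
  truth$sig_recovered <- FALSE
  truth$bp_exact <- NA
  for (i in seq_len(nrow(truth))) {
    cand <- which(calls$signature == truth$signature[i] &
                    abs(calls$pos - truth$start[i]) <= tol)
    cand <- cand[order(abs(calls$pos[cand] - truth$start[i]))]
    truth$sig_recovered[i] <- length(cand) > 0L
    if (truth$n_ops[i] == 1L &&
        truth$signature[i] %in% c("DEL", "INS", "INV")) {
      truth$bp_exact[i] <- length(cand) > 0L &&
        breakpoints_equal(calls[cand[1L], ], truth[i, ], ref, ops)
    }
  }
  truth
}

breakpoints_equal <- function(call, tr, ref, ops = NULL) {
  sig <- tr$signature
  if (sig == "DEL") {
    all(normalize_del(ref, call$pos, call$end) ==
          normalize_del(ref, tr$start, tr$end))
  } else if (sig == "INV") {
    all(normalize_inv(ref, call$pos, call$end) ==
          normalize_inv(ref, tr$start, tr$end))
  } else {
    segs <- call$segments[[1L]]
    alt <- paste(segs$seq[!is.na(segs$seq)], collapse = "")
    if (!nzchar(alt)) return(FALSE)
    ncall <- normalize_ins(ref, call$pos, alt)
    if (is.null(ops)) return(ncall$pos == tr$start)
    op <- ops[ops$kind == "INS" & ops$start == tr$start, , drop = FALSE]
    if (!nrow(op)) return(FALSE)
    payload <- with_seed(op$payload_seed[1L],
                         random_dna(op$payload_len[1L]))
    ntruth <- normalize_ins(ref, tr$start, payload)
    ncall$pos == ntruth$pos && ncall$alt == ntruth$alt
  }
}

#' Run the simulator/resolver recovery benchmark
#'
#' Draws `n_plans` seeded rearrangement plans, applies each to a fresh
#' simulated reference, resolves the haplotype, and scores signature
#' recovery, exact simple breakpoints, and byte-identical haplotype
#' reconstruction.
#'
#' @param n_plans number of plans.
#' @param seed base RNG seed; plan `i` uses `seed + i` offsets.
#' @param ref_len reference length per plan.
#' @param config [plan_config()] for the plans.
#' @param params [sv_params()] for the resolver.
#' @return list with `truth` (scored truth rows across plans), `summary`
#'   (recovery percentages), and `roundtrip` (logical per plan).
#' @export
evaluate_recovery <- function(n_plans, seed, ref_len = 150000L,
                              config = plan_config(),
                              params = sv_params()) {
  truth_all <- list()
  roundtrip <- logical(n_plans)
  for (i in seq_len(n_plans)) {
    ref <- make_reference(seed + 2L * i, ref_len)
    # a draw can be infeasible (no room for an event under the spacing and
    # donor-distance constraints); redraw deterministically
    plan <- NULL
    for (attempt in 0:9) {
      plan <- tryCatch(
        random_plan(seed + 2L * i + 1L + attempt * 97L, ref_len, config),
        error = function(e) NULL)
      if (!is.null(plan)) break
    }
    if (is.null(plan)) stop("no feasible plan for index ", i)
    sim <- apply_plan(ref, plan)
    res <- resolve_haplotype(ref, sim$hap, params = params)
    roundtrip[i] <- identical(reconstruct_haplotype(ref, res$calls)$seq,
                              sim$hap$seq)
    tr <- match_truth(res$calls, sim$truth, ref, ops = sim$ops)
    tr$plan <- i
    truth_all[[i]] <- tr
  }
  truth <- do.call(rbind, truth_all)
  cx <- truth[truth$complex, , drop = FALSE]
  simple <- truth[!is.na(truth$bp_exact), , drop = FALSE]
  list(truth = truth,
       roundtrip = roundtrip,
       summary = list(
         n_clusters = nrow(truth),
         n_complex = nrow(cx),
         sig_recovery_all_pct = 100 * mean(truth$sig_recovered),
         sig_recovery_complex_pct =
           if (nrow(cx)) 100 * mean(cx$sig_recovered) else NA_real_,
         simple_bp_exact_pct =
           if (nrow(simple)) 100 * mean(simple$bp_exact) else NA_real_,
         roundtrip_pct = 100 * mean(roundtrip)))
}
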