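# Classification of accepted variants into simple calls and composite
# signatures, mimic flagging, and haplotype reconstruction.

test_that("each event class resolves to its signature and reconstructs", {
  ref <- make_reference(1, 60000)
  p <- sv_params(switch_dist = 20000)
  cases <- list(
    list(plan = list(rearrangement_op("DEL", 20000, 21000)),
         sig = "DEL", complex = FALSE),
    list(plan = list(rearrangement_op("INS", 20000, 20000,
                                      payload_seed = 7, payload_len = 400)),
         sig = "INS", complex = FALSE),
    list(plan = list(rearrangement_op("INV", 20000, 23000)),
         sig = "INV", complex = FALSE),
    list(plan = list(rearrangement_op("TANDEM_DUP", 20000, 21500)),
         sig = "DUP", complex = FALSE),
    list(plan = list(rearrangement_op("TANDEM_DUP", 20000, 21500,
                                      copies = 3)),
         sig = "DUP3", complex = TRUE),
    list(plan = list(rearrangement_op("INV_DUP", 20000, 21500)),
         sig = "INVDUP", complex = TRUE),
    list(plan = list(rearrangement_op("DISTAL_SWITCH", 20000, 22000,
                                      donor_start = 50000,
                                      donor_end = 52500,
                                      donor_strand = "-")),
         sig = "DEL-INS", complex = TRUE),
    list(plan = list(rearrangement_op("DEL", 20000, 21000),
                     rearrangement_op("INV", 21000, 24000),
                     rearrangement_op("DEL", 24000, 25500)),
         sig = "DEL-INV-DEL", complex = TRUE))
  for (case in cases) {
    out <- resolve_plan(ref, case$plan, p)
    calls <- out$res$calls
    expect_equal(nrow(calls), 1, info = case$sig)
    expect_equal(calls$signature, case$sig)
    expect_equal(calls$complex, case$complex, info = case$sig)
    if (case$complex) expect_gt(calls$n_breakpoints, 2)
    else expect_lte(calls$n_breakpoints, 2)
    expect_identical(reconstruct_haplotype(ref, calls)$seq,
                     out$sim$hap$seq, info = case$sig)
  }
})

test_that("empty call sets reconstruct the reference", {
  ref <- make_reference(3, 15000)
  expect_identical(reconstruct_haplotype(ref, complexsv:::empty_calls())$seq,
                   ref$seq)
})

test_that("overlapping calls are rejected by reconstruction", {
  ref <- make_reference(1, 60000)
  out <- resolve_plan(ref, list(rearrangement_op("DEL", 20000, 21000)))
  bad <- rbind(out$res$calls, out$res$calls)
  bad$pos[2] <- bad$pos[2] + 10L
  expect_error(reconstruct_haplotype(ref, bad), "overlap")
})

test_that("SD-mediated composite loss mimics a simple deletion", {
  ref <- make_reference(42, 80000, sd_specs = list(
    sd_spec(20000, 23000, 40000, 43000, "inverted", 98)))
  plan <- list(rearrangement_op("DEL", 15000, 20000),
               rearrangement_op("INV", 20000, 43000),
               rearrangement_op("DEL", 43000, 47000))
  out <- resolve_plan(ref, plan, sv_params(switch_dist = 10000))
  calls <- out$res$calls
  expect_equal(calls$signature, "DEL-INV-DEL")
  expect_true(calls$complex)
  expect_true(calls$mimic)
  expect_identical(reconstruct_haplotype(ref, calls)$seq, out$sim$hap$seq)
})

test_that("simple and balanced calls are never mimics", {
  ref <- make_reference(1, 60000)
  del <- resolve_plan(ref, list(rearrangement_op("DEL", 20000, 21000)))
  expect_false(del$res$calls$mimic)
  # balanced composite: inversion flanked by two sub-SV deletions summing
  # near zero net change is not length-consistent with a simple deletion
  inv <- resolve_plan(ref, list(rearrangement_op("INV", 20000, 23000)))
  expect_false(inv$res$calls$mimic)
  # a composite without paralogous junctions (no SD context) stays unflagged
  plain <- resolve_plan(ref, list(
    rearrangement_op("DEL", 20000, 21000),
    rearrangement_op("INV", 21000, 24000),
    rearrangement_op("DEL", 24000, 25500)))
  expect_true(plain$res$calls$complex)
  expect_false(plain$res$calls$mimic)
})

test_that("template switches across a 100%-identity SD pair are proposed", {
  ref <- make_reference(43, 80000, sd_specs = list(
    sd_spec(20000, 22000, 40000, 42000, "inverted", 100)))
  sim <- apply_plan(ref, list(rearrangement_op("INV", 20000, 42000)))
  p <- sv_params(switch_dist = 10000)
  recs <- align_assembly(ref, sim$hap, p)
  cands <- enumerate_candidates(recs, ref, sim$hap, p)
  ts <- list()
  for (e in cands) {
    for (v in e$variants) {
      if (v$vclass == "TEMPLATE_SWITCH") ts[[length(ts) + 1L]] <- v
    }
  }
  expect_equal(length(ts), 2)
  # each switch names the opposite SD copy as its donor
  donors <- vapply(ts, `[[`, integer(1), "donor_start")
  expect_true(any(donors < 23000) && any(donors > 39000))
})
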