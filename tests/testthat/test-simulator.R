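# Rearrangement simulator: references with SD structure, plans, truth.

test_that("reference generation is deterministic and validates input", {
  r1 <- make_reference(5, 12000)
  r2 <- make_reference(5, 12000)
  expect_identical(r1$seq, r2$seq)
  expect_false(identical(make_reference(6, 12000)$seq, r1$seq))
  expect_error(make_reference(1, 5000), "length")
  expect_error(sd_spec(0, 500, 2000, 2500), "1 kbp")
  expect_error(sd_spec(0, 2000, 1000, 3000), "overlap")
  expect_error(sd_spec(0, 2000, 3000, 5000, identity_pct = 80), "identity")
})

test_that("SD copies match the requested identity (edit-distance oracle)", {
  spec <- sd_spec(2000, 4000, 8000, 10000, "direct", identity_pct = 100)
  ref <- make_reference(9, 15000, list(spec))
  a <- substr(ref$seq, 2001, 4000); b <- substr(ref$seq, 8001, 10000)
  expect_identical(a, b)

  spec95 <- sd_spec(2000, 4000, 8000, 10000, "direct", identity_pct = 95)
  ref95 <- make_reference(9, 15000, list(spec95))
  a <- substr(ref95$seq, 2001, 4000); b <- substr(ref95$seq, 8001, 10000)
  ident <- 1 - drop(adist(a, b)) / nchar(a)
  expect_gt(ident, 0.94)
  expect_lt(ident, 0.96)

  inv <- sd_spec(2000, 4000, 8000, 10000, "inverted", identity_pct = 100)
  refi <- make_reference(9, 15000, list(inv))
  expect_identical(substr(refi$seq, 8001, 10000),
                   revcomp(substr(refi$seq, 2001, 4000)))
})

test_that("plans apply with exact length bookkeeping and truth signatures", {
  ref <- make_reference(3, 40000)
  empty <- apply_plan(ref, list())
  expect_identical(empty$hap$seq, ref$seq)
  expect_equal(nrow(empty$truth), 0)

  del <- apply_plan(ref, list(rearrangement_op("DEL", 10000, 10100)))
  expect_equal(nchar(del$hap$seq), nchar(ref$seq) - 100)
  expect_equal(del$truth$signature, "DEL")
  expect_equal(del$truth$n_breakpoints, 2)
  expect_false(del$truth$complex)

  mixed <- apply_plan(ref, list(
    rearrangement_op("DEL", 10000, 10500),
    rearrangement_op("INV", 10500, 12000),
    rearrangement_op("DEL", 12000, 12800)))
  expect_equal(mixed$truth$signature, "DEL-INV-DEL")
  expect_true(mixed$truth$complex)
  expect_equal(mixed$truth$svlen, -1300)
  expect_equal(nchar(mixed$hap$seq), nchar(ref$seq) - 1300)

  expect_error(apply_plan(ref, list(
    rearrangement_op("DEL", 10000, 11000),
    rearrangement_op("INV", 10500, 12000))), "overlap")
})

test_that("distal switch donors re-extract from the haplotype", {
  ref <- make_reference(8, 60000)
  op <- rearrangement_op("DISTAL_SWITCH", 10000, 12000,
                         donor_start = 40000, donor_end = 42500,
                         donor_strand = "-")
  sim <- apply_plan(ref, list(op))
  implanted <- substr(sim$hap$seq, 10001, 12500)
  expect_identical(implanted, revcomp(substr(ref$seq, 40001, 42500)))
  expect_equal(sim$truth$signature, "DEL-INS")
  expect_true(sim$truth$complex)
})

test_that("random plans are deterministic and follow class weights", {
  cfg <- plan_config(n_ops = 4L)
  p1 <- random_plan(21, 150000, cfg)
  p2 <- random_plan(21, 150000, cfg)
  expect_identical(complexsv:::ops_table(p1), complexsv:::ops_table(p2))

  only_del <- random_plan(3, 150000, plan_config(
    weights = c(DEL = 1), n_ops = 6L))
  expect_true(all(vapply(only_del, `[[`, character(1), "kind") == "DEL"))

  # 1,000 draws with equal weights: each class within 3 sd of uniform
  cfg6 <- plan_config(n_ops = 5L)
  kinds <- unlist(lapply(1:200, function(s) {
    vapply(random_plan(s + 500, 150000, cfg6), `[[`, character(1), "kind")
  }))
  n <- length(kinds)
  p <- 1 / 6
  sd3 <- 3 * sqrt(n * p * (1 - p))
  counts <- table(factor(kinds, levels = names(cfg6$weights)))
  expect_true(all(abs(counts - n * p) <= sd3))

  expect_error(plan_config(weights = c(DEL = 0)), "not all zero")
  expect_error(random_plan(1, 8000, plan_config()), "infeasible")
})

test_that("haplotype length always equals reference plus summed deltas", {
  for (s in 1:5) {
    ref <- make_reference(s, 120000)
    plan <- random_plan(s + 50, 120000, plan_config())
    sim <- apply_plan(ref, plan)
    expect_equal(nchar(sim$hap$seq), nchar(ref$seq) + sum(sim$ops$delta))
    expect_equal(sim$truth$svlen, unname(tapply(
      sim$ops$delta,
      complexsv:::cluster_events(sim$ops$start,
                                 pmax(sim$ops$end, sim$ops$start), 1000L),
      sum)), ignore_attr = TRUE)
  }
})
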