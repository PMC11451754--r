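# Cohort simulation and end-to-end allele-frequency recovery.

test_that("carrier counts follow round(AF * 2n) exactly", {
  ref <- make_reference(12, 30000)
  spec <- list(
    list(plan = list(rearrangement_op("DEL", 10000, 10400)), af = 1.0),
    list(plan = list(rearrangement_op("DEL", 15000, 15600)), af = 0.5),
    list(plan = list(rearrangement_op("INS", 20000, 20000,
                                      payload_seed = 2, payload_len = 300)),
         af = 0.10))
  cohort <- simulate_cohort(ref, n_samples = 10, seed = 4, af_spec = spec)
  expect_equal(cohort$n_haplotypes, 20)
  expect_equal(cohort$carriers$realised_af, c(1.0, 0.5, 0.10))
  # AF 1.0: every haplotype carries the variant
  n_carriers <- vapply(strsplit(cohort$carriers$carriers, ","), length,
                       integer(1))
  expect_equal(n_carriers, c(20, 10, 2))
  # determinism
  cohort2 <- simulate_cohort(ref, n_samples = 10, seed = 4, af_spec = spec)
  expect_identical(cohort$truth, cohort2$truth)
  # an AF too small for one carrier is dropped with a warning
  expect_warning(
    simulate_cohort(ref, n_samples = 2, seed = 1,
                    af_spec = list(list(
                      plan = list(rearrangement_op("DEL", 9000, 9300)),
                      af = 0.05))),
    "dropped")
})

test_that("cohort FASTA and truth TSV round-trip from disk", {
  ref <- make_reference(12, 30000)
  dir <- withr::local_tempdir()
  spec <- list(list(plan = list(rearrangement_op("DEL", 10000, 10400)),
                    af = 0.5))
  cohort <- simulate_cohort(ref, n_samples = 3, seed = 9, af_spec = spec,
                            dir = dir)
  fas <- list.files(dir, pattern = "\\.fa$")
  expect_length(fas, 6)
  one <- read_fasta(file.path(dir, fas[1]))
  expect_match(names(one), "^S01#1#")
  truth <- read_truth(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), nrow(cohort$truth))
})

test_that("merged callset recovers the specified allele frequencies", {
  ref <- make_reference(18, 60000)
  spec <- list(
    list(plan = list(rearrangement_op("DEL", 15000, 15800)), af = 1.0),
    list(plan = list(rearrangement_op("INV", 30000, 32000)), af = 0.5),
    list(plan = list(rearrangement_op("INS", 45000, 45000,
                                      payload_seed = 8, payload_len = 400)),
         af = 0.25))
  cohort <- simulate_cohort(ref, n_samples = 4, seed = 11, af_spec = spec)
  calls <- resolve_cohort(ref, cohort$haplotypes)
  merged <- allele_frequency(merge_nonredundant(calls),
                             n_haplotypes = cohort$n_haplotypes)
  merged <- merged[order(merged$pos), ]
  expect_equal(nrow(merged), 3)
  expect_equal(merged$af, c(1.0, 0.5, 0.25))
  expect_equal(merged$svtype, c("DEL", "INV", "INS"))
})
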