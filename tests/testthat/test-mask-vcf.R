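# Region masking, cross-reference linking, VCF I/O.

test_that("mask filtering honours overlap modes and is idempotent", {
  calls <- random_callset(7, n_calls = 10)
  empty <- filter_mask(calls, region_mask(character(0), integer(0),
                                          integer(0)))
  expect_equal(nrow(empty), nrow(calls))

  target <- calls[1, ]
  mask_all <- region_mask("ref", target$pos - 10, target$end + 10)
  f1 <- filter_mask(calls, mask_all, "any-overlap")
  f2 <- filter_mask(calls, mask_all, "contained")
  expect_false(any(f1$pos == target$pos))
  expect_false(any(f2$pos == target$pos))

  # 1 bp overlap: removed under any-overlap, kept under contained
  mask_edge <- region_mask("ref", target$end - 1, target$end + 5000)
  expect_lt(nrow(filter_mask(calls, mask_edge, "any-overlap")), nrow(calls))
  expect_equal(nrow(filter_mask(calls, mask_edge, "contained")),
               nrow(calls))

  again <- filter_mask(f1, mask_all, "any-overlap")
  expect_equal(nrow(again), nrow(f1))
  expect_lte(nrow(f1), nrow(calls))
})

test_that("cross-reference linking matches variants through the assembly", {
  ref <- make_reference(1, 60000)
  sim <- apply_plan(ref, list(rearrangement_op("DEL", 20000, 21000)))
  # same haplotype against two "references": the original and a copy with a
  # shifted coordinate frame (5 kbp prepended)
  refB <- genome_sequence("refB", paste0(random_dna(5000), ref$seq))
  callsA <- resolve_haplotype(ref, sim$hap)$calls
  callsB <- resolve_haplotype(refB, sim$hap)$calls
  expect_equal(callsB$pos, callsA$pos + 5000)
  links <- link_across_references(callsA, callsB)
  expect_equal(nrow(links), 1)
  rev <- link_across_references(callsB, callsA)
  expect_equal(rev$idx_a, links$idx_b)
  expect_equal(rev$idx_b, links$idx_a)
  # a reference-specific call stays unlinked
  none <- link_across_references(callsA, callsB[0, ])
  expect_equal(nrow(none), 0)
})

test_that("VCF round-trips calls and validates with a strict parser", {
  ref <- make_reference(1, 60000)
  p <- sv_params(switch_dist = 20000)
  plan <- list(rearrangement_op("DEL", 20000, 21000),
               rearrangement_op("INS", 30000, 30000, payload_seed = 3,
                                payload_len = 300),
               rearrangement_op("INV_DUP", 40000, 41500))
  calls <- resolve_plan(ref, plan, p)$res$calls
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, ref, path)
  back <- read_vcf(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$end, calls$end)
  expect_equal(back$svtype, calls$svtype)
  expect_equal(back$signature, calls$signature)
  expect_equal(back$svlen, calls$svlen)
  expect_equal(back$sample, calls$sample)
  # deletion POS/anchor convention
  del <- readLines(path)
  del <- del[!startsWith(del, "#")]
  f <- strsplit(del[1], "\t")[[1]]
  expect_equal(as.integer(f[2]), 20000)
  expect_match(f[8], "SVLEN=-1000")

  bcftools <- Sys.which("bcftools")
  skip_if(bcftools == "", "bcftools not on PATH")
  status <- system2(bcftools, c("view", path), stdout = FALSE,
                    stderr = FALSE)
  expect_equal(status, 0)
})

test_that("merged callsets round-trip carriers and AF through VCF", {
  calls <- random_callset(9, n_calls = 8)
  merged <- allele_frequency(merge_nonredundant(calls), n_haplotypes = 20)
  ref <- genome_sequence("ref", random_dna(1000000))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(merged, ref, path)
  back <- read_vcf(path)
  expect_equal(back$allele_count, merged$allele_count)
  expect_equal(back$af, merged$af, tolerance = 1e-6)
  expect_equal(back$carriers, merged$carriers, ignore_attr = TRUE)
})
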