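# Nonredundant merging, reciprocal overlap, sequence identity, allele
# frequencies.

test_that("reciprocal overlap follows its definition", {
  expect_equal(reciprocal_overlap(0, 100, 0, 100), 1.0)
  expect_equal(reciprocal_overlap(0, 100, 50, 150), 0.5)
  expect_equal(reciprocal_overlap(0, 100, 200, 300), 0.0)
  expect_equal(reciprocal_overlap(0, 1000, 400, 500), 0.1)
  expect_error(reciprocal_overlap(5, 5, 0, 10), "zero-length")
})

test_that("sequence identity matches independent alignment oracles", {
  expect_equal(sequence_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_error(sequence_identity("", "ACGT"), "empty")
  # ~10% substitutions -> identity 0.90 +/- 0.01
  set.seed(5)
  a <- random_dna(1000)
  bases <- strsplit(a, "")[[1]]
  idx <- sample(1000, 100)
  bases[idx] <- vapply(bases[idx], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1)
  }, character(1))
  b <- paste(bases, collapse = "")
  expect_equal(sequence_identity(a, b), 0.90, tolerance = 0.01)
  # full-DP oracle on short strings: same optimum as Biostrings
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    x <- random_dna(sample(50:200, 1)); y <- random_dna(sample(50:200, 1))
    ours <- complexsv:::nw_align(x, y, 1L, -1L, -1L)$score
    theirs <- Biostrings::score(Biostrings::pairwiseAlignment(
      x, y, substitutionMatrix = mat, gapOpening = 0, gapExtension = 1))
    expect_equal(ours, theirs)
  }
})

test_that("identical calls in a cohort merge with correct AF arithmetic", {
  calls <- random_callset(1, n_calls = 2, n_haps = 20)
  calls$pos <- calls$pos[1]; calls$end <- calls$end[1]
  calls$svtype <- calls$svtype[1]; calls$svlen <- calls$svlen[1]
  calls$sample <- c("S01", "S02"); calls$hap <- c(1L, 1L)
  merged <- merge_nonredundant(calls)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$allele_count, 2)
  af <- allele_frequency(merged, n_haplotypes = 20)
  expect_equal(af$af, 0.10)
})

test_that("calls below the reciprocal-overlap threshold stay separate", {
  a <- random_callset(2, n_calls = 1)[1, ]
  a$svtype <- a$signature <- "DEL"
  a$end <- a$pos + 1000L; a$svlen <- -1000L
  b <- a
  b$sample <- "S09"
  # shift so RO = 0.4
  len <- a$end - a$pos
  b$pos <- a$pos + as.integer(0.6 * len)
  b$end <- b$pos + len
  merged <- merge_nonredundant(rbind(a, b))
  expect_equal(nrow(merged), 2)
})

test_that("greedy merge equals the transitive-closure oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:25) {
    calls <- random_callset(s, n_calls = sample(10:50, 1))
    merged <- merge_nonredundant(calls)
    oracle <- closure_merge_oracle(
      calls[order(calls$rname, calls$pos, calls$end, calls$sample,
                  calls$hap), ])
    expect_equal(nrow(merged), length(unique(oracle)))
    # carrier conservation: every input call lands in exactly one variant
    expect_equal(sum(merged$allele_count), nrow(calls))
  }
})

test_that("duplicate records are deduplicated with a warning", {
  calls <- random_callset(3, n_calls = 5)
  expect_warning(merged <- merge_nonredundant(rbind(calls, calls[1, ])),
                 "deduplicated")
  expect_equal(sum(merged$allele_count), nrow(calls))
})

test_that("allele frequencies exclude configured samples consistently", {
  calls <- random_callset(4, n_calls = 12)
  merged <- merge_nonredundant(calls)
  af_all <- allele_frequency(merged, n_haplotypes = 20)
  expect_true(all(af_all$af > 0 & af_all$af <= 1))
  child <- sub("#.*", "", merged$carriers[[1]][1])
  af_ex <- allele_frequency(merged, n_haplotypes = 20,
                            excluded_samples = child)
  expect_equal(af_ex$allele_count[1],
               sum(!grepl(paste0("^", child, "#"), merged$carriers[[1]])))
  expect_error(allele_frequency(merged, n_haplotypes = 2,
                                excluded_samples = c("S01", "S02")),
               "no haplotypes")
})
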