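# Anchor seeding and colinear chaining.

test_that("self-alignment tiles every unique k-mer position", {
  ref <- make_reference(2, 12000)
  an <- index_and_anchor(ref, ref, k = 31)
  expect_true(all(an$strand == "+"))
  expect_true(all(an$qpos == an$rpos))
  # random 12 kbp sequence: essentially every position is a unique k-mer
  expect_gt(nrow(an), 12000 - 31 - 50)
})

test_that("reverse-complement haplotype anchors entirely on minus strand", {
  ref <- make_reference(2, 12000)
  rc <- genome_sequence("rc", revcomp(ref$seq))
  an <- index_and_anchor(ref, rc, k = 31)
  expect_true(all(an$strand == "-"))
  ch <- chain_anchors(an)
  expect_length(ch, 1)
})

test_that("anchors equal a brute-force k-mer scan on a small instance", {
  ref <- make_reference(13, 10000)
  hap <- apply_plan(ref, list(rearrangement_op("INV", 4000, 4600)))$hap
  k <- 31
  an <- index_and_anchor(ref, hap, k = k)
  # oracle: enumerate all k-mers of both sequences directly
  rk <- substring(ref$seq, 1:(nchar(ref$seq) - k + 1),
                  k:nchar(ref$seq))
  rc <- revcomp(rk)
  canon <- pmin(rk, rc)
  uniq <- !(duplicated(canon) | duplicated(canon, fromLast = TRUE))
  qk <- substring(hap$seq, 1:(nchar(hap$seq) - k + 1), k:nchar(hap$seq))
  oracle <- do.call(rbind, lapply(seq_along(qk), function(q) {
    fwd <- which(uniq & rk == qk[q])
    rev <- which(uniq & rc == qk[q])
    rbind(if (length(fwd)) data.frame(qpos = q - 1L, rpos = fwd - 1L,
                                      strand = "+"),
          if (length(rev)) data.frame(qpos = q - 1L, rpos = rev - 1L,
                                      strand = "-"))
  }))
  rownames(oracle) <- NULL
  rownames(an) <- NULL
  expect_equal(an, oracle)
})

test_that("an inverted middle segment yields exactly three chains", {
  ref <- make_reference(4, 20000)
  hap <- apply_plan(ref, list(rearrangement_op("INV", 8000, 12000)))$hap
  an <- index_and_anchor(ref, hap, k = 31)
  ch <- chain_anchors(an)
  expect_length(ch, 3)
  expect_equal(unname(vapply(ch, attr, character(1), "strand")),
               c("+", "-", "+"))
})

test_that("greedy chains match exhaustive colinear-subset search", {
  # oracle: largest colinear subset (same strand, monotone, bounded diagonal
  # shift) over a small anchor set, by exhaustive DP over subsets of chains
  ref <- make_reference(4, 20000)
  hap <- apply_plan(ref, list(rearrangement_op("DEL", 8000, 8200)))$hap
  an <- index_and_anchor(ref, hap, k = 31)
  an <- an[seq(1, nrow(an), length.out = 40), ]  # <= 50 anchors
  an <- an[order(an$qpos), ]
  ch <- chain_anchors(an, max_gap = 10000)
  best_len <- max(vapply(ch, nrow, integer(1)))
  # longest-increasing-subsequence style oracle
  n <- nrow(an)
  dp <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      compat <- an$strand[i] == an$strand[j] &&
        an$qpos[i] > an$qpos[j] &&
        (if (an$strand[i] == "+") an$rpos[i] > an$rpos[j]
         else an$rpos[i] < an$rpos[j]) &&
        abs((an$rpos[i] - an$qpos[i]) - (an$rpos[j] - an$qpos[j])) <= 10000
      if (compat) dp[i] <- max(dp[i], dp[j] + 1L)
    }
  }
  expect_equal(best_len, max(dp))
})
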