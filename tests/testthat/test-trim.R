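# Trimming of multiply-aligned query bases.

test_that("disjoint records pass through unchanged", {
  recs <- rbind(make_record(qstart = 0, qend = 1000, rstart = 0,
                            rend = 1000),
                make_record(qstart = 1500, qend = 2500, rstart = 2000,
                            rend = 3000))
  out <- trim_overlaps(recs)
  expect_equal(out$qstart, recs$qstart)
  expect_equal(out$qend, recs$qend)
})

test_that("the lower-scoring record is trimmed at the overlap", {
  a <- make_record(qstart = 0, qend = 1000, rstart = 0, rend = 1000,
                   score = 100)
  b <- make_record(qstart = 900, qend = 2000, rstart = 2000, rend = 3100,
                   score = 50)
  out <- trim_overlaps(rbind(a, b))
  expect_equal(out$qstart, c(0, 1000))
  expect_equal(out$qend, c(1000, 2000))
  expect_equal(out$rstart[2], 2100)  # 100 reference bases cut with the query
  expect_true(validate_records(out))
  # equal scores: the record with the larger qstart loses
  b2 <- make_record(qstart = 900, qend = 1900, rstart = 2000, rend = 3000,
                    score = 1000)
  a2 <- make_record(qstart = 0, qend = 1000, rstart = 0, rend = 1000,
                    score = 1000)
  out2 <- trim_overlaps(rbind(a2, b2))
  expect_equal(out2$qstart[2], 1000)
})

test_that("trimming is idempotent and output coverage fits in the query", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    starts <- sort(sample(0:5000, n))
    recs <- do.call(rbind, lapply(seq_len(n), function(j) {
      len <- sample(300:2000, 1)
      make_record(qstart = starts[j], qend = starts[j] + len,
                  rstart = starts[j] + 100, rend = starts[j] + 100 + len,
                  score = sample(50:500, 1))
    }))
    once <- trim_overlaps(recs)
    twice <- trim_overlaps(once)
    expect_equal(once[names(once) != "identity"],
                 twice[names(twice) != "identity"],
                 ignore_attr = TRUE)
    # disjoint output, total coverage bounded by the query length
    if (nrow(once) > 1) {
      expect_true(all(once$qstart[-1] >= once$qend[-nrow(once)]))
    }
    expect_lte(sum(once$qend - once$qstart), 10000)
  }
})

test_that("records trimmed below min_keep are dropped and logged", {
  a <- make_record(qstart = 0, qend = 1000, rstart = 0, rend = 1000,
                   score = 100)
  b <- make_record(qstart = 900, qend = 1150, rstart = 2000, rend = 2250,
                   score = 10)
  out <- trim_overlaps(rbind(a, b), min_keep = 200)
  expect_equal(nrow(out), 1)
  log <- attr(out, "trim_log")
  expect_true("drop" %in% log$action)
})
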