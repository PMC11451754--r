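# Variant graph construction and optimal-path solving.

test_that("penalty model follows the open + log-size law", {
  p <- sv_params()
  cand <- complexsv:::new_candidate("DEL", 100, 100)
  expect_equal(score_variant(cand, p), unname(p$open[["DEL"]]))
  # doubling a large span adds about size_coef
  c1 <- complexsv:::new_candidate("DEL", 0, 4000)
  c2 <- complexsv:::new_candidate("DEL", 0, 8000)
  expect_equal(score_variant(c2, p) - score_variant(c1, p), p$size_coef,
               tolerance = 1e-3)
  # hand-computed defaults for spans 10 and 1000
  for (cls in c("INS", "DEL", "INV", "DUP", "TEMPLATE_SWITCH")) {
    for (span in c(10, 1000)) {
      cand <- if (cls == "INS") {
        complexsv:::new_candidate("INS", 0, 0, alt_seq = strrep("A", span))
      } else {
        complexsv:::new_candidate(cls, 0, span)
      }
      expect_equal(score_variant(cand, p),
                   unname(p$open[[cls]]) + 0.5 * log2(1 + span))
    }
  }
  expect_error(sv_params(size_coef = -1), "non-negative")
})

test_that("trivial graphs have the expected shape", {
  recs <- make_record(qstart = 0, qend = 1000, rstart = 0, rend = 1000)
  g <- build_dag(recs, list(), sv_params())
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)
  expect_true(all(g$edges$label == "null"))
  path <- solve_optimal_path(g)
  expect_equal(path$nodes, c(0, 1, 2))
  expect_equal(path$penalty, 0)
})

test_that("parallel candidate edges and counts match a hand-built fixture", {
  recs <- rbind(
    make_record(qstart = 0, qend = 1000, rstart = 0, rend = 1000),
    make_record(qstart = 1000, qend = 2000, rstart = 1500, rend = 2500),
    make_record(qstart = 2000, qend = 3000, rstart = 2500, rend = 3500),
    make_record(qstart = 3000, qend = 4000, rstart = 4000, rend = 5000))
  cands <- list(
    list(from = 1L, to = 2L,
         variants = list(complexsv:::new_candidate("DEL", 1000, 1500)),
         penalty = 5),
    list(from = 1L, to = 2L,
         variants = list(complexsv:::new_candidate(
           "TEMPLATE_SWITCH", 1000, 1500, alt_seq = "ACGT",
           donor_start = 9000L, donor_end = 9500L, donor_strand = "+")),
         penalty = 7),
    list(from = 2L, to = 3L, variants = list(), penalty = 0),
    list(from = 3L, to = 4L,
         variants = list(complexsv:::new_candidate("DEL", 3500, 4000)),
         penalty = 4))
  g <- build_dag(recs, cands, sv_params())
  # 4 records + SOURCE/SINK; 4 pair edges + 4 SOURCE + 4 SINK connections
  expect_equal(nrow(g$nodes), 6)
  expect_equal(sum(g$edges$from == 1 & g$edges$to == 2), 2)
  expect_equal(nrow(g$edges), 12)
  path <- solve_optimal_path(g)
  expect_equal(path$penalty, 9)
  chosen <- g$edges[path$edge_idx, ]
  expect_true("DEL" %in% chosen$label)
  expect_false("TEMPLATE_SWITCH" %in% chosen$label)
})

test_that("optimal path equals exhaustive enumeration on random DAGs", {
  for (s in 1:150) {
    g <- random_graph(s, max_nodes = 12)
    path <- solve_optimal_path(g)
    expect_equal(path$penalty, brute_force_best_path(g), tolerance = 1e-9)
  }
})

test_that("tie-breaking is deterministic: fewer edges, then node order", {
  nodes <- data.frame(node = 0:3,
                      label = c("SOURCE", "R001", "R002", "SINK"),
                      qstart = c(-1, 100, 200, 300))
  edges <- data.frame(from = c(0, 0, 1, 2, 0),
                      to = c(1, 2, 3, 3, 3),
                      penalty = c(1, 1, 1, 1, 2),
                      label = "null")
  edges$variants <- rep(list(list()), nrow(edges))
  g <- structure(list(nodes = nodes, edges = edges, n_records = 2),
                 class = "variant_graph")
  path <- solve_optimal_path(g)
  # three penalty-2 paths exist; the single-edge path wins, and reruns agree
  expect_equal(path$nodes, c(0, 3))
  expect_identical(path, solve_optimal_path(g))
})

test_that("an unreachable SINK is reported with the break position", {
  recs <- rbind(
    make_record(qstart = 0, qend = 1000, rstart = 0, rend = 1000),
    make_record(qstart = 500000, qend = 501000, qlen = 600000,
                rstart = 5000, rend = 6000))
  g <- build_dag(recs, list(), sv_params(max_join = 1000))
  expect_error(solve_optimal_path(g), "unreachable|break")
})
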