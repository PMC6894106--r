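# Toy fixture: a small graph with known structure.
#   hub -- b1 -- cand, hub -- b2 -- cand, hub -- direct
toy_graph <- function() {
  cooccurrence_graph(parse_relations(c(
    "1 | 1 | hub | DISEASE | b1 | GENE | CO-OCCUR |",
    "1 | 2 | hub | DISEASE | b1 | GENE | CO-OCCUR |",
    "2 | 1 | b1 | GENE | cand | GENE | CO-OCCUR |",
    "3 | 1 | hub | DISEASE | b2 | GENE | CO-OCCUR |",
    "4 | 1 | b2 | GENE | cand | GENE | CO-OCCUR |",
    "5 | 1 | hub | DISEASE | direct | GENE | CO-OCCUR |",
    "5 | 2 | hub | DISEASE | direct | GENE | CO-OCCUR |")))
}

toy_provider <- function() {
  table_provider(data.frame(
    a = c("hub", "b1", "hub", "b2", "hub"),
    b = c("b1", "cand", "b2", "cand", "direct"),
    s = c(0.8, 0.6, 0.5, 0.4, 0.9)))
}

test_that("the direct score is relatedness times 2*alpha + beta", {
  expect_equal(direct_score(0.427029, 4123, 1003), 3949.592,
               tolerance = 0.01 / 3949.592)
  expect_equal(direct_score(0, 123, 456), 0)
  expect_equal(direct_score(0.37, 0, 1), 0.37)
  expect_error(direct_score(0.5, -1, 2), "non-negative")
})

test_that("path scores weight each leg's relatedness by its co-occurrence count", {
  expect_equal(path_score(0.434575, 1750, 0.712967, 1562), 1874.1596,
               tolerance = 0.01 / 1874)
  expect_equal(path_score(0.398862, 692, 0.774334, 1294), 1278.0003,
               tolerance = 0.01 / 1278)
  expect_equal(path_score(0.25, 1, 0.25, 1), 0.5)
  expect_error(path_score(0.5, 0, 0.5, 3), "positive")
})

test_that("indirect relatedness is the frequency-weighted mean of the leg relatednesses", {
  expect_equal(indirect_relatedness(0.434575, 1750, 0.712967, 1562),
               0.56587, tolerance = 0.0001 / 0.56587)
  expect_equal(indirect_relatedness(0.42, 17, 0.42, 930), 0.42)
  expect_error(indirect_relatedness(0.1, 0, 0.2, 0), "positive")
  withr_seed(40, {
    for (i in 1:200) {
      s1 <- runif(1, -1, 1); s2 <- runif(1, -1, 1)
      a <- sample.int(1000, 1); b <- sample.int(1000, 1)
      s_ind <- indirect_relatedness(s1, a, s2, b)
      expect_equal(s_ind, path_score(s1, a, s2, b) / (a + b))
      expect_gte(s_ind, min(s1, s2) - 1e-12)
      expect_lte(s_ind, max(s1, s2) + 1e-12)
    }
  })
})

test_that("the indirect score accumulates one path score per shared intermediate", {
  g <- toy_graph()
  p <- toy_provider()
  res <- indirect_score(g, p, "hub", "cand")
  # b1 path: 0.8*2 + 0.6*1 = 2.2 ; b2 path: 0.5*1 + 0.4*1 = 0.9
  expect_equal(res$y_indirect, 3.1)
  expect_equal(res$paths$intermediate, c("b1", "b2"))
  expect_equal(res$paths$x, c(2.2, 0.9))
  # no shared neighbors -> zero with an empty path table
  # ("direct" only neighbors hub; "cand" only neighbors b1, b2)
  none <- indirect_score(g, p, "direct", "cand")
  expect_equal(none$y_indirect, 0)
  expect_equal(nrow(none$paths), 0L)
  # triangle with unit counts and unit relatedness scores 2
  tri <- cooccurrence_graph(parse_relations(c(
    "1 | 1 | a | GENE | b | GENE | CO-OCCUR |",
    "2 | 1 | b | GENE | c | GENE | CO-OCCUR |")))
  ones <- table_provider(data.frame(a = c("a", "b"), b = c("b", "c"),
                                    s = c(1, 1)))
  expect_equal(indirect_score(tri, ones, "a", "c")$y_indirect, 2)
})

test_that("indirect scores equal brute-force path enumeration on random graphs", {
  for (seed in 1:12) {
    recs <- random_records(90, n_entities = sample(5:15, 1), seed = seed)
    g <- cooccurrence_graph(recs)
    p <- random_provider(g$nodes, seed = seed + 500)
    pick <- withr_seed(seed + 900, sample(g$nodes, 2))
    got <- indirect_score(g, p, pick[1], pick[2])$y_indirect
    expect_equal(got, brute_indirect(recs, p, pick[1], pick[2]),
                 tolerance = 1e-10)
  }
})

test_that("the hybrid score decomposes into direct plus indirect and is symmetric", {
  g <- toy_graph(); p <- toy_provider()
  ts <- total_score(g, p, "hub", "cand")
  expect_equal(ts$y_direct, 0)         # hub and cand never co-occur directly
  expect_equal(ts$y_total, 3.1)
  expect_equal(ts$n_intermediates, 2L)
  td <- total_score(g, p, "hub", "direct")
  expect_equal(td$y_direct, 0.9 * (2 * 2 + 0))  # one abstract, two mentions
  for (seed in 1:5) {
    recs <- random_records(80, seed = seed)
    g2 <- cooccurrence_graph(recs)
    p2 <- random_provider(g2$nodes, seed = seed + 50)
    pick <- withr_seed(seed + 60, sample(g2$nodes, 2))
    f <- total_score(g2, p2, pick[1], pick[2])
    r <- total_score(g2, p2, pick[2], pick[1])
    expect_equal(f$y_total, r$y_total)
    expect_equal(f$y_total, f$y_direct + f$y_indirect)
    ind <- indirect_score(g2, p2, pick[1], pick[2])$y_indirect
    expect_equal(f$y_indirect, ind)
  }
  # disconnected pair scores zero overall
  iso <- cooccurrence_graph(parse_relations(c(
    "1 | 1 | a | GENE | b | GENE | CO-OCCUR |",
    "2 | 1 | c | GENE | d | GENE | CO-OCCUR |")))
  expect_equal(total_score(iso, toy_provider(), "a", "c")$y_total, 0)
})

test_that("ranking sorts by total score with lexicographic ties and min-max normalization", {
  g <- toy_graph(); p <- toy_provider()
  rl <- rank_candidates(g, p, "hub")
  expect_s3_class(rl, "ranked_list")
  # direct: 0.9*(2*2) = 3.6 ; b1: 0.8*4 = 3.2 ; cand: 3.1 ; b2: 0.5
  expect_identical(rl$candidate, c("direct", "b1", "cand", "b2"))
  expect_equal(rl$normalized[1], 1)
  expect_equal(rl$normalized[nrow(rl)], 0)
  expect_false(is.unsorted(rev(rl$y_total)))
  # scores agree with independently recomputed total scores
  for (i in seq_len(nrow(rl))) {
    expect_equal(rl$y_total[i],
                 total_score(g, p, "hub", rl$candidate[i])$y_total)
  }
  # single-candidate list is degenerate and normalizes to 1
  one <- rank_candidates(g, p, "hub", candidates = "cand")
  expect_equal(one$normalized, 1)
  expect_error(rank_candidates(g, p, "nope"), "unknown entity")
})

test_that("ranking order matches a sort of independently computed scores on random graphs", {
  for (seed in 1:5) {
    recs <- random_records(100, seed = seed)
    g <- cooccurrence_graph(recs)
    p <- random_provider(g$nodes, seed = seed + 70)
    target <- g$nodes[1]
    rl <- rank_candidates(g, p, target)
    ys <- vapply(rl$candidate, function(cc)
      total_score(g, p, target, cc)$y_total, 0)
    ord <- order(-ys, names(ys), method = "radix")
    expect_identical(rl$candidate, unname(names(ys)[ord]))
  }
})

test_that("scaling every relatedness by k > 0 scales scores and preserves the ranking", {
  recs <- random_records(100, seed = 42)
  g <- cooccurrence_graph(recs)
  pairs <- t(combn(g$nodes, 2))
  base <- withr_seed(43, data.frame(a = pairs[, 1], b = pairs[, 2],
                                    s = runif(nrow(pairs), 0.05, 1)))
  scaled <- transform(base, s = s * 3.7)
  r1 <- rank_candidates(g, table_provider(base), g$nodes[1])
  r2 <- rank_candidates(g, table_provider(scaled), g$nodes[1])
  expect_identical(r1$candidate, r2$candidate)
  expect_equal(r2$y_total, 3.7 * r1$y_total, tolerance = 1e-10)
  expect_equal(r2$normalized, r1$normalized, tolerance = 1e-10)
})

test_that("adding a positively related intermediate never decreases the hybrid score", {
  base_lines <- c(
    "1 | 1 | a | GENE | m1 | GENE | CO-OCCUR |",
    "2 | 1 | m1 | GENE | c | GENE | CO-OCCUR |")
  extra_lines <- c(base_lines,
    "3 | 1 | a | GENE | m2 | GENE | CO-OCCUR |",
    "4 | 1 | m2 | GENE | c | GENE | CO-OCCUR |")
  p <- table_provider(data.frame(a = c("a", "m1", "a", "m2"),
                                 b = c("m1", "c", "m2", "c"),
                                 s = c(0.4, 0.5, 0.2, 0.3)))
  y0 <- total_score(cooccurrence_graph(parse_relations(base_lines)),
                    p, "a", "c")$y_total
  y1 <- total_score(cooccurrence_graph(parse_relations(extra_lines)),
                    p, "a", "c")$y_total
  expect_gte(y1, y0)
})

test_that("the co-occurrence baseline ranks by edge totals with the same normalization", {
  star <- cooccurrence_graph(parse_relations(c(
    "1 | 1 | hub | DISEASE | x | GENE | CO-OCCUR |",
    "1 | 2 | hub | DISEASE | x | GENE | CO-OCCUR |",
    "2 | 1 | hub | DISEASE | x | GENE | CO-OCCUR |",
    "3 | 1 | hub | DISEASE | y | GENE | CO-OCCUR |",
    "4 | 1 | hub | DISEASE | y | GENE | CO-OCCUR |",
    "5 | 1 | hub | DISEASE | z | GENE | CO-OCCUR |")))
  rl <- rank_by_cooccurrence(star, "hub")
  expect_identical(rl$candidate, c("x", "y", "z"))
  expect_equal(rl$y_total, c(3, 2, 1))
  expect_equal(rl$normalized, c(1, 0.5, 0))
  # record-order permutation leaves the baseline ranking unchanged
  recs <- random_records(120, seed = 3)
  g1 <- cooccurrence_graph(recs)
  g2 <- cooccurrence_graph(withr_seed(4, recs[sample.int(nrow(recs)), ]))
  t1 <- rank_by_cooccurrence(g1, g1$nodes[1])
  t2 <- rank_by_cooccurrence(g2, g1$nodes[1])
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("min-max normalization handles the degenerate all-equal case", {
  expect_equal(minmax_normalize(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(minmax_normalize(c(3, 2, 1)), c(1, 0.5, 0))
  expect_equal(minmax_normalize(numeric(0)), numeric(0))
})
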