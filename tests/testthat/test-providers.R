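test_that("table provider gives symmetric lookup, implicit self-similarity, and defaults", {
  tp <- table_provider(data.frame(a = "alzheimer's disease", b = "app",
                                  s = 0.427029))
  expect_equal(relatedness(tp, "app", "Alzheimer's disease"), 0.427029)
  expect_equal(relatedness(tp, "alzheimer's disease", "app"), 0.427029)
  expect_equal(relatedness(tp, "app", "app"), 1)
  expect_equal(relatedness(tp, "app", "unknown gene"), 0)
  expect_true(coverage(tp, "APP"))
  expect_false(coverage(tp, "psen1"))
  tp5 <- table_provider(data.frame(a = "x", b = "y", s = 0.3), default = 0.5)
  expect_equal(relatedness(tp5, "x", "zzz"), 0.5)
  expect_error(
    table_provider(data.frame(a = c("x", "y"), b = c("y", "x"),
                              s = c(0.3, 0.4))),
    "conflicting")
  # consistent duplicates are fine
  expect_silent(table_provider(data.frame(a = c("x", "y"), b = c("y", "x"),
                                          s = c(0.3, 0.3))))
})

test_that("relatedness tables round-trip through the TSV format", {
  df <- data.frame(entity_a = c("a", "b"), entity_b = c("b", "c"),
                   s = c(0.25, -0.1))
  f <- withr_tempfile(".tsv")
  write_relatedness_table(df, f)
  tp <- read_relatedness_table(f)
  expect_equal(relatedness(tp, "a", "b"), 0.25)
  expect_equal(relatedness(tp, "c", "b"), -0.1)
})

test_that("corpus construction orders tokens by sentence and doubles the record count", {
  rec <- parse_relations(
    "19,395,124 | 8 | MCI | DISEASE | depression | DISEASE | CO-OCCUR |")
  corp <- corpus_from_records(rec)
  expect_identical(corp, list(`19395124` = c("mci", "depression")))
  expect_identical(corpus_from_records(parse_relations(character(0))),
                   structure(list(), names = character(0)))
  rr <- random_records(80, seed = 3)
  corp <- corpus_from_records(rr)
  expect_equal(length(unlist(corp)), 2L * nrow(rr))
  expect_setequal(names(corp), as.character(unique(rr$pmid)))
  # within a document, tokens follow sentence order
  one <- rr[rr$pmid == rr$pmid[1], ]
  one <- one[order(one$sentence_index), ]
  expect_identical(corp[[as.character(rr$pmid[1])]],
                   as.vector(rbind(one$entity_a, one$entity_b)))
})

test_that("skip-gram separates co-occurring from non-co-occurring tokens", {
  # 100 documents: u,v always share a document (with a common filler
  # vocabulary); w lives on a disjoint background and never meets u
  corp <- withr_seed(500, c(
    lapply(1:50, function(i) c(sample(c("u", "v")),
                               sample(paste0("f", 1:20), 3))),
    lapply(1:50, function(i) c("w", sample(paste0("g", 1:20), 3)))))
  for (seed in 1:5) {
    m <- train_skipgram(corp, dim = 30, epochs = 20, seed = seed)
    expect_gt(relatedness(m, "u", "v"), relatedness(m, "u", "w"))
    expect_equal(relatedness(m, "u", "u"), 1)
  }
})

test_that("skip-gram training is deterministic under a fixed seed", {
  corp <- corpus_from_records(random_records(120, seed = 21))
  m1 <- train_skipgram(corp, dim = 16, epochs = 2, seed = 4)
  m2 <- train_skipgram(corp, dim = 16, epochs = 2, seed = 4)
  expect_identical(m1$vectors, m2$vectors)
  m3 <- train_skipgram(corp, dim = 16, epochs = 2, seed = 5)
  expect_false(identical(m1$vectors, m3$vectors))
})

test_that("specialized training reduces to plain skip-gram when the extra-context rate is 0", {
  corp <- corpus_from_records(random_records(80, seed = 8))
  th <- thesaurus(list(c("ent1", "ent2")))
  plain <- train_skipgram(corp, dim = 12, epochs = 2, seed = 6)
  spec0 <- train_specialized_skipgram(corp, th, context_sample_rate = 0,
                                      dim = 12, epochs = 2, seed = 6)
  expect_identical(plain$vectors, spec0$vectors)
})

test_that("specialized training warns and falls back when the thesaurus misses the corpus", {
  corp <- list(d1 = c("a", "b"), d2 = c("b", "c"), d3 = c("a", "c"))
  th <- thesaurus(list(c("nothere1", "nothere2")))
  expect_warning(
    spec <- train_specialized_skipgram(corp, th, context_sample_rate = 0.5,
                                       dim = 8, epochs = 2, seed = 2),
    "falling back")
  plain <- train_skipgram(corp, dim = 8, epochs = 2, seed = 2)
  expect_identical(spec$vectors, plain$vectors)
})

test_that("thesaurus contexts raise the cosine of grouped never-co-occurring tokens", {
  sc <- synth_corpus(synth_config(n_abstracts = 200, seed = 19))
  corp <- corpus_from_records(sc$records)
  wins <- 0L
  for (seed in 1:3) {
    plain <- train_skipgram(corp, dim = 40, epochs = 5, seed = seed)
    spec <- train_specialized_skipgram(corp, sc$thesaurus,
                                       context_sample_rate = 0.5,
                                       dim = 40, epochs = 5, seed = seed)
    s_p <- relatedness(plain, "app", "amyloid precursor protein")
    s_s <- relatedness(spec, "app", "amyloid precursor protein")
    expect_equal(s_s, relatedness(spec, "amyloid precursor protein", "app"))
    wins <- wins + (s_s > s_p)
  }
  expect_gte(wins, 2L)
})

test_that("embedding models persist to and from the plain-text format", {
  corp <- corpus_from_records(random_records(60, seed = 12))
  m <- train_skipgram(corp, dim = 10, epochs = 2, seed = 3)
  f <- withr_tempfile(".vec")
  write_embedding(m, f)
  back <- read_embedding(f)
  toks <- rownames(m$vectors)
  expect_equal(relatedness(back, toks[1], toks[2]),
               relatedness(m, toks[1], toks[2]), tolerance = 1e-12)
  expect_identical(rownames(back$vectors), toks)
})

test_that("the COALS transform matches a literal reference implementation on a toy corpus", {
  corp <- list(d1 = c("a", "b", "c", "a"),
               d2 = c("b", "c", "d", "e"),
               d3 = c("f", "a", "b", "f"),
               d4 = c("e", "d", "c", "b"))
  co <- build_coals(corp, window = 4, max_columns = 4)
  ref <- naive_coals_matrix(corp, window = 4, max_columns = 4)
  expect_equal(co$mat[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
  expect_true(all(co$mat >= 0))
  expect_equal(relatedness(co, "a", "a"), 1)
  # row-correlation similarity agrees with cor() on the reference matrix
  expect_equal(relatedness(co, "a", "b"), cor(ref["a", ], ref["b", ]),
               tolerance = 1e-12)
  expect_error(build_coals(corp, max_columns = 1), "max_columns")
})

test_that("COALS output is invariant to document order", {
  corp <- corpus_from_records(random_records(80, seed = 14))
  co1 <- build_coals(corp, max_columns = 8)
  co2 <- build_coals(rev(corp), max_columns = 8)
  expect_equal(co1$mat, co2$mat)
})

test_that("random-indexing index vectors are balanced ternary and similarities reproducible", {
  corp <- corpus_from_records(random_records(100, seed = 17))
  ri <- build_random_indexing(corp, dimension = 60, nonzeros = 6, seed = 5)
  expect_true(all(rowSums(ri$index_vectors != 0) == 6))
  expect_true(all(rowSums(ri$index_vectors) == 0))
  expect_true(all(ri$index_vectors %in% c(-1L, 0L, 1L)))
  ri2 <- build_random_indexing(corp, dimension = 60, nonzeros = 6, seed = 5)
  expect_identical(ri$vectors, ri2$vectors)
  expect_error(build_random_indexing(corp, dimension = 4, nonzeros = 6),
               "exceed")
  expect_error(build_random_indexing(corp, dimension = 60, nonzeros = 5),
               "even")
})

test_that("tokens with identical contexts get random-indexing cosine 1", {
  corp <- lapply(1:20, function(i) {
    ctx <- paste0("c", i %% 4)
    c(ctx, "twin1", ctx, "twin2", ctx)
  })
  ri <- build_random_indexing(corp, dimension = 80, nonzeros = 8,
                              window = 1, seed = 3)
  expect_equal(relatedness(ri, "twin1", "twin2"), 1, tolerance = 1e-9)
})

test_that("every provider type is symmetric with unit self-similarity on covered entities", {
  corp <- corpus_from_records(random_records(80, seed = 23))
  provs <- list(
    sg = train_skipgram(corp, dim = 12, epochs = 2, seed = 1),
    coals = build_coals(corp, max_columns = 6),
    ri = build_random_indexing(corp, dimension = 40, nonzeros = 4, seed = 1),
    tab = random_provider(paste0("ent", 1:6), seed = 2))
  for (p in provs) {
    toks <- if (inherits(p, "relatedness_table")) p$entities else
      if (inherits(p, "coals_provider")) rownames(p$mat) else
        rownames(p$vectors)
    pick <- toks[1:2]
    expect_equal(relatedness(p, pick[1], pick[2]),
                 relatedness(p, pick[2], pick[1]))
    expect_equal(relatedness(p, pick[1], pick[1]), 1)
  }
})
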