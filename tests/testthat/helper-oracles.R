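# Independent oracles and random-input generators shared by the suite.
# Everything here recomputes quantities by brute force, without touching
# the package's aggregation or scoring internals.

rand_label <- function(n) {
  paste0("e", sample.int(50, n, replace = TRUE))
}

# Random well-formed relation records (entities already normalized).
random_records <- function(n, n_entities = 8, n_pmids = 6, seed = NULL) {
  gen <- function() {
    ents <- paste0("ent", seq_len(n_entities))
    a <- sample(ents, n, replace = TRUE)
    b <- sample(ents, n, replace = TRUE)
    while (any(a == b)) {
      i <- a == b
      b[i] <- sample(ents, sum(i), replace = TRUE)
    }
    data.frame(
      pmid = sample.int(n_pmids, n, replace = TRUE) + 1000L,
      sentence_index = sample.int(30, n, replace = TRUE),
      entity_a = a,
      type_a = sample(c("GENE", "DRUG", "DISEASE", "OTHER"), n, replace = TRUE),
      entity_b = b,
      type_b = sample(c("GENE", "DRUG", "DISEASE", "OTHER"), n, replace = TRUE),
      relation = sample(c("CO-OCCUR", "RESULT_OF", "INHIBITS"), n,
                        replace = TRUE),
      stringsAsFactors = FALSE)
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

withr_tempfile <- function(ext = ".txt") tempfile(fileext = ext)

# minimal local stand-in for withr::with_seed
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Brute-force recount of one pair's statistics from raw records.
brute_pair_stats <- function(records, x, y) {
  hit <- (records$entity_a == x & records$entity_b == y) |
         (records$entity_a == y & records$entity_b == x)
  if (!any(hit)) return(NULL)
  per_abstract <- table(records$pmid[hit])
  c_d <- as.integer(per_abstract)
  list(total = sum(c_d), alpha = sum(c_d[c_d >= 2]), beta = sum(c_d == 1),
       abstracts_multi = sum(c_d >= 2), abstracts_single = sum(c_d == 1))
}

# Brute-force shared-intermediate enumeration from raw records.
brute_intermediates <- function(records, a, c_) {
  nb <- function(x) {
    unique(c(records$entity_b[records$entity_a == x],
             records$entity_a[records$entity_b == x]))
  }
  setdiff(intersect(nb(a), nb(c_)), c(a, c_))
}

# Brute-force indirect score by explicit A-B-C path enumeration.
brute_indirect <- function(records, provider, a, c_) {
  mids <- brute_intermediates(records, a, c_)
  total <- 0
  for (b in mids) {
    sa <- brute_pair_stats(records, a, b)$total
    sb <- brute_pair_stats(records, b, c_)$total
    total <- total + relatedness(provider, a, b) * sa +
      relatedness(provider, b, c_) * sb
  }
  total
}

# Random relatedness table covering all pairs over a set of entities.
random_provider <- function(entities, seed) {
  withr_seed(seed, {
    pairs <- t(combn(sort(entities), 2))
    table_provider(data.frame(a = pairs[, 1], b = pairs[, 2],
                              s = round(runif(nrow(pairs)), 4)))
  })
}

# Naive COALS reference: literal loop-based implementation of the
# ramped-count / correlation / truncation / sqrt pipeline plus row
# correlation, independent of the package's vectorized version.
naive_coals_matrix <- function(corpus, window, max_columns) {
  tokens <- unlist(corpus, use.names = FALSE)
  freq <- table(tokens)
  vocab <- names(freq)[order(-as.integer(freq), names(freq))]
  cols <- vocab[seq_len(min(max_columns, length(vocab)))]
  M <- matrix(0, length(vocab), length(cols),
              dimnames = list(vocab, cols))
  for (doc in corpus) {
    for (i in seq_along(doc)) {
      for (j in seq_along(doc)) {
        off <- abs(i - j)
        if (j == i || off > window) next
        if (doc[j] %in% cols) {
          M[doc[i], doc[j]] <- M[doc[i], doc[j]] + (window - off + 1)
        }
      }
    }
  }
  total <- sum(M)
  r <- rowSums(M); cl <- colSums(M)
  X <- M
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      den <- sqrt(r[i] * (total - r[i]) * cl[j] * (total - cl[j]))
      X[i, j] <- if (den > 0) (total * M[i, j] - r[i] * cl[j]) / den else 0
      if (X[i, j] < 0) X[i, j] <- 0
      X[i, j] <- sqrt(X[i, j])
    }
  }
  X
}
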