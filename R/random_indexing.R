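#' Build a random-indexing relatedness provider
#'
#' Incremental distributional model: every token is assigned a seeded
#' sparse ternary index vector with `nonzeros` nonzero entries (half +1,
#' half -1, positions random) in `dimension` dimensions. A token's
#' context vector is the sum of the index vectors of its neighbors within
#' `window` positions, accumulated over the corpus. Similarity is the
#' cosine of context vectors. Fully reproducible under a fixed seed.
#'
#' @param corpus named list of token vectors.
#' @param dimension length of the index/context vectors.
#' @param nonzeros number of nonzero entries per index vector; must be
#'   even and smaller than `dimension`.
#' @param window context window (symmetric, unweighted).
#' @param seed RNG seed for index-vector construction.
#' @param default score for uncovered or zero-context pairs.
#' @return An `"embedding"` provider whose vectors are the context
#'   vectors; the ternary index vectors are kept in `$index_vectors`.
#' @export
build_random_indexing <- function(corpus, dimension = 300, nonzeros = 8,
                                  window = 4, seed = 1, default = 0) {
  if (nonzeros %% 2 != 0) stop_value("nonzeros must be even")
  if (dimension <= nonzeros) stop_value("dimension must exceed nonzeros")
  stopifnot(window >= 1)
  vc <- corpus_vocab(corpus)
  vocab <- vc$vocab
  nv <- length(vocab)
  idx <- with_seed(seed, {
    m <- matrix(0L, nrow = nv, ncol = dimension,
                dimnames = list(vocab, NULL))
    for (v in seq_len(nv)) {
      pos <- sample.int(dimension, nonzeros)
      m[v, pos] <- rep(c(1L, -1L), each = nonzeros / 2L)
    }
    m
  })
  ctx <- matrix(0, nrow = nv, ncol = dimension, dimnames = list(vocab, NULL))
  for (doc in corpus) {
    ids <- match(doc, vocab)
    n <- length(ids)
    if (n < 2L) next
    for (off in seq_len(min(window, n - 1L))) {
      i1 <- ids[seq_len(n - off)]
      i2 <- ids[seq.int(off + 1L, n)]
      for (k in seq_along(i1)) {
        ctx[i1[k], ] <- ctx[i1[k], ] + idx[i2[k], ]
        ctx[i2[k], ] <- ctx[i2[k], ] + idx[i1[k], ]
      }
    }
  }
  model <- new_embedding(ctx,
                         meta = list(method = "random_indexing",
                                     dim = dimension, nonzeros = nonzeros,
                                     window = window, seed = seed),
                         default = default)
  model$index_vectors <- idx
  model
}
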