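#' Build a training corpus from relation records
#'
#' Converts relation records into per-abstract token sequences suitable
#' for embedding training: for each PMID, records are ordered by
#' `sentence_index` (then original record order), and each record
#' contributes its two entities as adjacent tokens. The result emulates
#' the entity-level "text" the extraction pipeline sees — raw prose is
#' not reconstructed.
#'
#' @param records relation records data frame.
#' @return A named list (one element per PMID, in order of first
#'   appearance) of character token vectors.
#' @examples
#' recs <- parse_relations("19,395,124 | 8 | MCI | DISEASE | depression | DISEASE | CO-OCCUR |")
#' corpus_from_records(recs)
#' @export
corpus_from_records <- function(records) {
  check_records(records)
  if (nrow(records) == 0L) return(structure(list(), names = character(0)))
  ord <- order(match(records$pmid, unique(records$pmid)),
               records$sentence_index)
  r <- records[ord, , drop = FALSE]
  idx <- split(seq_len(nrow(r)), factor(r$pmid, levels = unique(r$pmid)))
  lapply(idx, function(i) {
    as.vector(rbind(r$entity_a[i], r$entity_b[i]))
  })
}

# Vocabulary ordered by frequency (desc), ties broken lexicographically.
corpus_vocab <- function(corpus) {
  tokens <- unlist(corpus, use.names = FALSE)
  if (length(tokens) == 0L) stop_value("corpus is empty")
  tab <- table(tokens)
  vocab <- names(tab)[order(-as.integer(tab), vapply(names(tab), identity, ""),
                            method = "radix")]
  list(vocab = vocab, counts = as.integer(tab[vocab]))
}

#' Train skip-gram embeddings on an entity corpus
#'
#' Standard skip-gram with negative sampling (SGNS): for every center
#' token, context tokens within a dynamic window are predicted against
#' `negative` samples drawn from the unigram distribution raised to the
#' 3/4 power. Training is single-threaded and fully deterministic for a
#' fixed `seed`. Relatedness is the cosine of the learned input vectors.
#'
#' @param corpus named list of token vectors (see
#'   [corpus_from_records()]).
#' @param dim embedding dimension (>= 2).
#' @param window maximum context window; the effective window per
#'   position is sampled in `1..window` as in word2vec.
#' @param negative number of negative samples per positive pair.
#' @param epochs passes over the corpus.
#' @param learning_rate initial learning rate, decayed linearly.
#' @param seed RNG seed for initialization and sampling.
#' @param default relatedness returned for uncovered pairs.
#' @return An `"embedding"` relatedness provider.
#' @export
train_skipgram <- function(corpus, dim = 100, window = 5, negative = 5,
                           epochs = 5, learning_rate = 0.025, seed = 1,
                           default = 0) {
  train_sgns_impl(corpus, NULL, 0, dim, window, negative, epochs,
                  learning_rate, seed, default, method = "skipgram")
}

#' Train thesaurus-specialized skip-gram embeddings
#'
#' Identical to [train_skipgram()] except that the training objective is
#' supplemented with thesaurus contexts: at each center position whose
#' token belongs to a thesaurus group, with probability
#' `context_sample_rate` one additional (token, context) pair is trained,
#' the context drawn uniformly from the other members of the token's
#' group that occur in the corpus. This pulls synonyms and associated
#' entities together even when they never co-occur in any abstract.
#' With `context_sample_rate = 0` the result is bit-identical to
#' [train_skipgram()] under the same seed.
#'
#' @inheritParams train_skipgram
#' @param thesaurus a [thesaurus] object supplying the extra contexts.
#' @param context_sample_rate probability in `[0, 1]` of one extra
#'   thesaurus pair per eligible center position.
#' @return An `"embedding"` relatedness provider.
#' @export
train_specialized_skipgram <- function(corpus, thesaurus,
                                       context_sample_rate = 0.5,
                                       dim = 100, window = 5, negative = 5,
                                       epochs = 5, learning_rate = 0.025,
                                       seed = 1, default = 0) {
  stopifnot(inherits(thesaurus, "thesaurus"),
            context_sample_rate >= 0, context_sample_rate <= 1)
  train_sgns_impl(corpus, thesaurus, context_sample_rate, dim, window,
                  negative, epochs, learning_rate, seed, default,
                  method = "specialized_skipgram")
}

train_sgns_impl <- function(corpus, thesaurus, rate, dim, window, negative,
                            epochs, learning_rate, seed, default, method) {
  vc <- corpus_vocab(corpus)
  if (length(vc$vocab) < 2L) stop_value("vocabulary below 2 tokens")
  stopifnot(dim >= 2, window >= 1, epochs >= 1)
  docs <- lapply(corpus, function(d) match(d, vc$vocab) - 1L)
  groups <- rep(list(integer(0)), length(vc$vocab))
  if (!is.null(thesaurus) && rate > 0) {
    covered <- FALSE
    for (g in thesaurus$groups) {
      members <- intersect(g, vc$vocab)
      if (length(members) >= 1L) covered <- TRUE
      if (length(members) < 2L) next
      for (m in members) {
        others <- setdiff(members, m)
        groups[[match(m, vc$vocab)]] <- match(others, vc$vocab) - 1L
      }
    }
    if (!covered) {
      warning("thesaurus covers no corpus token; falling back to plain skip-gram",
              call. = FALSE)
      rate <- 0
    }
  }
  V <- sgns_train_cpp(docs, vc$counts, as.integer(dim), as.integer(window),
                      as.integer(negative), as.integer(epochs),
                      learning_rate, rate, groups,
                      as.integer(seed) %% .Machine$integer.max)
  rownames(V) <- vc$vocab
  new_embedding(V, meta = list(method = method, dim = dim, window = window,
                               negative = negative, epochs = epochs,
                               context_sample_rate = rate, seed = seed),
                default = default)
}
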