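#' Fit a hybrid literature-based discovery ranking model
#'
#' The front door of the package: aggregates relation records into a
#' co-occurrence graph and attaches a semantic relatedness provider,
#' returning a fitted model whose [predict.lbd()] method ranks candidate
#' entities for any target. The hybrid score of a pair (A, C) is
#' \deqn{Y = S_{(A,C)}(2\alpha + \beta)
#'       + \sum_i [S_{(A,B_i)} a_i + S_{(B_i,C)} b_i],}
#' the relatedness-weighted direct co-occurrence evidence plus the
#' accumulated evidence of every length-two path through a shared
#' intermediate \eqn{B_i} (Swanson's ABC model).
#'
#' @param records relation records data frame (see [read_relations()]).
#' @param relatedness which relatedness provider to train or load:
#'   `"specialized"` (thesaurus-specialized skip-gram, the default),
#'   `"skipgram"`, `"coals"`, `"ri"` (random indexing), or `"table"`
#'   (precomputed scores; supply `scores`).
#' @param thesaurus optional [thesaurus]; required for
#'   `relatedness = "specialized"`.
#' @param scores data frame of precomputed `(entity, entity, score)`
#'   rows, required for `relatedness = "table"`.
#' @param types entity types retained before building the graph
#'   (`NULL` keeps all).
#' @param seed RNG seed forwarded to stochastic trainers.
#' @param ... further arguments passed to the chosen trainer
#'   ([train_specialized_skipgram()], [train_skipgram()],
#'   [build_coals()], [build_random_indexing()], [table_provider()]).
#' @return An object of class `"lbd"`: list with `graph`, `provider`,
#'   `records_used`, `method`, `call`.
#' @examples
#' sc <- synth_corpus(synth_config(n_abstracts = 40, seed = 7))
#' fit <- lbd(sc$records, relatedness = "table", scores = sc$relatedness)
#' fit
#' head(predict(fit, target = sc$ground_truth$hub), 3)
#' @export
lbd <- function(records,
                relatedness = c("specialized", "skipgram", "coals", "ri",
                                "table"),
                thesaurus = NULL, scores = NULL, types = NULL,
                seed = 1, ...) {
  relatedness <- match.arg(relatedness)
  check_records(records)
  if (!is.null(types)) records <- filter_by_type(records, types)
  graph <- cooccurrence_graph(records)
  provider <- switch(relatedness,
    table = {
      if (is.null(scores)) stop_value("relatedness = \"table\" requires `scores`")
      table_provider(scores, ...)
    },
    specialized = {
      if (is.null(thesaurus)) {
        stop_value("relatedness = \"specialized\" requires a thesaurus")
      }
      train_specialized_skipgram(corpus_from_records(records), thesaurus,
                                 seed = seed, ...)
    },
    skipgram = train_skipgram(corpus_from_records(records), seed = seed, ...),
    coals = build_coals(corpus_from_records(records), ...),
    ri = build_random_indexing(corpus_from_records(records), seed = seed, ...)
  )
  structure(list(graph = graph, provider = provider,
                 n_records = nrow(records), method = relatedness,
                 call = match.call()),
            class = "lbd")
}

#' @export
print.lbd <- function(x, ...) {
  cat("Hybrid LBD ranking model\n")
  cat("  records:   ", x$n_records, "\n", sep = "")
  cat("  entities:  ", length(x$graph$nodes), "\n", sep = "")
  cat("  pairs:     ", nrow(x$graph$edges), "\n", sep = "")
  cat("  relatedness provider: ", x$method, "\n", sep = "")
  invisible(x)
}

#' @export
summary.lbd <- function(object, ...) {
  e <- object$graph$edges
  structure(list(
    n_records = object$n_records,
    n_entities = length(object$graph$nodes),
    n_pairs = nrow(e),
    method = object$method,
    total_mentions = sum(e$total),
    multi_abstract_share = if (nrow(e)) sum(e$alpha) / sum(e$total) else NA_real_,
    top_pairs = head(e[order(-e$total), c("entity_a", "entity_b", "total",
                                          "alpha", "beta")], 5L)),
    class = "summary.lbd")
}

#' @export
print.summary.lbd <- function(x, ...) {
  cat("Hybrid LBD ranking model\n")
  cat(sprintf("  %d records over %d entities (%d co-occurring pairs)\n",
              x$n_records, x$n_entities, x$n_pairs))
  cat(sprintf("  relatedness provider: %s\n", x$method))
  if (!is.na(x$multi_abstract_share)) {
    cat(sprintf("  mentions: %d total, %.1f%% from repeat-mention abstracts (alpha)\n",
                x$total_mentions, 100 * x$multi_abstract_share))
  }
  cat("  most frequent pairs:\n")
  print.data.frame(x$top_pairs, row.names = FALSE)
  invisible(x)
}

#' Rank candidates for a target entity from a fitted model
#'
#' @param object an [lbd] model.
#' @param target target entity label (must be a graph node).
#' @param method `"hybrid"` for the direct + indirect score,
#'   `"cooccurrence"` for the frequency baseline.
#' @param candidates `"all"` or a character vector (see
#'   [rank_candidates()]).
#' @param direct_only restrict candidates to direct neighbors.
#' @param top optional integer; return only the top rows.
#' @param ... unused.
#' @return A `"ranked_list"` data frame.
#' @export
predict.lbd <- function(object, target,
                        method = c("hybrid", "cooccurrence"),
                        candidates = "all", direct_only = FALSE,
                        top = NULL, ...) {
  method <- match.arg(method)
  rl <- if (method == "hybrid") {
    rank_candidates(object$graph, object$provider, target,
                    candidates = candidates, direct_only = direct_only)
  } else {
    rank_by_cooccurrence(object$graph, target, candidates = candidates,
                         direct_only = direct_only)
  }
  if (!is.null(top)) {
    at <- attributes(rl)
    rl <- head(rl, top)
    attr(rl, "target") <- at$target
    attr(rl, "bounds") <- at$bounds
    class(rl) <- c("ranked_list", "data.frame")
  }
  rl
}
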