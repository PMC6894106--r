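#' Read a reference entity set
#'
#' One entity per line (e.g. a curated disease-gene list); labels are
#' normalized with the same rules as the graph so matching is
#' case-insensitive.
#'
#' @param file path to a UTF-8 text file.
#' @return Character vector of unique normalized labels.
#' @export
read_reference <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_value("reference set is empty")
  sort_c(unique(normalize_entity(lines)))
}

#' Top-k% evaluation of a ranked list against a reference set
#'
#' Takes the top `fraction` of the ranked candidates
#' (`k = ceiling(fraction * length)`) and scores the overlap with the
#' reference set. Recall is always `|hits| / |reference|`. Published
#' reports of this protocol are ambiguous about the precision
#' denominator, so it is switchable:
#' \describe{
#'   \item{`"min"` (default)}{`|hits| / min(k, |reference|)` — the
#'     maximum-attainable-hits denominator;}
#'   \item{`"k"`}{classic precision-at-k, `|hits| / k`;}
#'   \item{`"reference"`}{`|hits| / |reference|` (equal to recall).}
#' }
#' F-measure is the harmonic mean `2PR/(P+R)` (0 when both are 0).
#'
#' @param ranked a `"ranked_list"` or a character vector of candidate
#'   labels in rank order.
#' @param reference character vector of reference entities (normalized
#'   on use).
#' @param fraction cutoff fraction in `(0, 1]`.
#' @param precision_denominator one of `"min"`, `"k"`, `"reference"`.
#' @return An object of class `"eval_report"`: list with `precision`,
#'   `recall`, `f_measure`, `k`, `hits`.
#' @export
topk_eval <- function(ranked, reference, fraction = 0.2,
                      precision_denominator = c("min", "k", "reference")) {
  precision_denominator <- match.arg(precision_denominator)
  if (fraction <= 0 || fraction > 1) {
    stop_value("fraction must lie in (0, 1]")
  }
  cand <- if (is.data.frame(ranked)) ranked$candidate else as.character(ranked)
  if (length(cand) == 0L) stop_value("ranked list is empty")
  reference <- unique(normalize_entity(reference))
  k <- as.integer(ceiling(fraction * length(cand)))
  topk <- head(cand, k)
  hits <- intersect(topk, reference)
  denom <- switch(precision_denominator,
                  min = min(k, length(reference)),
                  k = k,
                  reference = length(reference))
  p <- length(hits) / denom
  r <- length(hits) / length(reference)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, f_measure = f, k = k,
                 hits = sort_c(hits),
                 precision_denominator = precision_denominator),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Top-%d evaluation: P = %.4f  R = %.4f  F = %.4f  (%d hits)\n",
              x$k, x$precision, x$recall, x$f_measure, length(x$hits)))
  invisible(x)
}

#' Rank positions of probe entities across methods
#'
#' Looks up the 1-based rank of each probe entity in each method's
#' ranked list. Probes missing from a method's candidate universe are
#' reported as absent (`NA` rank), never as rank 0.
#'
#' @param rankings named list of `"ranked_list"` objects, one per
#'   method.
#' @param probes character vector of entities to look up.
#' @return Data frame with columns `entity`, `method`, `rank` (integer,
#'   `NA` when absent), `absent` (logical), sorted by entity then
#'   method.
#' @export
rank_positions <- function(rankings, probes) {
  stopifnot(is.list(rankings), length(rankings) > 0L,
            !is.null(names(rankings)), all(nzchar(names(rankings))))
  probes <- unique(normalize_entity(probes))
  out <- expand.grid(entity = probes, method = names(rankings),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$rank <- NA_integer_
  for (m in names(rankings)) {
    rl <- rankings[[m]]
    cand <- if (is.data.frame(rl)) rl$candidate else as.character(rl)
    sel <- out$method == m
    out$rank[sel] <- match(out$entity[sel], cand)
  }
  out$absent <- is.na(out$rank)
  out <- out[order(out$entity, out$method, method = "radix"), ]
  rownames(out) <- NULL
  out
}
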