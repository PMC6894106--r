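#' Direct score of an entity pair
#'
#' The direct component of the hybrid score,
#' \deqn{Y_{direct} = S_{(A,C)} (2\alpha + \beta),}
#' where \eqn{S_{(A,C)}} is the semantic relatedness of the pair,
#' \eqn{\alpha} is the number of mentions contributed by abstracts where
#' the pair co-occurs more than once, and \eqn{\beta} the number of
#' abstracts with exactly one mention. Repeated within-abstract
#' co-occurrence is thus rewarded with double weight.
#'
#' @param s semantic relatedness \eqn{S_{(A,C)}}.
#' @param alpha,beta non-negative co-occurrence counts (see
#'   [cooccurrence_graph()]).
#' @return Numeric score.
#' @examples
#' direct_score(0.427029, 4123, 1003)  # 3949.59
#' @export
direct_score <- function(s, alpha, beta) {
  if (any(alpha < 0) || any(beta < 0)) {
    stop_value("alpha and beta must be non-negative")
  }
  s * (2 * alpha + beta)
}

#' Indirect path score through one intermediate
#'
#' For an intermediate entity B linking A and C, the path score is
#' \deqn{X = S_{(A,B)} a + S_{(B,C)} b,}
#' the frequency-weighted average relatedness of the two legs
#' ([indirect_relatedness()]) multiplied by the total link count
#' \eqn{a + b}. Here \eqn{a} and \eqn{b} are the direct co-occurrence
#' frequencies of (A, B) and (B, C).
#'
#' @param s_ab,s_bc leg relatednesses \eqn{S_{(A,B)}}, \eqn{S_{(B,C)}}.
#' @param a,b leg co-occurrence frequencies, both >= 1.
#' @return Numeric path score X.
#' @examples
#' path_score(0.434575, 1750, 0.712967, 1562)  # 1874.16
#' @export
path_score <- function(s_ab, a, s_bc, b) {
  if (any(a < 1) || any(b < 1)) {
    stop_value("leg co-occurrence counts must be positive")
  }
  s_ab * a + s_bc * b
}

#' Weighted-average indirect relatedness of a length-two path
#'
#' \deqn{S_{indirect(A,C)} = [S_{(A,B)} a + S_{(B,C)} b] / (a + b),}
#' a convex combination of the two leg relatednesses, so the result
#' always lies between them. Equals [path_score()] divided by the link
#' count \eqn{a + b}.
#'
#' @inheritParams path_score
#' @return Numeric relatedness.
#' @export
indirect_relatedness <- function(s_ab, a, s_bc, b) {
  if (any(a + b <= 0)) stop_value("a + b must be positive")
  (s_ab * a + s_bc * b) / (a + b)
}

#' Indirect score of an entity pair
#'
#' Accumulates the path scores of every length-two path A--B--C through
#' the shared intermediates of the pair:
#' \deqn{Y_{indirect} = \sum_{i=1}^{n} X_i
#'   = \sum_{i=1}^{n} [S_{(A,B_i)} a_{(A,B_i)} + S_{(B_i,C)} b_{(B_i,C)}],}
#' where \eqn{n} is the number of intermediates. Path weights are the
#' legs' total co-occurrence counts.
#'
#' @param graph a `"cooc_graph"`.
#' @param provider a relatedness provider.
#' @param a_entity,c_entity entity labels; both must be graph nodes.
#' @return A list with `y_indirect` (numeric) and `paths`, a data frame
#'   with one row per intermediate: `intermediate`, `s_ab`, `a`, `s_bc`,
#'   `b`, `x`, sorted by intermediate label.
#' @export
indirect_score <- function(graph, provider, a_entity, c_entity) {
  a_ent <- check_node(graph, a_entity)
  c_ent <- check_node(graph, c_entity)
  mids <- intermediates(graph, a_ent, c_ent)
  if (length(mids) == 0L) {
    return(list(y_indirect = 0,
                paths = data.frame(intermediate = character(0),
                                   s_ab = numeric(0), a = integer(0),
                                   s_bc = numeric(0), b = integer(0),
                                   x = numeric(0))))
  }
  a_cnt <- vapply(mids, function(b) edge_total(graph, a_ent, b), 0L)
  b_cnt <- vapply(mids, function(b) edge_total(graph, b, c_ent), 0L)
  s_ab <- relatedness(provider, rep(a_ent, length(mids)), mids)
  s_bc <- relatedness(provider, mids, rep(c_ent, length(mids)))
  x <- path_score(s_ab, a_cnt, s_bc, b_cnt)
  paths <- data.frame(intermediate = mids, s_ab = s_ab, a = a_cnt,
                      s_bc = s_bc, b = b_cnt, x = x,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(y_indirect = sum(x), paths = paths)
}

#' Hybrid (direct + indirect) score of an entity pair
#'
#' \deqn{Y = Y_{direct} + Y_{indirect}.}
#' The direct component uses the pair's own \eqn{\alpha}, \eqn{\beta}
#' from the co-occurrence graph; a pair that never co-occurs directly
#' has \eqn{Y_{direct} = 0} and can still score through its
#' intermediates, which is what lets purely hidden relations surface.
#'
#' @inheritParams indirect_score
#' @return One-row data frame with `target`, `candidate`, `y_direct`,
#'   `y_indirect`, `y_total`, `n_intermediates`.
#' @export
total_score <- function(graph, provider, a_entity, c_entity) {
  a_ent <- check_node(graph, a_entity)
  c_ent <- check_node(graph, c_entity)
  st <- pair_stats(graph, a_ent, c_ent)
  yd <- if (is.null(st)) 0 else {
    direct_score(relatedness(provider, a_ent, c_ent), st$alpha, st$beta)
  }
  ind <- indirect_score(graph, provider, a_ent, c_ent)
  data.frame(target = a_ent, candidate = c_ent,
             y_direct = yd, y_indirect = ind$y_indirect,
             y_total = yd + ind$y_indirect,
             n_intermediates = nrow(ind$paths),
             stringsAsFactors = FALSE)
}

#' Min-max normalization of a score vector
#'
#' Rescales scores to `[0, 1]` via \eqn{(y - min)/(max - min)}. In the
#' degenerate all-equal case every score maps to 1.
#'
#' @param y numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(y) {
  if (length(y) == 0L) return(numeric(0))
  lo <- min(y); hi <- max(y)
  if (hi > lo) (y - lo) / (hi - lo) else rep(1, length(y))
}

#' Rank candidate entities for a target
#'
#' Scores every candidate against the target with [total_score()], sorts
#' descending by the hybrid score `y_total` (ties broken
#' lexicographically by candidate label for determinism), and attaches
#' min-max-normalized ranking scores.
#'
#' The default candidate universe contains every entity sharing a direct
#' edge or at least one intermediate with the target (excluding the
#' target itself); `direct_only = TRUE` restricts it to direct
#' co-occurrence neighbors.
#'
#' @param graph a `"cooc_graph"`.
#' @param provider a relatedness provider.
#' @param target entity label; must be a graph node.
#' @param candidates `"all"` for the default universe, or a character
#'   vector of candidate labels.
#' @param direct_only restrict the default universe to direct neighbors.
#' @return A data frame of class `"ranked_list"` with columns `rank`,
#'   `candidate`, `y_direct`, `y_indirect`, `y_total`,
#'   `n_intermediates`, `normalized`; attributes `target`, `bounds`.
#' @export
rank_candidates <- function(graph, provider, target, candidates = "all",
                            direct_only = FALSE) {
  target <- check_node(graph, target)
  cand <- resolve_candidates(graph, target, candidates, direct_only)
  rows <- lapply(cand, function(cc) total_score(graph, provider, target, cc))
  finish_ranking(rows, target)
}

#' Rank candidates by raw co-occurrence frequency
#'
#' Baseline ranking: candidates are scored by the total co-occurrence
#' count of their edge with the target (0 when no direct edge), with the
#' same candidate universe, tie-breaking and min-max normalization as
#' [rank_candidates()].
#'
#' @inheritParams rank_candidates
#' @return A `"ranked_list"` data frame (the `y_*` columns carry the
#'   co-occurrence totals; `y_direct` and `n_intermediates` are 0).
#' @export
rank_by_cooccurrence <- function(graph, target, candidates = "all",
                                 direct_only = FALSE) {
  target <- check_node(graph, target)
  cand <- resolve_candidates(graph, target, candidates, direct_only)
  rows <- lapply(cand, function(cc) {
    tot <- edge_total(graph, target, cc)
    data.frame(target = target, candidate = cc, y_direct = 0,
               y_indirect = 0, y_total = as.numeric(tot),
               n_intermediates = 0L, stringsAsFactors = FALSE)
  })
  finish_ranking(rows, target)
}

resolve_candidates <- function(graph, target, candidates, direct_only) {
  if (identical(candidates, "all")) {
    direct <- neighbors(graph, target)
    if (direct_only) return(direct)
    two_hop <- unique(unlist(lapply(direct, function(b) neighbors(graph, b)),
                             use.names = FALSE))
    sort_c(setdiff(union(direct, two_hop), target))
  } else {
    sort_c(unique(normalize_entity(candidates)))
  }
}

finish_ranking <- function(rows, target) {
  if (length(rows) == 0L) {
    out <- data.frame(rank = integer(0), candidate = character(0),
                      y_direct = numeric(0), y_indirect = numeric(0),
                      y_total = numeric(0), n_intermediates = integer(0),
                      normalized = numeric(0))
    return(structure(out, target = target, bounds = c(NA_real_, NA_real_),
                     class = c("ranked_list", "data.frame")))
  }
  df <- do.call(rbind, rows)
  ord <- order(-df$y_total, df$candidate, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$normalized <- minmax_normalize(df$y_total)
  out <- data.frame(rank = seq_len(nrow(df)), candidate = df$candidate,
                    y_direct = df$y_direct, y_indirect = df$y_indirect,
                    y_total = df$y_total,
                    n_intermediates = df$n_intermediates,
                    normalized = df$normalized,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, target = target,
            bounds = c(min(df$y_total), max(df$y_total)),
            class = c("ranked_list", "data.frame"))
}

#' @export
print.ranked_list <- function(x, n = 10L, ...) {
  cat("Ranked candidates for:", attr(x, "target"),
      sprintf("(%d scored)\n", nrow(x)))
  print.data.frame(head(as.data.frame(x), n), digits = 6, row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' @export
plot.ranked_list <- function(x, n = 20L, ...) {
  top <- head(x, n)
  hb <- rbind(direct = top$y_direct, indirect = top$y_indirect)
  colnames(hb) <- top$candidate
  op <- par(mar = c(9, 4, 2, 1))
  on.exit(par(op))
  barplot(hb, las = 2, cex.names = 0.75,
          main = paste("Hybrid score decomposition:", attr(x, "target")),
          ylab = "score", legend.text = TRUE, ...)
  invisible(x)
}

#' Write a ranked list to a tab-separated file
#'
#' Columns: `rank`, `candidate`, `y_direct`, `y_indirect`, `y_total`,
#' `n_intermediates`, `normalized`.
#'
#' @param ranked a `"ranked_list"`.
#' @param file path.
#' @export
write_ranked <- function(ranked, file) {
  write.table(as.data.frame(ranked), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
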