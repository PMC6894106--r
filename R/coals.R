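#' Build a COALS relatedness provider
#'
#' Correlated Occurrence Analog to Lexical Semantics: a count-based
#' distributional model. The pipeline is
#' \enumerate{
#'   \item weighted co-occurrence counts with a ramped window — a
#'     neighbor at offset \eqn{o \le window} contributes weight
#'     \eqn{window - o + 1} (weights 4, 3, 2, 1 for the default window
#'     of 4);
#'   \item the column set is restricted to the `max_columns` most
#'     frequent tokens (ties broken lexicographically);
#'   \item each cell is replaced by the pairwise correlation statistic
#'     of its row and column margins,
#'     \eqn{(T w_{ij} - r_i c_j) / \sqrt{r_i (T - r_i) c_j (T - c_j)}};
#'   \item negative correlations are set to 0;
#'   \item positive cells are square-rooted.
#' }
#' Similarity between two tokens is the Pearson correlation of their
#' transformed row vectors; a token's similarity to itself is 1.
#'
#' @param corpus named list of token vectors.
#' @param window ramp width of the weighting window.
#' @param max_columns number of most-frequent tokens kept as feature
#'   columns (>= 2).
#' @param default score for uncovered or degenerate pairs.
#' @return An object of class `"coals_provider"`.
#' @export
build_coals <- function(corpus, window = 4, max_columns = 1000, default = 0) {
  if (max_columns < 2) stop_value("max_columns must be >= 2")
  stopifnot(window >= 1)
  vc <- corpus_vocab(corpus)
  vocab <- vc$vocab
  nv <- length(vocab)
  nc <- min(max_columns, nv)
  cols <- vocab[seq_len(nc)]  # vocab is frequency-ordered
  M <- matrix(0, nrow = nv, ncol = nc, dimnames = list(vocab, cols))
  for (doc in corpus) {
    ids <- match(doc, vocab)
    n <- length(ids)
    if (n < 2L) next
    for (off in seq_len(min(window, n - 1L))) {
      w <- window - off + 1
      i1 <- ids[seq_len(n - off)]
      i2 <- ids[seq.int(off + 1L, n)]
      # symmetric accumulation, columns restricted to the top-nc tokens
      for (k in seq_along(i1)) {
        if (i2[k] <= nc) M[i1[k], i2[k]] <- M[i1[k], i2[k]] + w
        if (i1[k] <= nc) M[i2[k], i1[k]] <- M[i2[k], i1[k]] + w
      }
    }
  }
  M <- coals_transform(M)
  structure(list(mat = M, default = default,
                 meta = list(window = window, max_columns = max_columns)),
            class = "coals_provider")
}

# Correlation transform + negative truncation + square root (steps 3-5).
coals_transform <- function(M) {
  total <- sum(M)
  if (total == 0) return(M)
  r <- rowSums(M)
  cl <- colSums(M)
  num <- total * M - outer(r, cl)
  den <- sqrt(outer(r * (total - r), cl * (total - cl)))
  X <- ifelse(den > 0, num / den, 0)
  X[X < 0] <- 0
  sqrt(X)
}

#' @export
relatedness.coals_provider <- function(provider, x, y) {
  x <- normalize_entity(x); y <- normalize_entity(y)
  M <- provider$mat
  ix <- match(x, rownames(M)); iy <- match(y, rownames(M))
  out <- numeric(length(ix))
  for (k in seq_along(ix)) {
    if (is.na(ix[k]) || is.na(iy[k])) {
      out[k] <- provider$default
    } else if (ix[k] == iy[k]) {
      out[k] <- 1
    } else {
      rx <- M[ix[k], ]; ry <- M[iy[k], ]
      if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
        out[k] <- provider$default
      } else {
        out[k] <- stats::cor(rx, ry)
      }
    }
  }
  out
}

#' @export
coverage.coals_provider <- function(provider, entity) {
  normalize_entity(entity) %in% rownames(provider$mat)
}

#' @export
print.coals_provider <- function(x, ...) {
  cat(sprintf("COALS provider: %d tokens x %d feature columns (window %d)\n",
              nrow(x$mat), ncol(x$mat), x$meta$window))
  invisible(x)
}
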