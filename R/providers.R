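#' Semantic relatedness of an entity pair
#'
#' Generic contract shared by every relatedness provider: a symmetric
#' score \eqn{S(x, y)} with \eqn{S(x, x) = 1} for any covered entity, and
#' \eqn{|S| \le 1} for embedding-backed providers (cosine range). Pairs
#' with at least one uncovered entity return the provider's configured
#' `default` (0 unless set otherwise), which drops their contribution
#' from path scores rather than inventing relatedness.
#'
#' @param provider a relatedness provider ([table_provider()],
#'   [train_skipgram()], [train_specialized_skipgram()], [build_coals()],
#'   [build_random_indexing()]).
#' @param x,y entity labels (normalized on lookup). Vectorized over pairs.
#' @return Numeric vector of scores.
#' @export
relatedness <- function(provider, x, y) UseMethod("relatedness")

#' Is an entity covered by a provider?
#'
#' @inheritParams relatedness
#' @param entity entity label(s).
#' @return Logical vector.
#' @export
coverage <- function(provider, entity) UseMethod("coverage")

#' Relatedness provider backed by a precomputed score table
#'
#' Wraps a table of `(entity, entity, score)` rows as a symmetric lookup:
#' `S(x, y) = S(y, x)`, `S(x, x) = 1` implicitly for any entity appearing
#' in the table, and uncovered pairs return `default`. Conflicting
#' duplicate pairs (same pair, different score) are a load error;
#' consistent duplicates are tolerated.
#'
#' @param scores data frame with columns `entity_a`, `entity_b`, `s` (or
#'   any three columns in that order).
#' @param default score returned for uncovered pairs.
#' @return An object of class `"relatedness_table"`.
#' @examples
#' tp <- table_provider(data.frame(a = "alzheimer's disease",
#'                                 b = "app", s = 0.427029))
#' relatedness(tp, "APP", "Alzheimer's disease")
#' @export
table_provider <- function(scores, default = 0) {
  stopifnot(is.data.frame(scores), ncol(scores) >= 3L)
  a <- normalize_entity(as.character(scores[[1L]]))
  b <- normalize_entity(as.character(scores[[2L]]))
  s <- as.numeric(scores[[3L]])
  if (anyNA(s)) stop_value("non-numeric relatedness score in table")
  key <- pair_key(a, b)$key
  first <- !duplicated(key)
  for (k in unique(key[duplicated(key)])) {
    vals <- unique(s[key == k])
    if (length(vals) > 1L) {
      stop_value("conflicting duplicate scores for pair: ",
                 gsub("\t", " / ", k))
    }
  }
  env <- new.env(parent = emptyenv(), size = max(1L, length(key)))
  for (i in which(first)) assign(key[i], s[i], envir = env)
  structure(list(scores = env,
                 entities = sort_c(unique(c(a, b))),
                 default = default),
            class = "relatedness_table")
}

#' @export
relatedness.relatedness_table <- function(provider, x, y) {
  x <- normalize_entity(x); y <- normalize_entity(y)
  key <- pair_key(x, y)$key
  out <- numeric(length(key))
  for (i in seq_along(key)) {
    if (x[i] == y[i]) {
      out[i] <- if (x[i] %in% provider$entities) 1 else provider$default
    } else {
      out[i] <- get0(key[i], envir = provider$scores,
                     ifnotfound = provider$default)
    }
  }
  out
}

#' @export
coverage.relatedness_table <- function(provider, entity) {
  normalize_entity(entity) %in% provider$entities
}

#' @export
print.relatedness_table <- function(x, ...) {
  cat("Relatedness table:", length(ls(x$scores)), "pairs,",
      length(x$entities), "entities (default", x$default, ")\n")
  invisible(x)
}

#' Read and write precomputed relatedness tables
#'
#' Tab-separated `entityA <TAB> entityB <TAB> score` with a header line.
#'
#' @param file path to a UTF-8 text file.
#' @param default default score for uncovered pairs.
#' @export
read_relatedness_table <- function(file, default = 0) {
  df <- read.table(file, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  table_provider(df, default = default)
}

#' @rdname read_relatedness_table
#' @param scores data frame with columns `entity_a`, `entity_b`, `s`.
#' @export
write_relatedness_table <- function(scores, file) {
  stopifnot(is.data.frame(scores), ncol(scores) >= 3L)
  out <- scores[1:3]
  names(out) <- c("entity_a", "entity_b", "s")
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# ---- embedding-backed providers -------------------------------------------

new_embedding <- function(vectors, meta, default = 0) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors))) {
    stop_value("duplicate tokens in embedding vocabulary")
  }
  norms <- sqrt(rowSums(vectors^2))
  structure(list(vectors = vectors, norms = norms, meta = meta,
                 default = default),
            class = "embedding")
}

#' @export
relatedness.embedding <- function(provider, x, y) {
  x <- normalize_entity(x); y <- normalize_entity(y)
  V <- provider$vectors
  ix <- match(x, rownames(V)); iy <- match(y, rownames(V))
  out <- numeric(length(ix))
  for (k in seq_along(ix)) {
    if (is.na(ix[k]) || is.na(iy[k])) {
      out[k] <- provider$default
    } else if (ix[k] == iy[k]) {
      out[k] <- 1
    } else {
      nx <- provider$norms[ix[k]]; ny <- provider$norms[iy[k]]
      out[k] <- if (nx == 0 || ny == 0) provider$default
                else sum(V[ix[k], ] * V[iy[k], ]) / (nx * ny)
    }
  }
  out
}

#' @export
coverage.embedding <- function(provider, entity) {
  normalize_entity(entity) %in% rownames(provider$vectors)
}

#' @export
print.embedding <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Embedding model (%s): %d tokens x %d dims\n",
              m$method %||% "?", nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Persist and restore embedding models
#'
#' Plain-text format: a header line `#method <TAB> dim <TAB> window <TAB>
#' seed`, then one `token <TAB> v1 ... vd` line per token.
#'
#' @param model an `"embedding"` provider.
#' @param file path.
#' @export
write_embedding <- function(model, file) {
  stopifnot(inherits(model, "embedding"))
  m <- model$meta
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#%s\t%d\t%d\t%d", m$method %||% "embedding",
                     ncol(model$vectors), as.integer(m$window %||% 0),
                     as.integer(m$seed %||% 0)), con)
  V <- model$vectors
  writeLines(paste(rownames(V),
                   apply(V, 1L, function(r)
                     paste(formatC(r, format = "g", digits = 17),
                           collapse = "\t")),
                   sep = "\t"), con)
  invisible(file)
}

#' @rdname write_embedding
#' @param default default score for uncovered pairs.
#' @export
read_embedding <- function(file, default = 0) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  hdr <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  tokens <- vapply(body, `[`, "", 1L)
  V <- do.call(rbind, lapply(body, function(p) as.numeric(p[-1L])))
  rownames(V) <- tokens
  new_embedding(V, meta = list(method = hdr[1L],
                               window = as.integer(hdr[3L]),
                               seed = as.integer(hdr[4L])),
                default = default)
}
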