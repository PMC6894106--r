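#' Build a co-occurrence graph from relation records
#'
#' Aggregates sentence-level relation records into per-pair co-occurrence
#' statistics. For each unordered entity pair the within-abstract mention
#' count \eqn{c_d} is computed per distinct PMID; the pair's edge then
#' carries
#' \describe{
#'   \item{`total`}{\eqn{f = \sum_d c_d}, the direct co-occurrence
#'     frequency used as the path weight in indirect scoring;}
#'   \item{`alpha`}{\eqn{\alpha = \sum_{c_d \ge 2} c_d}, mentions
#'     contributed by abstracts where the pair repeats ("sum_same");}
#'   \item{`beta`}{\eqn{\beta = \#\{d : c_d = 1\}}, the number of
#'     abstracts with a single mention ("sum_different").}
#' }
#' By construction \eqn{\alpha + \beta = f} on every edge. Each record
#' line counts as one mention, so the same pair extracted twice from one
#' abstract with different relation labels contributes 2 to that
#' abstract's count.
#'
#' @param records relation records data frame (see [parse_relations()]).
#' @return An object of class `"cooc_graph"`: a list with `nodes` (sorted
#'   entity labels), `edges` (data frame with `entity_a`, `entity_b` in
#'   canonical lexicographic order, `total`, `alpha`, `beta`,
#'   `abstracts_multi`, `abstracts_single`), and an adjacency index.
#' @examples
#' recs <- parse_relations(c(
#'   "1 | 1 | x | GENE | y | GENE | CO-OCCUR |",
#'   "1 | 2 | x | GENE | y | GENE | RESULT_OF |",
#'   "2 | 1 | x | GENE | y | GENE | CO-OCCUR |"))
#' g <- cooccurrence_graph(recs)
#' g$edges  # total 3, alpha 2, beta 1
#' @export
cooccurrence_graph <- function(records) {
  check_records(records)
  if (nrow(records) == 0L) {
    return(new_cooc_graph(empty_edges()))
  }
  pk <- pair_key(records$entity_a, records$entity_b)
  # within-abstract mention counts c_d per (pair, pmid)
  cell <- paste(pk$key, records$pmid, sep = "\r")
  c_d <- vapply(split(seq_along(cell), cell), length, 1L)
  cell_pair <- sub("\r.*$", "", names(c_d))
  agg <- function(f) vapply(split(c_d, cell_pair), f, 1)
  total <- agg(sum)
  alpha <- agg(function(v) sum(v[v >= 2L]))
  beta <- agg(function(v) sum(v == 1L))
  multi <- agg(function(v) sum(v >= 2L))
  keys <- names(total)
  ab <- strsplit(keys, "\t", fixed = TRUE)
  edges <- data.frame(
    entity_a = vapply(ab, `[`, "", 1L),
    entity_b = vapply(ab, `[`, "", 2L),
    total = as.integer(total),
    alpha = as.integer(alpha),
    beta = as.integer(beta),
    abstracts_multi = as.integer(multi),
    abstracts_single = as.integer(beta),
    stringsAsFactors = FALSE
  )
  edges <- edges[order_c(paste(edges$entity_a, edges$entity_b, sep = "\t")), ]
  rownames(edges) <- NULL
  new_cooc_graph(edges)
}

empty_edges <- function() {
  data.frame(entity_a = character(0), entity_b = character(0),
             total = integer(0), alpha = integer(0), beta = integer(0),
             abstracts_multi = integer(0), abstracts_single = integer(0),
             stringsAsFactors = FALSE)
}

new_cooc_graph <- function(edges) {
  nodes <- sort_c(unique(c(edges$entity_a, edges$entity_b)))
  key <- paste(edges$entity_a, edges$entity_b, sep = "\t")
  index <- new.env(parent = emptyenv(), size = max(1L, nrow(edges)))
  for (i in seq_len(nrow(edges))) assign(key[i], i, envir = index)
  adj <- new.env(parent = emptyenv(), size = max(1L, length(nodes)))
  nb <- split(c(edges$entity_b, edges$entity_a),
              c(edges$entity_a, edges$entity_b))
  for (nm in names(nb)) assign(nm, sort_c(unique(nb[[nm]])), envir = adj)
  structure(list(nodes = nodes, edges = edges,
                 .index = index, .adj = adj),
            class = "cooc_graph")
}

#' @export
print.cooc_graph <- function(x, ...) {
  cat("Co-occurrence graph:", length(x$nodes), "entities,",
      nrow(x$edges), "pairs,", sum(x$edges$total), "mentions\n")
  invisible(x)
}

#' Neighbors of an entity in a co-occurrence graph
#'
#' @param graph a `"cooc_graph"`.
#' @param entity entity label (normalized on lookup).
#' @return Sorted character vector of co-occurring entities.
#' @export
neighbors <- function(graph, entity) {
  entity <- check_node(graph, entity)
  get0(entity, envir = graph$.adj, ifnotfound = character(0))
}

#' Intermediate entities shared by a pair
#'
#' Returns the set of entities B that co-occur with both `a_entity` (A)
#' and `c_entity` (C), excluding A and C themselves. These are the
#' intermediates of the ABC model: each one supports an indirect
#' length-two path A--B--C.
#'
#' @param graph a `"cooc_graph"`.
#' @param a_entity,c_entity entity labels; both must be graph nodes.
#' @return Sorted character vector of intermediates (possibly empty).
#' @export
intermediates <- function(graph, a_entity, c_entity) {
  a <- check_node(graph, a_entity)
  c_ <- check_node(graph, c_entity)
  setdiff(intersect(neighbors(graph, a), neighbors(graph, c_)), c(a, c_))
}

#' Co-occurrence statistics of one pair
#'
#' Order-insensitive edge lookup: `pair_stats(g, y, x)` equals
#' `pair_stats(g, x, y)`. Returns `NULL` when the pair never co-occurs.
#'
#' @param graph a `"cooc_graph"`.
#' @param a_entity,c_entity entity labels.
#' @return One-row data frame of edge statistics, or `NULL`.
#' @export
pair_stats <- function(graph, a_entity, c_entity) {
  stopifnot(inherits(graph, "cooc_graph"))
  a <- normalize_entity(a_entity)
  b <- normalize_entity(c_entity)
  key <- pair_key(a, b)$key
  i <- get0(key, envir = graph$.index, ifnotfound = NULL)
  if (is.null(i)) return(NULL)
  graph$edges[i, , drop = FALSE]
}

# Fast internal lookup of an edge total (0 when absent).
edge_total <- function(graph, a, b) {
  i <- get0(pair_key(a, b)$key, envir = graph$.index, ifnotfound = NULL)
  if (is.null(i)) 0L else graph$edges$total[i]
}

check_node <- function(graph, entity) {
  stopifnot(inherits(graph, "cooc_graph"))
  e <- normalize_entity(entity)
  if (!(e %in% graph$nodes)) stop_value("unknown entity: ", e)
  e
}

#' Read and write co-occurrence graph edge lists
#'
#' Tab-separated edge list with header
#' `entity_a entity_b total alpha beta`. Per-abstract breakdowns
#' (`abstracts_multi`) are not part of the interchange format; on read,
#' `abstracts_single` is recovered as `beta` and `abstracts_multi` is `NA`.
#'
#' @param graph a `"cooc_graph"`.
#' @param file path to a UTF-8 text file.
#' @return [read_cooccurrence()] returns a `"cooc_graph"`;
#'   [write_cooccurrence()] returns `file` invisibly.
#' @export
write_cooccurrence <- function(graph, file) {
  stopifnot(inherits(graph, "cooc_graph"))
  write.table(graph$edges[c("entity_a", "entity_b", "total", "alpha", "beta")],
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cooccurrence
#' @export
read_cooccurrence <- function(file) {
  edges <- read.table(file, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "",
                      colClasses = c("character", "character",
                                     "integer", "integer", "integer"))
  if (any(edges$alpha + edges$beta != edges$total)) {
    stop_value("corrupt edge list: alpha + beta != total")
  }
  edges$abstracts_multi <- NA_integer_
  edges$abstracts_single <- edges$beta
  new_cooc_graph(edges)
}
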