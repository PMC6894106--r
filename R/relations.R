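#' Normalize an entity label
#'
#' Canonicalizes raw entity strings so that surface variants ("APOE",
#' " apoe ") map to a single graph node: leading/trailing whitespace is
#' trimmed, the label is case-folded to lower case, and internal runs of
#' whitespace are collapsed to single spaces. When a [thesaurus] is
#' supplied and the folded label belongs to a synonym group, the group's
#' lexicographically smallest member is returned as the canonical head, so
#' all synonyms share one node.
#'
#' Normalization is idempotent: `normalize_entity(normalize_entity(x))`
#' equals `normalize_entity(x)`.
#'
#' @param label character vector of raw entity labels.
#' @param thesaurus optional [thesaurus] object used for synonym
#'   canonicalization.
#' @return character vector of normalized labels.
#' @examples
#' normalize_entity("  APOE ")
#' th <- thesaurus(list(c("APP", "amyloid precursor protein")))
#' normalize_entity("APP", th)
#' @export
normalize_entity <- function(label, thesaurus = NULL) {
  if (length(label) == 0L) return(character(0))
  x <- tolower(trimws(label))
  x <- gsub("[[:space:]]+", " ", x)
  if (any(!nzchar(x))) {
    stop_value("entity label is empty after trimming")
  }
  if (!is.null(thesaurus)) {
    stopifnot(inherits(thesaurus, "thesaurus"))
    hit <- match(x, names(thesaurus$heads))
    x <- ifelse(is.na(hit), x, unname(thesaurus$heads[hit]))
  }
  x
}

#' Synonym/association thesaurus
#'
#' A thesaurus is a collection of synonym (or association) groups, each a
#' set of at least two entity labels, emulating resources such as gene
#' synonym lists. Membership lookup is case-insensitive: all members are
#' normalized with [normalize_entity()] (without thesaurus recursion) on
#' construction. Each group's canonical head is its lexicographically
#' smallest member; [normalize_entity()] maps every member to that head.
#'
#' @param groups list of character vectors, each with >= 2 distinct labels
#'   after normalization.
#' @param provenance free-form source tag.
#' @return An object of class `"thesaurus"` with elements `groups`
#'   (normalized, sorted members) and `heads` (named lookup member -> head).
#' @examples
#' th <- thesaurus(list(c("APP", "amyloid precursor protein")))
#' th$heads[["app"]]
#' @export
thesaurus <- function(groups, provenance = "") {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) {
    g <- unique(normalize_entity(as.character(g)))
    if (length(g) < 2L) {
      stop_value("thesaurus group has fewer than 2 distinct members")
    }
    sort_c(g)
  })
  heads <- character(0)
  for (g in groups) {
    heads[g] <- g[1L]  # lexicographic head: first of the sorted group
  }
  structure(list(groups = groups, heads = heads, provenance = provenance),
            class = "thesaurus")
}

#' @export
print.thesaurus <- function(x, ...) {
  cat("Thesaurus:", length(x$groups), "groups,",
      length(x$heads), "members")
  if (nzchar(x$provenance)) cat(" (", x$provenance, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Read and write a thesaurus file
#'
#' One group per line, members separated by tabs.
#'
#' @param file path to a UTF-8 text file.
#' @param provenance source tag attached to the result.
#' @return [read_thesaurus()] returns a [thesaurus] object;
#'   [write_thesaurus()] returns `file` invisibly.
#' @export
read_thesaurus <- function(file, provenance = file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  thesaurus(strsplit(lines, "\t", fixed = TRUE), provenance = provenance)
}

#' @rdname read_thesaurus
#' @param x a [thesaurus] object.
#' @export
write_thesaurus <- function(x, file) {
  stopifnot(inherits(x, "thesaurus"))
  writeLines(vapply(x$groups, paste, "", collapse = "\t"), file)
  invisible(file)
}

#' Parse pipe-delimited entity-relation records
#'
#' Reads the 7-field extraction format
#' `pmid | sentence location | entity1 | type | entity2 | type | relations`
#' as emitted by entity/relation extraction pipelines. PMIDs may carry
#' thousands separators (`"19,395,124"`), which are stripped. A trailing
#' empty 8th field caused by a terminal `|` is tolerated. Entity labels are
#' normalized with [normalize_entity()]; records whose two entities
#' coincide after normalization are malformed (a co-occurrence pair needs
#' two distinct entities).
#'
#' In strict mode any malformed line raises an error identifying the line;
#' otherwise malformed lines are skipped and counted in the `"n_skipped"`
#' attribute of the result.
#'
#' @param lines character vector, one record per element.
#' @param strict logical; error on malformed lines instead of skipping.
#' @param thesaurus optional [thesaurus] for synonym canonicalization.
#' @return A data frame with columns `pmid` (integer), `sentence_index`
#'   (integer), `entity_a`, `type_a`, `entity_b`, `type_b`, `relation`,
#'   plus attribute `n_skipped`.
#' @examples
#' parse_relations("19,395,124 | 8 | MCI | DISEASE | depression | DISEASE | CO-OCCUR |")
#' @export
parse_relations <- function(lines, strict = FALSE, thesaurus = NULL) {
  lines <- lines[nzchar(trimws(lines))]
  n_skipped <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- parse_relation_line(lines[[i]], thesaurus)
    if (is.character(rec)) {  # error message
      if (strict) stop_value("line ", i, ": ", rec, ": ", lines[[i]])
      n_skipped <- n_skipped + 1L
    } else {
      rows[[i]] <- rec
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(pmid = integer(0), sentence_index = integer(0),
               entity_a = character(0), type_a = character(0),
               entity_b = character(0), type_b = character(0),
               relation = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

# One line -> one-row data.frame, or a character error message.
parse_relation_line <- function(line, thesaurus = NULL) {
  parts <- strsplit(line, "|", fixed = TRUE)[[1L]]
  if (length(parts) == 8L && !nzchar(trimws(parts[8L]))) {
    parts <- parts[1:7]  # tolerate terminal "|"
  }
  if (length(parts) != 7L) {
    return(sprintf("expected 7 pipe-delimited fields, found %d",
                   length(parts)))
  }
  parts <- trimws(parts)
  pmid_raw <- gsub(",", "", parts[1L], fixed = TRUE)
  if (!grepl("^[0-9]+$", pmid_raw)) return("non-numeric pmid")
  pmid <- suppressWarnings(as.integer(pmid_raw))
  if (is.na(pmid) || pmid <= 0L) return("pmid must be a positive integer")
  if (!grepl("^[0-9]+$", parts[2L])) return("non-numeric sentence location")
  sidx <- as.integer(parts[2L])
  ta <- toupper(parts[4L]); tb <- toupper(parts[6L])
  if (!(ta %in% ENTITY_TYPES) || !(tb %in% ENTITY_TYPES)) {
    return("unknown entity type tag")
  }
  if (!nzchar(parts[3L]) || !nzchar(parts[5L])) return("empty entity label")
  ea <- normalize_entity(parts[3L], thesaurus)
  eb <- normalize_entity(parts[5L], thesaurus)
  if (ea == eb) return("entities coincide after normalization")
  data.frame(pmid = pmid, sentence_index = sidx,
             entity_a = ea, type_a = ta, entity_b = eb, type_b = tb,
             relation = parts[7L], stringsAsFactors = FALSE)
}

#' @rdname parse_relations
#' @param file path to a UTF-8 text file, one record per line.
#' @export
read_relations <- function(file, strict = FALSE, thesaurus = NULL) {
  parse_relations(readLines(file, encoding = "UTF-8", warn = FALSE),
                  strict = strict, thesaurus = thesaurus)
}

#' Write entity-relation records
#'
#' Serializes records in the same pipe-delimited format accepted by
#' [parse_relations()], one record per line with a terminal `|`.
#' `parse_relations(write -> read)` is the identity on normalized records.
#'
#' @param records data frame as returned by [parse_relations()].
#' @param file path or connection.
#' @return `file`, invisibly.
#' @export
write_relations <- function(records, file) {
  check_records(records)
  lines <- sprintf("%d | %d | %s | %s | %s | %s | %s |",
                   records$pmid, records$sentence_index,
                   records$entity_a, records$type_a,
                   records$entity_b, records$type_b, records$relation)
  writeLines(lines, file)
  invisible(file)
}

#' Filter records by entity type
#'
#' Keeps only records where both entities' type tags lie in
#' `allowed_types`, preserving order. Used to restrict the co-occurrence
#' graph to, e.g., genes, drugs, and diseases.
#'
#' @param records relation records data frame.
#' @param allowed_types non-empty character subset of [ENTITY_TYPES].
#' @return Filtered records data frame.
#' @export
filter_by_type <- function(records, allowed_types = c("GENE", "DRUG", "DISEASE")) {
  check_records(records)
  allowed_types <- toupper(allowed_types)
  if (length(allowed_types) == 0L) stop_value("allowed_types must be non-empty")
  keep <- records$type_a %in% allowed_types & records$type_b %in% allowed_types
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_records <- function(records) {
  need <- c("pmid", "sentence_index", "entity_a", "type_a",
            "entity_b", "type_b", "relation")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop_value("records must be a data frame with columns ",
               paste(need, collapse = ", "))
  }
  invisible(records)
}
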