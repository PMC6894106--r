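#' Configuration for the synthetic corpus generator
#'
#' Describes a corpus of extraction records with planted structure around
#' a hub entity (the ranking target):
#' \describe{
#'   \item{direct pairs}{entities that co-occur directly with a partner
#'     entity (`with`, the hub by default). Each fires per abstract with
#'     probability `rate`; a firing abstract carries
#'     `1 + Bernoulli(multi)` mentions, the simplest process that
#'     exercises the \eqn{\alpha}/\eqn{\beta} split. An optional `phase`
#'     (`"even"`/`"odd"`) restricts firing to abstracts of that parity, so
#'     two complementary-phase entities never share an abstract — used to
#'     plant thesaurus-grouped synonyms with zero co-occurrence and
#'     disjoint contexts, emulating sub-literatures that use different
#'     names for one concept.}
#'   \item{hidden pairs}{entities with \emph{zero} direct co-occurrence
#'     with the hub, linked through exactly `m` dedicated intermediate
#'     entities. Each leg (hub--intermediate, intermediate--entity) fires
#'     per abstract with probability `leg_rate`; `strength` is the
#'     relatedness score planted for both legs.}
#'   \item{control pair}{a frequency-matched direct-only contrast for the
#'     first hidden pair: its expected mention total equals the hidden
#'     pair's expected total leg mentions (`m * leg_rate * n_abstracts`),
#'     so baseline co-occurrence ranking favors it while the hybrid score
#'     should favor the hidden pair.}
#'   \item{noise}{with probability `noise_rate` per abstract, one record
#'     over a pair of filler entities.}
#' }
#'
#' @param n_abstracts number of abstracts (distinct PMIDs).
#' @param hub target entity label.
#' @param direct_pairs list of lists with fields `entity`, `type`,
#'   `rate`, `multi`, `s` (planted relatedness to the partner), optional
#'   `phase` and `with` (partner entity and its type, as
#'   `c(label, type)`; defaults to the hub).
#' @param hidden_pairs list of lists with fields `entity`, `type`, `m`,
#'   `strength`, `leg_rate`.
#' @param control `NULL` to derive the frequency-matched control
#'   automatically from the first hidden pair, `NA` to disable, or a
#'   list like a direct-pair entry.
#' @param noise_entities character vector of filler entity labels.
#' @param noise_rate per-abstract probability of one noise record.
#' @param thesaurus_groups list of character vectors injected as
#'   thesaurus groups.
#' @param s_noise planted relatedness among filler entities.
#' @param seed RNG seed; a fixed seed yields byte-identical output.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_abstracts = 120,
                         hub = "alzheimer's disease",
                         direct_pairs = list(
                           list(entity = "app", type = "GENE",
                                rate = 0.6, multi = 0.3, s = 0.60,
                                phase = "even"),
                           list(entity = "amyloid precursor protein",
                                type = "GENE", rate = 0.6, multi = 0.3,
                                s = 0.60, phase = "odd",
                                with = c("dementia", "DISEASE")),
                           list(entity = "tau", type = "GENE",
                                rate = 0.5, multi = 0.2, s = 0.55),
                           list(entity = "memantine", type = "DRUG",
                                rate = 0.3, multi = 0.1, s = 0.50)),
                         hidden_pairs = list(
                           list(entity = "psen2", type = "GENE", m = 5,
                                strength = 0.9, leg_rate = 0.25)),
                         control = NULL,
                         noise_entities = paste0("filler", 1:8),
                         noise_rate = 0.3,
                         thesaurus_groups = list(
                           c("app", "amyloid precursor protein")),
                         s_noise = 0.1,
                         seed = 1) {
  stopifnot(n_abstracts >= 1, noise_rate >= 0, noise_rate <= 1,
            length(noise_entities) >= 2)
  hub <- normalize_entity(hub)
  for (dp in direct_pairs) {
    stopifnot(dp$rate >= 0, dp$rate <= 1, dp$multi >= 0, dp$multi <= 1)
  }
  for (hp in hidden_pairs) {
    stopifnot(hp$m >= 1, hp$leg_rate > 0, hp$leg_rate <= 1)
  }
  if (is.null(control) && length(hidden_pairs) > 0L) {
    hp <- hidden_pairs[[1L]]
    target_total <- hp$m * hp$leg_rate  # expected mentions per abstract
    control <- list(entity = "apoe", type = "GENE",
                    rate = min(1, target_total),
                    multi = max(0, min(1, target_total - 1)),
                    s = 0.60, phase = NULL)
  }
  if (length(control) == 1L && is.na(control[1L])) control <- NULL
  planted <- c(hub,
               vapply(direct_pairs, `[[`, "", "entity"),
               vapply(hidden_pairs, `[[`, "", "entity"),
               if (!is.null(control)) control$entity)
  planted <- normalize_entity(planted)
  if (anyDuplicated(planted)) stop_value("planted entity labels must be distinct")
  if (any(normalize_entity(noise_entities) %in% planted)) {
    stop_value("noise entities must not overlap planted entities")
  }
  structure(list(n_abstracts = as.integer(n_abstracts), hub = hub,
                 direct_pairs = direct_pairs, hidden_pairs = hidden_pairs,
                 control = control,
                 noise_entities = normalize_entity(noise_entities),
                 noise_rate = noise_rate,
                 thesaurus_groups = thesaurus_groups,
                 s_noise = s_noise, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic extraction corpus with known ground truth
#'
#' Emits relation records realizing the planted structure of a
#' [synth_config()], together with the matching thesaurus, a planted
#' relatedness table (so scoring can be tested independently of
#' embedding training), a reference entity set (the planted GENE
#' entities), and exact per-pair ground-truth co-occurrence statistics
#' tracked during emission.
#'
#' @param config a [synth_config()].
#' @return An object of class `"synth_corpus"`: list with `records`
#'   (data frame in the relation-record layout), `thesaurus`,
#'   `relatedness` (data frame `entity_a`, `entity_b`, `s`), `reference`
#'   (character), `ground_truth` (list with `pair_stats`, `hub`,
#'   `hidden`, `control`, `intermediates`), and `config`.
#' @examples
#' sc <- synth_corpus(synth_config(n_abstracts = 20, seed = 42))
#' head(sc$records)
#' sc$ground_truth$pair_stats[1:3, ]
#' @export
synth_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  hub <- config$hub
  mediators <- lapply(config$hidden_pairs, function(hp) {
    normalize_entity(sprintf("%s mediator %d", hp$entity, seq_len(hp$m)))
  })
  direct_all <- config$direct_pairs
  if (!is.null(config$control)) direct_all <- c(direct_all, list(config$control))

  rows <- list()
  stats <- new.env(parent = emptyenv())
  bump <- function(tally, a, b, k = 1L) {
    key <- pair_key(a, b)$key
    tally[[key]] <- (tally[[key]] %||% 0L) + k
    tally
  }
  emit <- function(pmid, sid, ea, ta, eb, tb, rel = "CO-OCCUR") {
    rows[[length(rows) + 1L]] <<- data.frame(
      pmid = pmid, sentence_index = sid, entity_a = ea, type_a = ta,
      entity_b = eb, type_b = tb, relation = rel, stringsAsFactors = FALSE)
  }

  with_seed(config$seed, {
    for (d in seq_len(config$n_abstracts)) {
      pmid <- 100000L + d
      sid <- 0L
      tally <- list()
      for (dp in direct_all) {
        ph <- dp$phase %||% NULL
        if (!is.null(ph)) {
          if (ph == "even" && d %% 2L != 0L) next
          if (ph == "odd" && d %% 2L != 1L) next
        }
        if (runif(1) < dp$rate) {
          partner <- dp$with %||% c(hub, "DISEASE")
          n_m <- 1L + stats::rbinom(1L, 1L, dp$multi)
          for (m in seq_len(n_m)) {
            sid <- sid + 1L
            emit(pmid, sid, normalize_entity(partner[1L]), partner[2L],
                 normalize_entity(dp$entity), dp$type)
          }
          tally <- bump(tally, normalize_entity(partner[1L]),
                        normalize_entity(dp$entity), n_m)
        }
      }
      for (h in seq_along(config$hidden_pairs)) {
        hp <- config$hidden_pairs[[h]]
        ent <- normalize_entity(hp$entity)
        for (b in mediators[[h]]) {
          if (runif(1) < hp$leg_rate) {
            sid <- sid + 1L
            emit(pmid, sid, hub, "DISEASE", b, "GENE")
            tally <- bump(tally, hub, b)
          }
          if (runif(1) < hp$leg_rate) {
            sid <- sid + 1L
            emit(pmid, sid, b, "GENE", ent, hp$type)
            tally <- bump(tally, b, ent)
          }
        }
      }
      if (runif(1) < config$noise_rate) {
        pick <- sample(config$noise_entities, 2L)
        sid <- sid + 1L
        emit(pmid, sid, pick[1L], "OTHER", pick[2L], "OTHER")
        tally <- bump(tally, pick[1L], pick[2L])
      }
      # fold the abstract's counts into the running alpha/beta split
      for (key in names(tally)) {
        c_d <- tally[[key]]
        st <- get0(key, envir = stats,
                   ifnotfound = c(total = 0L, alpha = 0L, beta = 0L,
                                  abstracts_multi = 0L,
                                  abstracts_single = 0L))
        st["total"] <- st["total"] + c_d
        if (c_d >= 2L) {
          st["alpha"] <- st["alpha"] + c_d
          st["abstracts_multi"] <- st["abstracts_multi"] + 1L
        } else {
          st["beta"] <- st["beta"] + 1L
          st["abstracts_single"] <- st["abstracts_single"] + 1L
        }
        assign(key, st, envir = stats)
      }
    }
  })

  records <- if (length(rows)) do.call(rbind, rows) else
    parse_relations(character(0))
  rownames(records) <- NULL

  keys <- sort_c(ls(stats))
  gt <- do.call(rbind, lapply(keys, function(k) {
    ab <- strsplit(k, "\t", fixed = TRUE)[[1L]]
    st <- get(k, envir = stats)
    data.frame(entity_a = ab[1L], entity_b = ab[2L],
               total = st[["total"]], alpha = st[["alpha"]],
               beta = st[["beta"]],
               abstracts_multi = st[["abstracts_multi"]],
               abstracts_single = st[["abstracts_single"]],
               stringsAsFactors = FALSE)
  })) %||% empty_edges()

  rel <- list()
  add_rel <- function(a, b, s) {
    rel[[length(rel) + 1L]] <<- data.frame(entity_a = a, entity_b = b,
                                           s = s, stringsAsFactors = FALSE)
  }
  for (dp in direct_all) {
    partner <- dp$with %||% c(hub, "DISEASE")
    add_rel(normalize_entity(partner[1L]), normalize_entity(dp$entity), dp$s)
  }
  for (h in seq_along(config$hidden_pairs)) {
    hp <- config$hidden_pairs[[h]]
    for (b in mediators[[h]]) {
      add_rel(hub, b, hp$strength)
      add_rel(b, normalize_entity(hp$entity), hp$strength)
    }
  }
  ne <- config$noise_entities
  for (i in seq_len(length(ne) - 1L)) {
    for (j in seq.int(i + 1L, length(ne))) add_rel(ne[i], ne[j], config$s_noise)
  }
  relatedness_tab <- do.call(rbind, rel)

  # reference = planted GENE entities tied to the hub (directly or hidden)
  gene_of <- function(lst) {
    keep <- Filter(function(p) identical(p$type, "GENE") &&
                     is.null(p$with), lst)
    vapply(keep, function(p) normalize_entity(p$entity), "")
  }
  reference <- sort_c(unique(c(
    gene_of(direct_all),
    vapply(Filter(function(p) identical(p$type, "GENE"),
                  config$hidden_pairs),
           function(p) normalize_entity(p$entity), ""))))

  structure(list(
    records = records,
    thesaurus = if (length(config$thesaurus_groups))
      thesaurus(config$thesaurus_groups, provenance = "synthetic") else NULL,
    relatedness = relatedness_tab,
    reference = reference,
    ground_truth = list(
      pair_stats = gt,
      hub = hub,
      hidden = vapply(config$hidden_pairs,
                      function(hp) normalize_entity(hp$entity), ""),
      control = if (!is.null(config$control))
        normalize_entity(config$control$entity) else NULL,
      intermediates = mediators),
    config = config), class = "synth_corpus")
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("Synthetic corpus:", length(unique(x$records$pmid)), "abstracts,",
      nrow(x$records), "records,",
      nrow(x$ground_truth$pair_stats), "planted pairs (seed",
      x$config$seed, ")\n")
  invisible(x)
}

#' Write all synthetic corpus artifacts to a directory
#'
#' Emits `records.txt` (pipe-delimited relation records),
#' `thesaurus.txt`, `relatedness.tsv`, `reference.txt`, and
#' `pair_stats.tsv` (the ground-truth co-occurrence statistics).
#'
#' @param x a `"synth_corpus"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(x, dir) {
  stopifnot(inherits(x, "synth_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_relations(x$records, file.path(dir, "records.txt"))
  if (!is.null(x$thesaurus)) {
    write_thesaurus(x$thesaurus, file.path(dir, "thesaurus.txt"))
  }
  write_relatedness_table(x$relatedness, file.path(dir, "relatedness.tsv"))
  writeLines(x$reference, file.path(dir, "reference.txt"))
  write.table(x$ground_truth$pair_stats, file.path(dir, "pair_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
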