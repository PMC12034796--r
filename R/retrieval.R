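#' Construct a filter-cascade query
#'
#' A query bundles a population scope with the optional precision filters of
#' the cascade. The default settings mirror the prospective surveillance use
#' case: retrieve randomized controlled trials of phase III or later for the
#' topic population, excluding pediatric trials; the significance filter is
#' off by default as it is the most experimental criterion.
#'
#' @param population a [expand_population()] result
#' @param date_min,date_max optional closed date window on the record date
#' @param sources subset of `c("pubmed", "registry", "pokb")`
#' @param rct_only keep randomized controlled trials only
#' @param min_phase optional minimum phase code (see [phase_at_least()];
#'   records with unknown phase fail any threshold)
#' @param exclude_children drop records whose population overlaps the
#'   configured pediatric concept set
#' @param significant_only keep records flagged SIGNIFICANT only
#' @param require_known_intervention keep records with at least one
#'   intervention mentioned in the guideline (class not ABSENT)
#' @param require_unknown_intervention keep records with at least one
#'   non-stoplist intervention absent from the guideline
#' @return object of class `filter_query`
#' @export
filter_query <- function(population,
                         date_min = NULL, date_max = NULL,
                         sources = c("pubmed", "registry", "pokb"),
                         rct_only = FALSE, min_phase = NULL,
                         exclude_children = FALSE, significant_only = FALSE,
                         require_known_intervention = FALSE,
                         require_unknown_intervention = FALSE) {
  stopifnot(inherits(population, "population_set"))
  sources <- match.arg(sources, c("pubmed", "registry", "pokb"),
                       several.ok = TRUE)
  if (!is.null(date_min)) date_min <- as.Date(date_min)
  if (!is.null(date_max)) date_max <- as.Date(date_max)
  if (!is.null(date_min) && !is.null(date_max) && date_min > date_max) {
    stop("date_min is after date_max", call. = FALSE)
  }
  if (!is.null(min_phase)) stopifnot(min_phase %in% PHASE_LEVELS)
  structure(
    list(population = population, date_min = date_min, date_max = date_max,
         sources = sources, rct_only = rct_only, min_phase = min_phase,
         exclude_children = exclude_children,
         significant_only = significant_only,
         require_known_intervention = require_known_intervention,
         require_unknown_intervention = require_unknown_intervention),
    class = "filter_query"
  )
}

#' Population match for a single record
#'
#' @param population_cuis character vector of a record's population concepts
#' @param population a `population_set`
#' @return the intersection with the expanded population (a record is
#'   retrieved iff this is non-empty)
#' @export
match_population <- function(population_cuis, population) {
  intersect(as.character(population_cuis), population$expanded_cuis)
}

# record date used by the search window: publication date, else results
# posting, else trial start
record_date <- function(records) {
  d <- records$publication_date
  d[is.na(d)] <- records$results_posted_date[is.na(d)]
  d[is.na(d)] <- records$start_date[is.na(d)]
  d
}

#' Apply the conjunctive filter cascade
#'
#' Filters are pure per-record predicates applied conjunctively in a fixed
#' order (source, date window, population match, RCT flag, minimum phase,
#' pediatric exclusion, significance, known intervention, unknown
#' intervention); because the cascade is a pure conjunction, the final hit
#' set is independent of filter order, and each additional filter can only
#' shrink it. Per-filter survivor counts are attached for logging.
#'
#' @param records [evidence_records()]
#' @param query a [filter_query()]
#' @param index optional `mention_index` for the query's guideline topic
#'   (required by the known/unknown-intervention filters and for context
#'   annotation); its topic must match the query population's topic
#' @param pediatric_cuis concept set defining pediatric populations (used by
#'   `exclude_children`), typically a descendant closure of child/adolescent
#'   seed concepts
#' @param stoplist generic-intervention concept identifiers ignored by the
#'   unknown-intervention test
#' @return tibble of class `search_hits`: the surviving records plus
#'   `matched_population_cuis` and `intervention_contexts` (list of
#'   `(cui, context)` tibbles covering the record's interventions); attribute
#'   `survivors` holds the per-filter counts.
#' @export
apply_cascade <- function(records, query, index = NULL,
                          pediatric_cuis = character(),
                          stoplist = character()) {
  stopifnot(inherits(query, "filter_query"))
  if (!is.null(index)) {
    stopifnot(inherits(index, "mention_index"))
    if (nzchar(index$topic_id) && nzchar(query$population$topic_id) &&
        index$topic_id != query$population$topic_id) {
      stop("mention index topic '", index$topic_id,
           "' does not match query topic '", query$population$topic_id, "'",
           call. = FALSE)
    }
  }
  if ((query$require_known_intervention ||
       query$require_unknown_intervention) && is.null(index)) {
    stop("intervention-context filters require a mention index",
         call. = FALSE)
  }

  keep <- rep(TRUE, nrow(records))
  survivors <- integer()
  note <- function(name) {
    survivors[[name]] <<- sum(keep)
    survivors <<- survivors
  }

  keep <- keep & records$source %in% query$sources
  note("source")
  d <- record_date(records)
  if (!is.null(query$date_min)) keep <- keep & !is.na(d) & d >= query$date_min
  if (!is.null(query$date_max)) keep <- keep & !is.na(d) & d <= query$date_max
  note("date_window")
  matched <- lapply(records$population_cuis, match_population,
                    population = query$population)
  keep <- keep & vapply(matched, length, integer(1)) > 0L
  note("population")
  if (query$rct_only) keep <- keep & records$is_rct
  note("rct_only")
  if (!is.null(query$min_phase)) {
    keep <- keep & phase_at_least(records$phase, query$min_phase)
  }
  note("min_phase")
  if (query$exclude_children && length(pediatric_cuis) > 0L) {
    pediatric <- vapply(records$population_cuis, function(p) {
      any(p %in% pediatric_cuis)
    }, logical(1))
    keep <- keep & !pediatric
  }
  note("exclude_children")
  if (query$significant_only) {
    keep <- keep & records$significance == "SIGNIFICANT"
  }
  note("significant_only")

  contexts <- lapply(records$intervention_cuis, function(cuis) {
    cuis <- sort(unique(cuis))
    ctx <- if (is.null(index)) rep(NA_character_, length(cuis)) else
      classify_intervention(cuis, index)
    tibble::tibble(cui = cuis, context = ctx)
  })
  if (query$require_known_intervention) {
    keep <- keep & vapply(contexts, function(cc) {
      any(cc$context %in% c("IN_RECOMMENDATION", "MENTIONED"))
    }, logical(1))
  }
  note("known_intervention")
  if (query$require_unknown_intervention) {
    keep <- keep & vapply(contexts, function(cc) {
      any(cc$context %in% "ABSENT" & !(cc$cui %in% stoplist))
    }, logical(1))
  }
  note("unknown_intervention")

  hits <- records[keep, , drop = FALSE]
  hits$matched_population_cuis <- matched[keep]
  hits$intervention_contexts <- contexts[keep]
  attr(hits, "survivors") <- survivors
  class(hits) <- unique(c("search_hits", class(hits)))
  hits
}

#' Assemble a trial timeline
#'
#' Orders the milestones of one registered trial — start date, results
#' posting, and the publication dates of linked articles — together with
#' guideline version releases as markers, providing the temporal view of the
#' state of research around a trial relative to guideline updates.
#'
#' @param nct_id registry identifier of the trial
#' @param records [evidence_records()] containing the registry record and
#'   any linked publications (via `linked_registry_ids`)
#' @param guideline_versions optional list of [guideline_document()]s whose
#'   release dates become `guideline_release` markers
#' @return tibble with columns `date`, `event`, `record_id`, sorted by date
#'   (events without a date are dropped)
#' @export
build_timeline <- function(nct_id, records, guideline_versions = list()) {
  trial <- records[records$record_id == nct_id &
                     records$source == "registry", , drop = FALSE]
  if (nrow(trial) == 0L) {
    stop("unknown registry id: ", nct_id, call. = FALSE)
  }
  events <- tibble::tibble(
    date = c(trial$start_date[1], trial$results_posted_date[1]),
    event = c("trial_start", "results_posted"),
    record_id = nct_id
  )
  linked <- records[records$source == "pubmed" &
                      vapply(records$linked_registry_ids,
                             function(x) nct_id %in% x, logical(1)), ,
                    drop = FALSE]
  if (nrow(linked) > 0L) {
    events <- rbind(events, tibble::tibble(
      date = linked$publication_date,
      event = "publication",
      record_id = linked$record_id
    ))
  }
  for (gv in guideline_versions) {
    events <- rbind(events, tibble::tibble(
      date = gv$release_date,
      event = "guideline_release",
      record_id = paste0(gv$guideline_id, ":", gv$version)
    ))
  }
  events <- events[!is.na(events$date), , drop = FALSE]
  events[order(events$date, events$event), , drop = FALSE]
}
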