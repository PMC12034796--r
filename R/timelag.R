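#' Identify newly recommended interventions between guideline versions
#'
#' An intervention concept is "new" when it is mentioned in the
#' recommendation sections of the new guideline version but not in those of
#' the old one, and survives four quality filters: (1) mention confidence of
#' at least `min_confidence` (default 0.1 — low-confidence normalizations
#' are mostly noise), (2) not on the generic-intervention stoplist
#' ("chemotherapy"-type concepts), (3) semantic type among `allowed_types`
#' (pharmacologic substances T121 or therapeutic/preventive procedures T061
#' by default), and (4) at least one corpus record lists the concept as an
#' intervention.
#'
#' @param old_version,new_version [guideline_document()]s sharing a
#'   `guideline_id`, with `old_version` released first
#' @param graph a [concept_graph()] supplying semantic types
#' @param corpus [evidence_records()]
#' @param min_confidence minimum mention confidence (filter 1)
#' @param stoplist generic-intervention CUIs (filter 2)
#' @param allowed_types semantic-type tokens (filter 3)
#' @return character vector of concept identifiers
#' @export
identify_new_interventions <- function(old_version, new_version, graph,
                                       corpus, min_confidence = 0.1,
                                       stoplist = character(),
                                       allowed_types = c("T121", "T061")) {
  stopifnot(inherits(old_version, "guideline_document"),
            inherits(new_version, "guideline_document"))
  if (old_version$guideline_id != new_version$guideline_id) {
    stop("guideline versions do not share a guideline_id", call. = FALSE)
  }
  if (!(old_version$release_date < new_version$release_date)) {
    stop("old_version must be released before new_version", call. = FALSE)
  }
  new_idx <- build_mention_index(new_version, min_confidence = min_confidence)
  old_idx <- build_mention_index(old_version, min_confidence = 0)
  candidates <- setdiff(new_idx$recommendation_cuis,
                        old_idx$recommendation_cuis)
  candidates <- setdiff(candidates, stoplist)
  candidates <- candidates[candidates %in% graph$concepts$cui]
  candidates <- filter_by_semantic_type(graph, candidates, allowed_types)
  trialed <- unique(unlist(corpus$intervention_cuis))
  sort(intersect(candidates, trialed))
}

#' Build intervention translation timelines
#'
#' For each newly recommended intervention: the start date of the first
#' human trial over all phases (including early phase 1), the earliest
#' result publication (publication date of a report, or results posting of a
#' registered trial), the recommendation date (release date of the guideline
#' version that first recommends the concept), and whether any trial of the
#' intervention reached phase III. Interventions without any dated trial are
#' dropped with a warning. Negative publication-to-recommendation lags are
#' legitimate: a recommendation can precede the publication of an ongoing
#' trial's results.
#'
#' @param new_cuis character vector of intervention concepts
#' @param corpus [evidence_records()]
#' @param new_version the recommending [guideline_document()]
#' @param phase3_publication_only when `TRUE`, the first result publication
#'   is taken over phase-III-or-later trials only (the "pivotal trial"
#'   reading); default uses the earliest publication of any trial
#' @return tibble with columns `cui`, `first_trial_start`,
#'   `first_result_publication`, `recommendation_date`, `has_phase3`
#' @export
build_timelines <- function(new_cuis, corpus, new_version,
                            phase3_publication_only = FALSE) {
  stopifnot(inherits(new_version, "guideline_document"))
  rows <- list()
  dropped <- character()
  for (cui in new_cuis) {
    has <- vapply(corpus$intervention_cuis, function(x) cui %in% x, logical(1))
    sub <- corpus[has, , drop = FALSE]
    starts <- sub$start_date[!is.na(sub$start_date)]
    pub_sub <- if (phase3_publication_only) {
      sub[phase_at_least(sub$phase, "P3"), , drop = FALSE]
    } else {
      sub
    }
    pubs <- c(pub_sub$publication_date, pub_sub$results_posted_date)
    pubs <- pubs[!is.na(pubs)]
    if (length(starts) == 0L && length(pubs) == 0L) {
      dropped <- c(dropped, cui)
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cui = cui,
      first_trial_start = if (length(starts) > 0L) min(starts) else as.Date(NA),
      first_result_publication = if (length(pubs) > 0L) min(pubs) else
        as.Date(NA),
      recommendation_date = new_version$release_date,
      has_phase3 = any(phase_at_least(sub$phase, "P3"))
    )
  }
  if (length(dropped) > 0L) {
    warning("no dated trial for intervention(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(cui = character(),
                          first_trial_start = as.Date(character()),
                          first_result_publication = as.Date(character()),
                          recommendation_date = as.Date(character()),
                          has_phase3 = logical()))
  }
  do.call(rbind, rows)
}

# elapsed years between two dates, 365.25-day civil years
years_between <- function(from, to) {
  as.numeric(to - from) / 365.25
}

#' Summarize research-translation time lags
#'
#' Computes, per stratum, the distribution (n, mean, median, min, max, in
#' 365.25-day years) of three lags: the overall span from first trial start
#' to guideline recommendation, the start-to-publication leg, and the
#' publication-to-recommendation leg. When both legs use the same reference
#' publication they add up to the overall span exactly. Strata are `all`
#' timelines and, when `stratify_by_phase3` is set, the subsets with and
#' without a phase III trial; empty strata are omitted.
#'
#' @param timelines a [build_timelines()] result
#' @param stratify_by_phase3 also summarize by phase III availability
#' @return tibble with columns `stratum`, `lag`, `n`, `mean`, `median`,
#'   `min`, `max`
#' @export
summarize_lags <- function(timelines, stratify_by_phase3 = FALSE) {
  lag_table <- function(tl, stratum) {
    if (nrow(tl) == 0L) return(NULL)
    lags <- list(
      overall = years_between(tl$first_trial_start, tl$recommendation_date),
      start_to_publication = years_between(tl$first_trial_start,
                                           tl$first_result_publication),
      publication_to_recommendation = years_between(
        tl$first_result_publication, tl$recommendation_date)
    )
    do.call(rbind, lapply(names(lags), function(nm) {
      x <- lags[[nm]][!is.na(lags[[nm]])]
      if (length(x) == 0L) return(NULL)
      tibble::tibble(stratum = stratum, lag = nm, n = length(x),
                     mean = mean(x), median = stats::median(x),
                     min = min(x), max = max(x))
    }))
  }
  out <- lag_table(timelines, "all")
  if (stratify_by_phase3) {
    out <- rbind(out,
                 lag_table(timelines[timelines$has_phase3, , drop = FALSE],
                           "with_phase3"),
                 lag_table(timelines[!timelines$has_phase3, , drop = FALSE],
                           "without_phase3"))
  }
  out
}
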