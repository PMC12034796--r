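#' Trial-phase codes and ordering
#'
#' Phases are coded as `EARLY_1 < P1 < P1_2 < P2 < P2_3 < P3 < P4`, plus
#' `UNKNOWN`, which is incomparable and therefore fails every minimum-phase
#' threshold. For threshold tests ("phase II or later"), mixed designations
#' are promoted to their higher component: a phase I/II trial counts as
#' phase II or later, a phase II/III trial as phase III or later — the most
#' advanced claim in the design is what a reviewer would examine.
#'
#' @format Character vector of the ordered phase codes (without `UNKNOWN`).
#' @export
PHASE_LEVELS <- c("EARLY_1", "P1", "P1_2", "P2", "P2_3", "P3", "P4")

# promoted rank used for >= comparisons; UNKNOWN -> NA
phase_rank <- function(phase) {
  ranks <- c(EARLY_1 = 0.5, P1 = 1, P1_2 = 2, P2 = 2, P2_3 = 3, P3 = 3, P4 = 4)
  unname(ranks[as.character(phase)])
}

#' Test a minimum-phase threshold
#'
#' @param phase character vector of phase codes (see [PHASE_LEVELS];
#'   `"UNKNOWN"` allowed)
#' @param min_phase single phase code acting as the threshold
#' @return logical vector; `UNKNOWN` phases are always `FALSE`.
#' @export
phase_at_least <- function(phase, min_phase) {
  stopifnot(min_phase %in% PHASE_LEVELS)
  r <- phase_rank(phase)
  !is.na(r) & r >= phase_rank(min_phase)
}

#' Parse a registry phase string
#'
#' Accepts the spellings used in registry exports ("Phase 3", "PHASE3",
#' "Phase 1/Phase 2", "Early Phase 1", "N/A", ...).
#' @param x character vector
#' @return character vector of phase codes
#' @export
parse_registry_phase <- function(x) {
  key <- toupper(gsub("[^A-Z0-9]", "", toupper(as.character(x))))
  map <- c(EARLYPHASE1 = "EARLY_1", PHASE1 = "P1", PHASE1PHASE2 = "P1_2",
           PHASE12 = "P1_2", PHASE2 = "P2", PHASE2PHASE3 = "P2_3",
           PHASE23 = "P2_3", PHASE3 = "P3", PHASE4 = "P4")
  out <- unname(map[key])
  out[is.na(out)] <- "UNKNOWN"
  out
}

#' Construct a harmonized evidence-record table
#'
#' Every evidence source (publication corpus, trial registry, curated
#' precision-oncology knowledge base) is normalized to one row per record
#' with concept-identifier keyed population and intervention sets, so that
#' downstream retrieval treats all sources uniformly.
#'
#' @param record_id source-qualified identifier (PMID digits, registry ID,
#'   or assertion ID); must be unique
#' @param source one of `"pubmed"`, `"registry"`, `"pokb"`
#' @param title character
#' @param publication_date,start_date,results_posted_date `Date` (or
#'   ISO-8601 strings); any may be `NA`
#' @param is_rct logical flag
#' @param phase phase code (see [PHASE_LEVELS]) or `"UNKNOWN"`
#' @param population_cuis,intervention_cuis lists of character vectors
#' @param significance `"SIGNIFICANT"`, `"NOT_SIGNIFICANT"` or `"UNKNOWN"`
#' @param linked_registry_ids,raw_publication_types,raw_mesh_uis lists of
#'   character vectors
#' @return tibble of class `evidence_records`
#' @export
evidence_records <- function(record_id, source, title = NA_character_,
                             publication_date = as.Date(NA),
                             start_date = as.Date(NA),
                             results_posted_date = as.Date(NA),
                             is_rct = FALSE, phase = "UNKNOWN",
                             population_cuis = list(),
                             intervention_cuis = list(),
                             significance = "UNKNOWN",
                             linked_registry_ids = list(),
                             raw_publication_types = list(),
                             raw_mesh_uis = list()) {
  n <- length(record_id)
  fill_list <- function(x) {
    if (length(x) == 0L) x <- replicate(n, character(), simplify = FALSE)
    if (n > 0L && length(x) == 1L && !is.list(x)) x <- list(x)
    if (!is.list(x)) stop("expected a list of character vectors")
    if (length(x) != n) x <- rep(x, length.out = n)
    lapply(x, as.character)
  }
  rec <- tibble::tibble(
    record_id = as.character(record_id),
    source = rep_len(as.character(source), n),
    title = rep_len(as.character(title), n),
    publication_date = rep_len(as.Date(publication_date), n),
    start_date = rep_len(as.Date(start_date), n),
    results_posted_date = rep_len(as.Date(results_posted_date), n),
    is_rct = rep_len(as.logical(is_rct), n),
    phase = rep_len(as.character(phase), n),
    population_cuis = fill_list(population_cuis),
    intervention_cuis = fill_list(intervention_cuis),
    significance = rep_len(as.character(significance), n),
    linked_registry_ids = fill_list(linked_registry_ids),
    raw_publication_types = fill_list(raw_publication_types),
    raw_mesh_uis = fill_list(raw_mesh_uis)
  )
  validate_evidence_records(rec)
}

validate_evidence_records <- function(rec) {
  if (anyDuplicated(rec$record_id)) {
    stop("duplicate record_id: ", rec$record_id[duplicated(rec$record_id)][1],
         call. = FALSE)
  }
  bad_src <- setdiff(unique(rec$source), c("pubmed", "registry", "pokb"))
  if (length(bad_src) > 0L) stop("unknown source: ", bad_src[1], call. = FALSE)
  bad_phase <- setdiff(unique(rec$phase), c(PHASE_LEVELS, "UNKNOWN"))
  if (length(bad_phase) > 0L) stop("unknown phase: ", bad_phase[1], call. = FALSE)
  bad_sig <- setdiff(unique(rec$significance),
                     c("SIGNIFICANT", "NOT_SIGNIFICANT", "UNKNOWN"))
  if (length(bad_sig) > 0L) {
    stop("unknown significance: ", bad_sig[1], call. = FALSE)
  }
  class(rec) <- unique(c("evidence_records", class(rec)))
  rec
}

#' Bind several evidence-record tables into one corpus
#' @param ... `evidence_records` tibbles
#' @return a single `evidence_records` tibble; record ids must stay unique
#' @export
bind_records <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0,
                        logical(1))]
  if (length(parts) == 0L) return(evidence_records(character(), character()))
  validate_evidence_records(do.call(rbind, parts))
}
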