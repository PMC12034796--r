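#' Index guideline concept mentions
#'
#' Collects the concept identifiers mentioned anywhere in a guideline and
#' the subset mentioned inside recommendation sections, at or above a
#' minimum mention confidence. The index is the basis for contextualizing
#' trial interventions against current recommended practice.
#'
#' @param doc a [guideline_document()]
#' @param min_confidence mentions below this confidence are ignored
#'   (default 0: index everything; the stricter 0.1 cut-off is used by the
#'   time-lag analysis)
#' @return object of class `mention_index` with `guideline_id`, `topic_id`,
#'   `recommendation_cuis` and `anywhere_cuis`
#'   (`recommendation_cuis` is always a subset of `anywhere_cuis`).
#' @export
build_mention_index <- function(doc, min_confidence = 0) {
  stopifnot(inherits(doc, "guideline_document"))
  anywhere <- character()
  recommendation <- character()
  for (s in doc$sections) {
    cuis <- vapply(s$mentions, function(m) {
      if (m$confidence >= min_confidence) m$cui else NA_character_
    }, character(1))
    cuis <- cuis[!is.na(cuis)]
    anywhere <- c(anywhere, cuis)
    if (s$type == "recommendation") recommendation <- c(recommendation, cuis)
  }
  structure(
    list(guideline_id = doc$guideline_id,
         topic_id = doc$topic_id,
         recommendation_cuis = sort(unique(recommendation)),
         anywhere_cuis = sort(unique(anywhere))),
    class = "mention_index"
  )
}

#' @export
print.mention_index <- function(x, ...) {
  cat("<mention_index> ", x$guideline_id, ": ",
      length(x$recommendation_cuis), " recommendation / ",
      length(x$anywhere_cuis), " anywhere concepts\n", sep = "")
  invisible(x)
}

#' Build a mention index directly from known concept sets
#'
#' Convenience constructor used by fixtures and cached indexes.
#' @param guideline_id,topic_id identifiers
#' @param recommendation_cuis,anywhere_cuis character vectors; the anywhere
#'   set is completed to include the recommendation set
#' @return a `mention_index`
#' @export
mention_index <- function(guideline_id, topic_id, recommendation_cuis,
                          anywhere_cuis) {
  structure(
    list(guideline_id = as.character(guideline_id),
         topic_id = as.character(topic_id),
         recommendation_cuis = sort(unique(as.character(recommendation_cuis))),
         anywhere_cuis = sort(unique(as.character(
           c(anywhere_cuis, recommendation_cuis))))),
    class = "mention_index"
  )
}

#' Classify interventions against a guideline
#'
#' Each intervention concept stands in exactly one relation to a guideline:
#' `IN_RECOMMENDATION` when mentioned inside a recommendation section (this
#' dominates), `MENTIONED` when mentioned anywhere else in the guideline,
#' `ABSENT` otherwise. A "known" intervention is one that is not `ABSENT`.
#'
#' @param cuis character vector of intervention concept identifiers
#' @param index a `mention_index`
#' @return character vector of class tokens, same length as `cuis`
#' @export
classify_intervention <- function(cuis, index) {
  stopifnot(inherits(index, "mention_index"))
  cuis <- as.character(cuis)
  out <- rep("ABSENT", length(cuis))
  out[cuis %in% index$anywhere_cuis] <- "MENTIONED"
  out[cuis %in% index$recommendation_cuis] <- "IN_RECOMMENDATION"
  out
}

#' Serialize / restore a mention index
#' @param index a `mention_index`
#' @param path JSON file
#' @return `write_mention_index()`: invisibly, `path`
#' @export
write_mention_index <- function(index, path) {
  jsonlite::write_json(unclass(index), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mention_index
#' @export
read_mention_index <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mention_index(raw$guideline_id, raw$topic_id,
                as.character(raw$recommendation_cuis),
                as.character(raw$anywhere_cuis))
}

#' Read a stoplist of generic concepts
#'
#' Very general concepts ("treatment", "placebo", ...) are among the most
#' frequent automatically extracted interventions; the stoplist keeps them
#' out of the unknown-intervention signal and the time-lag analysis.
#' @param path TSV with header `cui` (a `preferred_term` column is allowed
#'   and ignored)
#' @return character vector of CUIs
#' @export
read_stoplist <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  stopifnot("cui" %in% names(df))
  unique(df$cui)
}
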