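#' Dictionary-based concept annotation
#'
#' Deterministic lexicon matcher standing behind the annotator contract:
#' case-insensitive, longest-leftmost matches at token boundaries, so
#' "chemoradiotherapy" matches the full term even when the lexicon also
#' contains "radiotherapy". Ties between equal-length candidates at the same
#' start are broken by the lexicographically smallest concept identifier.
#' Exact lexicon hits carry confidence 1.0. Any annotator with the same
#' signature (text -> mention tibble) can be plugged into [tag_pico()] and
#' the guideline indexing step instead.
#'
#' @param text character scalar
#' @param lexicon data frame with columns `term`, `cui` (terms matched
#'   case-insensitively)
#' @param graph optional [concept_graph()] used to copy semantic types onto
#'   mentions
#' @return tibble with columns `cui`, `surface`, `start`, `end` (0-based
#'   half-open character offsets), `confidence`, `semantic_types`
#'   (list-column); non-overlapping, sorted by `start`.
#' @export
dictionary_annotate <- function(text, lexicon, graph = NULL) {
  empty <- tibble::tibble(
    cui = character(), surface = character(), start = integer(),
    end = integer(), confidence = numeric(), semantic_types = list()
  )
  if (is.na(text) || !nzchar(text) || nrow(lexicon) == 0L) return(empty)
  stopifnot(all(c("term", "cui") %in% names(lexicon)))
  lex <- data.frame(term = tolower(as.character(lexicon$term)),
                    cui = as.character(lexicon$cui),
                    stringsAsFactors = FALSE)
  lex$len <- nchar(lex$term)
  lex <- lex[order(-lex$len, lex$cui), , drop = FALSE]
  low <- tolower(text)
  n <- nchar(low)
  is_word <- function(ch) grepl("[a-z0-9]", ch)
  boundary_ok <- function(start0, end0) {
    # token boundaries: no word character immediately adjacent outside
    before <- if (start0 > 0L) substr(low, start0, start0) else ""
    after <- if (end0 < n) substr(low, end0 + 1L, end0 + 1L) else ""
    (!nzchar(before) || !is_word(before)) && (!nzchar(after) || !is_word(after))
  }
  out <- list()
  pos <- 0L # 0-based scan position
  while (pos < n) {
    hit <- NULL
    for (j in seq_len(nrow(lex))) {
      len <- lex$len[j]
      if (pos + len > n) next
      if (substr(low, pos + 1L, pos + len) == lex$term[j] &&
          boundary_ok(pos, pos + len)) {
        hit <- lex[j, ]
        break # lex sorted by length desc, then cui: first match wins
      }
    }
    if (is.null(hit)) {
      pos <- pos + 1L
    } else {
      out[[length(out) + 1L]] <- list(
        cui = hit$cui,
        surface = substr(text, pos + 1L, pos + hit$len),
        start = pos, end = pos + hit$len
      )
      pos <- pos + hit$len
    }
  }
  if (length(out) == 0L) return(empty)
  cuis <- vapply(out, `[[`, character(1), "cui")
  types <- if (!is.null(graph)) {
    present <- cuis %in% graph$concepts$cui
    tt <- replicate(length(cuis), character(), simplify = FALSE)
    tt[present] <- unname(semantic_types_of(graph, cuis[present]))
    tt
  } else {
    replicate(length(cuis), character(), simplify = FALSE)
  }
  tibble::tibble(
    cui = cuis,
    surface = vapply(out, `[[`, character(1), "surface"),
    start = vapply(out, `[[`, integer(1), "start"),
    end = vapply(out, `[[`, integer(1), "end"),
    confidence = 1.0,
    semantic_types = types
  )
}

#' Default labelled-section headers for the PICO span baseline
#'
#' Upper-case structured-abstract headers routed to population or
#' intervention spans by [tag_pico()].
#' @format named character vector: header token -> span type
#' @export
PICO_SECTION_HEADERS <- c(
  "PATIENTS" = "population", "PARTICIPANTS" = "population",
  "POPULATION" = "population", "SUBJECTS" = "population",
  "INTERVENTION" = "intervention", "INTERVENTIONS" = "intervention",
  "TREATMENT" = "intervention", "METHODS" = "intervention"
)

#' Partition abstract concept mentions into population and intervention sets
#'
#' Baseline PICO tagger: structured-abstract headers (`"PATIENTS:"`,
#' `"INTERVENTION:"`, ...) delimit labelled spans; mentions whose start
#' offset falls inside a population span feed the population set, inside an
#' intervention span the intervention set. An unlabelled abstract is treated
#' as a single span of both types. A different annotator can be supplied to
#' replace the dictionary baseline.
#'
#' @param abstract_text character scalar
#' @param lexicon,graph passed to [dictionary_annotate()]
#' @param annotator optional function `(text) -> mention tibble` overriding
#'   the dictionary baseline
#' @param headers named character vector mapping header tokens to span types
#'   (see [PICO_SECTION_HEADERS])
#' @return list with `population_cuis`, `intervention_cuis` (sorted unique
#'   character vectors), `spans` (tibble of `span_type`, `start`, `end`) and
#'   `mentions`
#' @export
tag_pico <- function(abstract_text, lexicon = NULL, graph = NULL,
                     annotator = NULL, headers = PICO_SECTION_HEADERS) {
  if (is.null(annotator)) {
    annotator <- function(text) dictionary_annotate(text, lexicon, graph)
  }
  mentions <- annotator(abstract_text)
  n <- nchar(abstract_text)

  # locate "HEADER:" tokens; each labelled span runs to the next header
  m <- gregexpr("\\b[A-Z][A-Z ]{2,}:", abstract_text)[[1]]
  spans <- tibble::tibble(span_type = character(), start = integer(),
                          end = integer())
  if (m[1] != -1L) {
    starts <- as.integer(m) - 1L # 0-based
    lens <- attr(m, "match.length")
    labels <- substring(abstract_text, starts + 1L, starts + lens - 1L)
    types <- unname(headers[trimws(labels)])
    span_end <- c(starts[-1L], n)
    keep <- !is.na(types)
    spans <- tibble::tibble(span_type = types[keep],
                            start = (starts + lens)[keep],
                            end = span_end[keep])
  }
  if (nrow(spans) == 0L && n > 0L) {
    spans <- tibble::tibble(span_type = c("population", "intervention"),
                            start = 0L, end = n)
  }
  in_span <- function(type) {
    ss <- spans[spans$span_type == type, , drop = FALSE]
    if (nrow(mentions) == 0L || nrow(ss) == 0L) return(character())
    keep <- vapply(mentions$start, function(s) {
      any(s >= ss$start & s < ss$end)
    }, logical(1))
    sort(unique(mentions$cui[keep]))
  }
  list(
    population_cuis = in_span("population"),
    intervention_cuis = in_span("intervention"),
    spans = spans,
    mentions = mentions
  )
}

#' Significance flag from structured outcome analyses
#'
#' A trial is flagged significant iff any reported outcome analysis has
#' p < 0.05 (strict); trials with analyses but no qualifying p value are not
#' significant; trials without reported analyses are unknown. Adding an
#' analysis can only move the flag towards SIGNIFICANT, never away from it.
#'
#' @param p_values numeric vector of p values (may be empty)
#' @return `"SIGNIFICANT"`, `"NOT_SIGNIFICANT"` or `"UNKNOWN"`
#' @export
significance_from_structured <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p value outside [0,1]", call. = FALSE)
  }
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) return("UNKNOWN")
  if (any(p_values < 0.05)) "SIGNIFICANT" else "NOT_SIGNIFICANT"
}

#' Rule-based significance flag from abstract text
#'
#' Deterministic baseline standing behind the significance-classifier
#' contract: parses p-value expressions (`p = 0.03`, `p < 0.001`, ...) and
#' scans for affirmative or negated significance phrases. Any parsed
#' p < 0.05 or an affirmative phrase yields SIGNIFICANT; an explicit
#' negation yields NOT_SIGNIFICANT; otherwise UNKNOWN. For records where the
#' registry also reports structured analyses, the structured flag takes
#' precedence.
#'
#' @param abstract_text character scalar
#' @return `"SIGNIFICANT"`, `"NOT_SIGNIFICANT"` or `"UNKNOWN"`
#' @export
significance_from_abstract <- function(abstract_text) {
  if (is.na(abstract_text) || !nzchar(abstract_text)) return("UNKNOWN")
  text <- tolower(abstract_text)
  pm <- gregexpr("p\\s*(<=|>=|[=<>])\\s*(0?\\.[0-9]+|[01](\\.[0-9]+)?)",
                 text)[[1]]
  p_sig <- FALSE
  p_nonsig <- FALSE
  if (pm[1] != -1L) {
    toks <- regmatches(text, list(pm))[[1]]
    for (tok in toks) {
      op <- sub("^p\\s*([=<>]+).*$", "\\1", tok)
      val <- suppressWarnings(as.numeric(sub("^p\\s*[=<>]+\\s*", "", tok)))
      if (is.na(val)) next
      if ((op %in% c("=", "<", "<=") && val < 0.05)) p_sig <- TRUE
      else p_nonsig <- TRUE
    }
  }
  negated <- grepl(
    "no(t| statistically)? significant|non-?significant|no significant",
    text)
  affirmative <- !negated && grepl(
    "statistically significant|significant(ly)? (improv|increas|reduc|longer|better|higher|lower)",
    text)
  if (p_sig || affirmative) return("SIGNIFICANT")
  if (negated || p_nonsig) return("NOT_SIGNIFICANT")
  "UNKNOWN"
}

#' Read a term lexicon
#' @param path TSV with header `term<TAB>cui`
#' @return data frame with columns `term`, `cui`
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  stopifnot(all(c("term", "cui") %in% names(df)))
  df
}
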