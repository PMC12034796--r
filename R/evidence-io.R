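#' Read a Medline/PubMed XML subset
#'
#' Supports the metadata subset needed for harmonization: PMID,
#' ArticleTitle, AbstractText (concatenated in document order with single
#' spaces), PublicationType (with `UI` attribute), MeshHeading
#' DescriptorName `UI`, DataBank AccessionNumber, ArticleDate and PubDate.
#' Everything else in the DTD is ignored.
#'
#' A record is flagged as an RCT iff a publication type or a MeSH descriptor
#' identifier from `rct_descriptor_uis` is present (the randomized
#' controlled trial descriptor by default). Accession numbers matching the
#' registry pattern `NCT` + 8 digits become `linked_registry_ids`. The
#' publication date is the electronic article date when present, otherwise
#' the print date; a missing month or day is completed to the first day of
#' the period so that dates are totally ordered.
#'
#' @param path XML file
#' @param rct_descriptor_uis identifiers defining an RCT (publication type
#'   or MeSH descriptor UI)
#' @return [evidence_records()] with one extra column `abstract` (the
#'   concatenated abstract text, used by the annotation step). Articles
#'   without a PMID are skipped; their number is attached as attribute
#'   `n_skipped` and reported with a warning.
#' @export
read_medline_xml <- function(path, rct_descriptor_uis = "D016449") {
  doc <- xml2::read_xml(path)
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  n_skipped <- 0L
  rows <- vector("list", length(articles))
  for (i in seq_along(articles)) {
    a <- articles[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      n_skipped <- n_skipped + 1L
      next
    }
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//Article/ArticleTitle"))
    abstract <- paste(
      xml2::xml_text(xml2::xml_find_all(a, ".//Article/Abstract/AbstractText")),
      collapse = " "
    )
    ptype_nodes <- xml2::xml_find_all(a, ".//PublicationTypeList/PublicationType")
    ptype_uis <- xml2::xml_attr(ptype_nodes, "UI")
    ptype_text <- xml2::xml_text(ptype_nodes)
    mesh_uis <- xml2::xml_attr(
      xml2::xml_find_all(a, ".//MeshHeadingList/MeshHeading/DescriptorName"),
      "UI"
    )
    accessions <- xml2::xml_text(
      xml2::xml_find_all(a, ".//DataBankList/DataBank/AccessionNumberList/AccessionNumber")
    )
    e_date <- parse_medline_date(xml2::xml_find_first(a, ".//Article/ArticleDate"))
    p_date <- parse_medline_date(
      xml2::xml_find_first(a, ".//Article/Journal/JournalIssue/PubDate")
    )
    pub_types <- unique(stats::na.omit(c(ptype_uis, ptype_text)))
    is_rct <- any(pub_types %in% rct_descriptor_uis) ||
      "Randomized Controlled Trial" %in% ptype_text ||
      any(mesh_uis %in% rct_descriptor_uis)
    rows[[i]] <- list(
      record_id = pmid, title = title, abstract = abstract,
      publication_date = if (!is.na(e_date)) e_date else p_date,
      is_rct = is_rct,
      linked_registry_ids = sort(unique(grep("^NCT[0-9]{8}$", accessions,
                                             value = TRUE))),
      raw_publication_types = sort(pub_types),
      raw_mesh_uis = sort(unique(stats::na.omit(mesh_uis)))
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (n_skipped > 0L) {
    warning(n_skipped, " article(s) without PMID skipped", call. = FALSE)
  }
  rec <- evidence_records(
    record_id = vapply(rows, `[[`, character(1), "record_id"),
    source = "pubmed",
    title = vapply(rows, `[[`, character(1), "title"),
    publication_date = as.Date(
      vapply(rows, function(r) as.character(r$publication_date), character(1))
    ),
    is_rct = vapply(rows, `[[`, logical(1), "is_rct"),
    linked_registry_ids = lapply(rows, `[[`, "linked_registry_ids"),
    raw_publication_types = lapply(rows, `[[`, "raw_publication_types"),
    raw_mesh_uis = lapply(rows, `[[`, "raw_mesh_uis")
  )
  rec$abstract <- vapply(rows, `[[`, character(1), "abstract")
  attr(rec, "n_skipped") <- n_skipped
  rec
}

# Year/Month/Day children; month may be numeric or an English abbreviation.
parse_medline_date <- function(node) {
  if (inherits(node, "xml_missing") || is.na(xml2::xml_name(node))) {
    return(as.Date(NA))
  }
  year <- xml2::xml_text(xml2::xml_find_first(node, "./Year"))
  if (is.na(year) || !nzchar(year)) return(as.Date(NA))
  month <- xml2::xml_text(xml2::xml_find_first(node, "./Month"))
  day <- xml2::xml_text(xml2::xml_find_first(node, "./Day"))
  month <- if (is.na(month) || !nzchar(month)) "1" else month
  if (!grepl("^[0-9]+$", month)) {
    month <- as.character(match(tolower(substr(month, 1, 3)),
                                tolower(month.abb)))
  }
  day <- if (is.na(day) || !nzchar(day)) "1" else day
  as.Date(sprintf("%04d-%02d-%02d", as.integer(year), as.integer(month),
                  as.integer(day)))
}

#' Write evidence records as Medline-subset XML
#'
#' Inverse of [read_medline_xml()] for the documented subset: the fields a
#' Medline citation actually carries (identifier, title, abstract, dates,
#' publication types, MeSH descriptors, data-bank accessions) survive a
#' write/read round trip; harmonized fields derived by annotation (concept
#' sets, phase, significance) are not part of the format.
#'
#' @param records [evidence_records()], `source == "pubmed"`; an `abstract`
#'   column is written when present
#' @param path output file
#' @return invisibly, `path`
#' @export
write_medline_xml <- function(records, path) {
  stopifnot(all(records$source == "pubmed"))
  doc <- xml2::xml_new_root("PubmedArticleSet")
  abstracts <- if (!is.null(records$abstract)) records$abstract else
    rep("", nrow(records))
  for (i in seq_len(nrow(records))) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", records$record_id[i])
    a <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(a, "ArticleTitle",
                        if (is.na(records$title[i])) "" else records$title[i])
    if (nzchar(abstracts[i])) {
      ab <- xml2::xml_add_child(a, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", abstracts[i])
    }
    ptl <- xml2::xml_add_child(a, "PublicationTypeList")
    for (pt in records$raw_publication_types[[i]]) {
      node <- xml2::xml_add_child(ptl, "PublicationType", pt)
      if (grepl("^D[0-9]+$", pt)) xml2::xml_set_attr(node, "UI", pt)
    }
    d <- records$publication_date[i]
    if (!is.na(d)) {
      ad <- xml2::xml_add_child(a, "ArticleDate")
      xml2::xml_set_attr(ad, "DateType", "Electronic")
      xml2::xml_add_child(ad, "Year", format(d, "%Y"))
      xml2::xml_add_child(ad, "Month", format(d, "%m"))
      xml2::xml_add_child(ad, "Day", format(d, "%d"))
    }
    if (length(records$linked_registry_ids[[i]]) > 0L) {
      dbl <- xml2::xml_add_child(a, "DataBankList")
      db <- xml2::xml_add_child(dbl, "DataBank")
      xml2::xml_add_child(db, "DataBankName", "ClinicalTrials.gov")
      anl <- xml2::xml_add_child(db, "AccessionNumberList")
      for (acc in records$linked_registry_ids[[i]]) {
        xml2::xml_add_child(anl, "AccessionNumber", acc)
      }
    }
    if (length(records$raw_mesh_uis[[i]]) > 0L) {
      mhl <- xml2::xml_add_child(cit, "MeshHeadingList")
      for (ui in records$raw_mesh_uis[[i]]) {
        mh <- xml2::xml_add_child(mhl, "MeshHeading")
        dn <- xml2::xml_add_child(mh, "DescriptorName", ui)
        xml2::xml_set_attr(dn, "UI", ui)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read registry tables and a knowledge-base TSV into evidence records
#'
#' `registry_dir` must contain `studies.csv` (columns `nct_id`, `phase`,
#' `start_date`, `results_first_posted_date`, optional `brief_title`),
#' `conditions.csv` and `interventions.csv` (`nct_id`, `code`, `vocabulary`,
#' `term`), and `outcome_analyses.csv` (`nct_id`, `p_value`). Conditions map
#' to population concepts and interventions to intervention concepts through
#' the crosswalk; the significance flag is derived from the structured
#' outcome analyses via [significance_from_structured()].
#'
#' The knowledge-base TSV (`pokb_path`) has columns `assertion_id`,
#' `disease_code`, `phenotype_codes`, `therapy_codes` (pipe-joined
#' `VOCAB:code` tokens). Diseases and phenotypes both map to population
#' concepts, therapies to intervention concepts.
#'
#' Codes with no crosswalk entry are never guessed: they are skipped and
#' counted (attribute `n_unmapped`).
#'
#' @param registry_dir directory with the four registry CSVs (or `NULL`)
#' @param pokb_path knowledge-base TSV (or `NULL`)
#' @param crosswalk data frame with columns `vocabulary`, `code`, `cui`
#' @return [evidence_records()] with attribute `n_unmapped`
#' @export
read_coded_sources <- function(registry_dir = NULL, pokb_path = NULL,
                               crosswalk) {
  stopifnot(all(c("vocabulary", "code", "cui") %in% names(crosswalk)))
  unmapped <- 0L
  lookup <- function(vocab, code) {
    hit <- crosswalk$cui[crosswalk$vocabulary == vocab & crosswalk$code == code]
    if (length(hit) == 0L) {
      unmapped <<- unmapped + 1L
      return(character())
    }
    hit[1]
  }
  parts <- list()

  if (!is.null(registry_dir)) {
    read_req <- function(file, cols) {
      p <- file.path(registry_dir, file)
      df <- utils::read.csv(p, colClasses = "character")
      missing <- setdiff(cols, names(df))
      if (length(missing) > 0L) {
        stop(file, " is missing mandatory column: ", missing[1], call. = FALSE)
      }
      df
    }
    studies <- read_req("studies.csv",
                        c("nct_id", "phase", "start_date",
                          "results_first_posted_date"))
    conditions <- read_req("conditions.csv", c("nct_id", "code", "vocabulary"))
    interventions <- read_req("interventions.csv",
                              c("nct_id", "code", "vocabulary"))
    analyses <- read_req("outcome_analyses.csv", c("nct_id", "p_value"))
    map_codes <- function(df, id) {
      rows <- df[df$nct_id == id, , drop = FALSE]
      out <- character()
      for (j in seq_len(nrow(rows))) {
        out <- c(out, lookup(rows$vocabulary[j], rows$code[j]))
      }
      sort(unique(out))
    }
    sig <- function(id) {
      p <- suppressWarnings(as.numeric(analyses$p_value[analyses$nct_id == id]))
      significance_from_structured(p[!is.na(p)])
    }
    empty_as_na <- function(x) ifelse(nzchar(x), x, NA_character_)
    parts$registry <- evidence_records(
      record_id = studies$nct_id,
      source = "registry",
      title = if (!is.null(studies$brief_title)) studies$brief_title else NA,
      start_date = as.Date(empty_as_na(studies$start_date)),
      results_posted_date = as.Date(
        empty_as_na(studies$results_first_posted_date)),
      is_rct = TRUE,
      phase = parse_registry_phase(studies$phase),
      population_cuis = lapply(studies$nct_id, map_codes, df = conditions),
      intervention_cuis = lapply(studies$nct_id, map_codes, df = interventions),
      significance = vapply(studies$nct_id, sig, character(1))
    )
  }

  if (!is.null(pokb_path)) {
    pokb <- utils::read.delim(pokb_path, sep = "\t", colClasses = "character")
    missing <- setdiff(c("assertion_id", "disease_code", "phenotype_codes",
                         "therapy_codes"), names(pokb))
    if (length(missing) > 0L) {
      stop("knowledge-base table is missing mandatory column: ", missing[1],
           call. = FALSE)
    }
    map_tokens <- function(tokens) {
      tokens <- tokens[nzchar(tokens)]
      out <- character()
      for (tok in tokens) {
        vocab <- sub(":.*$", "", tok)
        code <- sub("^[^:]*:", "", tok)
        out <- c(out, lookup(vocab, code))
      }
      sort(unique(out))
    }
    split_pipe <- function(x) strsplit(ifelse(is.na(x), "", x), "|",
                                       fixed = TRUE)
    pop <- Map(function(d, ph) map_tokens(c(d, ph)),
               split_pipe(pokb$disease_code), split_pipe(pokb$phenotype_codes))
    parts$pokb <- evidence_records(
      record_id = pokb$assertion_id,
      source = "pokb",
      population_cuis = pop,
      intervention_cuis = lapply(split_pipe(pokb$therapy_codes), map_tokens)
    )
  }

  rec <- do.call(bind_records, unname(parts))
  attr(rec, "n_unmapped") <- unmapped
  rec
}

#' Read/write a machine-readable guideline document
#'
#' The JSON dialect is an object with `guideline_id`, `topic_id`, `version`,
#' `release_date` (ISO date) and `sections`: an ordered array of
#' `{type, text, mentions}` where `type` is `"recommendation"` or
#' `"background"` and each mention is `{cui, surface, start, end,
#' confidence, semantic_types}` with 0-based half-open character offsets
#' into the section text.
#'
#' @param path JSON file
#' @return object of class `guideline_document`
#' @export
read_guideline_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  sections <- lapply(raw$sections, function(s) {
    mentions <- lapply(s$mentions, function(m) {
      list(cui = as.character(m$cui),
           surface = as.character(m$surface %||% ""),
           start = as.integer(m$start), end = as.integer(m$end),
           confidence = as.numeric(m$confidence %||% 1),
           semantic_types = as.character(unlist(m$semantic_types)))
    })
    list(type = as.character(s$type), text = as.character(s$text %||% ""),
         mentions = mentions)
  })
  guideline_document(
    guideline_id = raw$guideline_id, topic_id = raw$topic_id,
    version = raw$version, release_date = raw$release_date,
    sections = sections
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct and validate a guideline document
#'
#' @param guideline_id,topic_id,version character scalars
#' @param release_date `Date` or ISO string (required)
#' @param sections list of `list(type, text, mentions)`; see
#'   [read_guideline_json()] for the mention fields
#' @return object of class `guideline_document`
#' @export
guideline_document <- function(guideline_id, topic_id, version, release_date,
                               sections = list()) {
  release_date <- as.Date(release_date)
  if (is.na(release_date)) stop("release_date is required", call. = FALSE)
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    if (!s$type %in% c("recommendation", "background")) {
      stop("section ", i, ": unknown section type '", s$type, "'",
           call. = FALSE)
    }
    n <- nchar(s$text)
    for (m in s$mentions) {
      if (is.na(m$start) || is.na(m$end) ||
          m$start < 0L || m$start >= m$end || m$end > n) {
        stop("section ", i, ": mention offsets [", m$start, ",", m$end,
             ") out of range for text of length ", n, call. = FALSE)
      }
      if (is.na(m$confidence) || m$confidence < 0 || m$confidence > 1) {
        stop("section ", i, ": mention confidence outside [0,1]",
             call. = FALSE)
      }
    }
  }
  structure(
    list(guideline_id = as.character(guideline_id),
         topic_id = as.character(topic_id),
         version = as.character(version),
         release_date = release_date,
         sections = sections),
    class = "guideline_document"
  )
}

#' @export
print.guideline_document <- function(x, ...) {
  cat("<guideline_document> ", x$guideline_id, " v", x$version, " (",
      format(x$release_date), "), ", length(x$sections), " sections\n",
      sep = "")
  invisible(x)
}

#' @rdname read_guideline_json
#' @param doc a `guideline_document`
#' @return `write_guideline_json()`: invisibly, `path`
#' @export
write_guideline_json <- function(doc, path) {
  stopifnot(inherits(doc, "guideline_document"))
  out <- list(
    guideline_id = doc$guideline_id, topic_id = doc$topic_id,
    version = doc$version, release_date = format(doc$release_date),
    sections = lapply(doc$sections, function(s) {
      list(type = s$type, text = s$text,
           mentions = lapply(s$mentions, function(m) {
             list(cui = m$cui, surface = m$surface, start = m$start,
                  end = m$end, confidence = m$confidence,
                  semantic_types = as.list(m$semantic_types))
           }))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a literature-screening log
#'
#' CSV with columns `ref_id`, `pmid`, `doi`, `title`, `year`, `duplicate`,
#' `ta_included`, `ft_included`, `already_in_guideline`, `manual_decision`
#' (`included`/`excluded`/`none`) and `is_rct`. `ta_included` /
#' `ft_included` are `true`/`false`/empty (empty = stage not reached or not
#' recorded; a log that starts at full-text screening simply leaves
#' `ta_included` empty throughout). Identifiers are normalized on read: PMIDs
#' to their digits, DOIs to lower case.
#'
#' @param path CSV file
#' @return object of class `screening_log` (a tibble). Contradictory
#'   decisions for the same reference (included and excluded at the same
#'   stage) raise a consistency error.
#' @export
read_screening_log <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  screening_log(df)
}

#' @rdname read_screening_log
#' @param df data frame with the documented columns
#' @export
screening_log <- function(df) {
  needed <- c("ref_id", "pmid", "doi", "title", "year", "duplicate",
              "ta_included", "ft_included", "already_in_guideline",
              "manual_decision", "is_rct")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("screening log is missing column: ", missing[1], call. = FALSE)
  }
  as_flag <- function(x) {
    x <- tolower(trimws(as.character(x)))
    out <- rep(NA, length(x))
    out[x %in% c("true", "1", "yes")] <- TRUE
    out[x %in% c("false", "0", "no")] <- FALSE
    out
  }
  log <- tibble::tibble(
    ref_id = as.character(df$ref_id),
    pmid = gsub("[^0-9]", "", as.character(df$pmid)),
    doi = tolower(trimws(as.character(df$doi))),
    title = as.character(df$title),
    year = as.character(df$year),
    duplicate = as_flag(df$duplicate) %in% TRUE,
    ta_included = as_flag(df$ta_included),
    ft_included = as_flag(df$ft_included),
    already_in_guideline = as_flag(df$already_in_guideline) %in% TRUE,
    manual_decision = ifelse(nzchar(trimws(df$manual_decision)),
                             tolower(trimws(df$manual_decision)), "none"),
    is_rct = as_flag(df$is_rct) %in% TRUE
  )
  bad <- setdiff(unique(log$manual_decision), c("included", "excluded", "none"))
  if (length(bad) > 0L) {
    stop("unknown manual_decision token: ", bad[1], call. = FALSE)
  }
  log$dedup_key <- screening_dedup_key(log)
  check_log_consistency(log)
  class(log) <- unique(c("screening_log", class(log)))
  log
}

# Dedup key: PMID if present, else DOI, else case-folded punctuation-stripped
# title plus year.
screening_dedup_key <- function(log) {
  norm_title <- tolower(gsub("[^a-z0-9 ]", "", tolower(log$title)))
  norm_title <- gsub(" +", " ", trimws(norm_title))
  ifelse(nzchar(log$pmid), sprintf("pmid:%s", log$pmid),
         ifelse(nzchar(log$doi), paste0("doi:", log$doi),
                paste0("title:", norm_title, ":", log$year)))
}

check_log_consistency <- function(log) {
  for (stage in c("ta_included", "ft_included")) {
    dec <- log[[stage]]
    keep <- !is.na(dec)
    if (!any(keep)) next
    tab <- table(log$dedup_key[keep], dec[keep])
    if (ncol(tab) < 2L) next
    conflict <- rownames(tab)[tab[, 1] > 0 & tab[, 2] > 0]
    if (length(conflict) > 0L) {
      stop("contradictory ", sub("_included", "", stage),
           " decisions for reference ", conflict[1], call. = FALSE)
    }
  }
  invisible(log)
}

#' @rdname read_screening_log
#' @param log a `screening_log`
#' @return `write_screening_log()`: invisibly, `path`
#' @export
write_screening_log <- function(log, path) {
  out <- as.data.frame(log[, c("ref_id", "pmid", "doi", "title", "year",
                               "duplicate", "ta_included", "ft_included",
                               "already_in_guideline", "manual_decision",
                               "is_rct")])
  for (col in c("duplicate", "ta_included", "ft_included",
                "already_in_guideline", "is_rct")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         ifelse(out[[col]], "true", "false"))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export search hits as a spreadsheet-compatible table
#'
#' One row per hit with columns `identifier`, `source`, `publication_date`,
#' `phase`, `title`, and one column per intervention
#' (`intervention_1`, `intervention_2`, ...) holding `CUI|CONTEXT_CLASS`
#' tokens, so a reviewer can see at a glance which trial interventions are
#' already recommended, merely mentioned, or absent from the guideline.
#'
#' @param hits a `search_hits` object from [apply_cascade()]
#' @param path output CSV
#' @return invisibly, `path`
#' @export
write_results_export <- function(hits, path) {
  ctx <- hits$intervention_contexts
  k <- max(0L, vapply(ctx, nrow, integer(1)))
  base <- data.frame(
    identifier = hits$record_id,
    source = hits$source,
    publication_date = as.character(hits$publication_date),
    phase = hits$phase,
    title = hits$title,
    stringsAsFactors = FALSE
  )
  if (k > 0L) {
    for (j in seq_len(k)) {
      base[[paste0("intervention_", j)]] <- vapply(ctx, function(cc) {
        if (nrow(cc) >= j) paste0(cc$cui[j], "|", cc$context[j]) else ""
      }, character(1))
    }
  }
  utils::write.csv(base, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a results export
#' @param path CSV written by [write_results_export()]
#' @return tibble with `identifier`, `source`, `publication_date`, `phase`,
#'   `title` and a list-column `interventions` of `(cui, context)` tibbles
#' @export
read_results_export <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  icols <- grep("^intervention_[0-9]+$", names(df), value = TRUE)
  interventions <- lapply(seq_len(nrow(df)), function(i) {
    toks <- unlist(df[i, icols], use.names = FALSE)
    toks <- toks[nzchar(toks)]
    tibble::tibble(cui = sub("\\|.*$", "", toks),
                   context = sub("^[^|]*\\|", "", toks))
  })
  tibble::tibble(
    identifier = df$identifier, source = df$source,
    publication_date = as.Date(ifelse(nzchar(df$publication_date),
                                      df$publication_date, NA)),
    phase = df$phase, title = df$title,
    interventions = interventions
  )
}

#' Lossless round trip for harmonized evidence records
#'
#' TSV serialization of the harmonized record table itself (as opposed to
#' the source formats): set-valued columns are pipe-joined. Used for caching
#' harmonized corpora and by the command-line interface.
#'
#' @param records [evidence_records()]
#' @param path TSV file
#' @return `write_records_tsv()`: invisibly, `path`;
#'   `read_records_tsv()`: [evidence_records()]
#' @export
write_records_tsv <- function(records, path) {
  join <- function(col) vapply(records[[col]], paste, character(1),
                               collapse = "|")
  out <- data.frame(
    record_id = records$record_id, source = records$source,
    title = records$title,
    publication_date = as.character(records$publication_date),
    start_date = as.character(records$start_date),
    results_posted_date = as.character(records$results_posted_date),
    is_rct = records$is_rct, phase = records$phase,
    population_cuis = join("population_cuis"),
    intervention_cuis = join("intervention_cuis"),
    significance = records$significance,
    linked_registry_ids = join("linked_registry_ids"),
    raw_publication_types = join("raw_publication_types"),
    raw_mesh_uis = join("raw_mesh_uis"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_records_tsv
#' @export
read_records_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character", na = "")
  split_pipe <- function(col) {
    x <- as.character(df[[col]])
    x[is.na(x)] <- ""
    lapply(strsplit(x, "|", fixed = TRUE), function(v) v[nzchar(v)])
  }
  evidence_records(
    record_id = df$record_id, source = df$source, title = df$title,
    publication_date = as.Date(df$publication_date),
    start_date = as.Date(df$start_date),
    results_posted_date = as.Date(df$results_posted_date),
    is_rct = df$is_rct == "TRUE", phase = df$phase,
    population_cuis = split_pipe("population_cuis"),
    intervention_cuis = split_pipe("intervention_cuis"),
    significance = df$significance,
    linked_registry_ids = split_pipe("linked_registry_ids"),
    raw_publication_types = split_pipe("raw_publication_types"),
    raw_mesh_uis = split_pipe("raw_mesh_uis")
  )
}

#' Per-source corpus statistics
#'
#' For each evidence source: document count, total population and
#' intervention concept occurrences (each record contributes the size of its
#' concept set), and the number of distinct concept identifiers across the
#' source. Guideline documents are summarized alongside: interventions are
#' mentions typed as pharmacologic substances or therapeutic procedures
#' (T121/T061), all other mentions count as population concepts.
#'
#' @param records [evidence_records()]
#' @param guidelines optional list of `guideline_document`s
#' @return tibble with one row per source
#' @export
corpus_statistics <- function(records, guidelines = NULL) {
  per_source <- function(src) {
    sub <- records[records$source == src, ]
    pop <- unlist(sub$population_cuis)
    int <- unlist(sub$intervention_cuis)
    tibble::tibble(
      source = src, documents = nrow(sub),
      population_total = length(pop),
      population_unique = length(unique(pop)),
      intervention_total = length(int),
      intervention_unique = length(unique(int))
    )
  }
  out <- do.call(rbind, lapply(c("pubmed", "registry", "pokb"), per_source))
  if (!is.null(guidelines) && length(guidelines) > 0L) {
    mentions <- do.call(rbind, lapply(guidelines, function(doc) {
      do.call(rbind, lapply(doc$sections, function(s) {
        do.call(rbind, lapply(s$mentions, function(m) {
          data.frame(cui = m$cui,
                     is_intervention = any(m$semantic_types %in%
                                             c("T121", "T061")),
                     stringsAsFactors = FALSE)
        }))
      }))
    }))
    if (is.null(mentions)) {
      mentions <- data.frame(cui = character(), is_intervention = logical())
    }
    pop <- mentions$cui[!(mentions$is_intervention %in% TRUE)]
    int <- mentions$cui[mentions$is_intervention %in% TRUE]
    out <- rbind(out, tibble::tibble(
      source = "guideline", documents = length(guidelines),
      population_total = length(pop),
      population_unique = length(unique(pop)),
      intervention_total = length(int),
      intervention_unique = length(unique(int))
    ))
  }
  out
}
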