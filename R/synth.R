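#' Synthetic-data generation
#'
#' Deterministic generators for concept graphs, harmonized corpora,
#' guideline versions and screening logs with *planted* structure: every
#' attribute a pipeline stage is supposed to recover (population match,
#' phase, significance, pediatric population, intervention context class,
#' relevance label) is assigned explicitly per record, so tests can verify
#' that each stage recovers exactly what was planted. All randomness flows
#' through a single seed; identical configurations produce identical output.
#'
#' @param seed integer seed
#' @param n_concepts number of graph nodes (>= 5)
#' @param n_topics number of guideline-topic seed concepts
#' @param n_records number of corpus records
#' @param frac_relevant,frac_irrelevant planted relevance fractions (the
#'   remainder has unknown relevance, i.e. never entered screening)
#' @param frac_population_match fraction of records whose population
#'   overlaps the topic expansion
#' @param frac_rct,frac_pediatric,frac_significant,frac_known_intervention,frac_unknown_intervention
#'   planted attribute fractions
#' @return a `synth_config` list
#' @export
synth_config <- function(seed = 1L, n_concepts = 60L, n_topics = 2L,
                         n_records = 120L,
                         frac_relevant = 0.2, frac_irrelevant = 0.5,
                         frac_population_match = 0.8,
                         frac_rct = 0.9, frac_pediatric = 0.1,
                         frac_significant = 0.3,
                         frac_known_intervention = 0.5,
                         frac_unknown_intervention = 0.5) {
  stopifnot(n_concepts >= 5L, frac_relevant + frac_irrelevant <= 1)
  structure(as.list(environment()), class = "synth_config")
}

# evaluate expr under a local RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random concept DAG with topic seeds
#'
#' Nodes are created in order and each node after the first draws one or two
#' parents among earlier nodes, so the graph is acyclic by construction and
#' has multi-parent nodes (overlapping topic subtrees). Semantic types are
#' sampled from a small palette of disease, substance and procedure tokens;
#' some concepts carry no type. Topic seeds are upper-level nodes; a
#' dedicated pediatric concept subtree is included for the child-exclusion
#' filter.
#'
#' @param config a [synth_config()]
#' @return list with `graph` ([concept_graph()]), `topic_seeds` (named list
#'   of seed CUIs per topic) and `pediatric_seeds`
#' @export
generate_graph <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_concepts
    cui <- sprintf("C%04d", seq_len(n))
    palette <- list("T047", "T121", "T061", c("T047", "T191"), character(0))
    types <- vapply(sample.int(length(palette), n, replace = TRUE),
                    function(i) paste(palette[[i]], collapse = "|"),
                    character(1))
    # reserve typed roles at the top of the id range: three intervention
    # concepts (used by the corpus generator) and one pediatric concept
    if (n >= 5L) {
      types[(n - 3L):(n - 1L)] <- c("T061", "T121", "T121")
      types[n] <- "T047"
    }
    concepts <- data.frame(cui = cui,
                           preferred_term = paste0("term ", tolower(cui)),
                           semantic_types = types,
                           stringsAsFactors = FALSE)
    edges <- NULL
    if (n > 2L) {
      child <- character()
      parent <- character()
      # the last node (the pediatric concept) stays a root so that pediatric
      # populations never fall inside a topic expansion by accident
      for (i in 2:(n - 1L)) {
        k <- sample(1:min(2L, i - 1L), 1L)
        for (p in sample.int(i - 1L, k)) {
          child <- c(child, cui[i])
          parent <- c(parent, cui[p])
        }
      }
      edges <- data.frame(child_cui = child, parent_cui = parent,
                          stringsAsFactors = FALSE)
    }
    graph <- concept_graph(concepts, edges)
    n_top <- min(config$n_topics, n - 1L)
    topic_seeds <- stats::setNames(
      as.list(cui[seq_len(n_top) + 1L]),
      paste0("topic_", seq_len(n_top))
    )
    list(graph = graph, topic_seeds = topic_seeds,
         pediatric_seeds = cui[n])
  })
}

#' Generate a corpus with planted filter attributes
#'
#' Each record's attributes follow a planted table drawn once from the
#' configured fractions; the corpus (records, two guideline versions, a
#' screening log, mention index, pediatric set and stoplist) is then
#' constructed so that every planted attribute holds by construction:
#' population-matching records carry a concept from the topic expansion,
#' "known intervention" records carry a concept mentioned in the new
#' guideline version, and so on. Relevance labels drive the screening log
#' (relevant: included at full text; irrelevant: excluded; unknown: never
#' screened).
#'
#' @param config a [synth_config()]
#' @param graph_bundle a [generate_graph()] result
#' @return list with `records`, `planted` (the attribute table),
#'   `guideline_old`, `guideline_new`, `index`, `population`,
#'   `pediatric_cuis`, `stoplist`, `log`, `lexicon`, `crosswalk`
#' @export
generate_corpus <- function(config, graph_bundle) {
  stopifnot(inherits(config, "synth_config"))
  graph <- graph_bundle$graph
  topic_id <- names(graph_bundle$topic_seeds)[1]
  population <- expand_population(graph, topic_id,
                                  graph_bundle$topic_seeds[[1]])
  pediatric_cuis <- descendant_closure(graph, graph_bundle$pediatric_seeds)

  all_cuis <- graph$concepts$cui
  n_all <- length(all_cuis)
  stopifnot(n_all >= 5L)
  # the three reserved intervention concepts (see generate_graph)
  generic_cui <- all_cuis[n_all - 3L]
  new_cui <- all_cuis[n_all - 2L]
  known_cui <- all_cuis[n_all - 1L]
  reserved <- c(generic_cui, new_cui, known_cui, pediatric_cuis)
  pop_pool <- setdiff(population$expanded_cuis, reserved)
  if (length(pop_pool) == 0L) pop_pool <- population$expanded_cuis
  off_pool <- setdiff(all_cuis, c(population$expanded_cuis, reserved))
  if (length(off_pool) == 0L) off_pool <- all_cuis[1]
  stoplist <- generic_cui

  with_seed(config$seed + 1L, {
    n <- config$n_records
    lab <- sample(c("relevant", "irrelevant", "unknown"), n, replace = TRUE,
                  prob = c(config$frac_relevant, config$frac_irrelevant,
                           1 - config$frac_relevant - config$frac_irrelevant))
    planted <- tibble::tibble(
      record_id = sprintf("%07d", 1000000L + seq_len(n)),
      source = rep_len(c("pubmed", "pubmed", "registry", "pokb"), n),
      relevance = lab,
      population_match = stats::runif(n) < config$frac_population_match,
      is_rct = stats::runif(n) < config$frac_rct,
      phase = sample(c(PHASE_LEVELS, "UNKNOWN"), n, replace = TRUE),
      pediatric = stats::runif(n) < config$frac_pediatric,
      significant = stats::runif(n) < config$frac_significant,
      known_intervention = stats::runif(n) < config$frac_known_intervention,
      unknown_intervention = stats::runif(n) < config$frac_unknown_intervention
    )
    planted$record_id[planted$source == "registry"] <- sprintf(
      "NCT%08d", which(planted$source == "registry"))
    planted$record_id[planted$source == "pokb"] <- sprintf(
      "AID%05d", which(planted$source == "pokb"))

    pop_sets <- lapply(seq_len(n), function(i) {
      base <- if (planted$population_match[i]) {
        sample(pop_pool, 1L)
      } else {
        sample(off_pool, 1L)
      }
      if (planted$pediatric[i]) c(base, pediatric_cuis[1]) else base
    })
    int_sets <- lapply(seq_len(n), function(i) {
      out <- generic_cui
      if (planted$known_intervention[i]) out <- c(out, known_cui)
      if (planted$unknown_intervention[i]) out <- c(out, new_cui)
      sort(out)
    })
    dates <- as.Date("2020-01-01") + sample.int(730L, n, replace = TRUE)

    records <- evidence_records(
      record_id = planted$record_id,
      source = planted$source,
      title = paste("Synthetic trial report", seq_len(n)),
      publication_date = as.Date(ifelse(planted$source == "pubmed",
                                        as.character(dates), NA)),
      start_date = dates - 365L,
      results_posted_date = as.Date(ifelse(planted$source == "registry",
                                           as.character(dates), NA)),
      is_rct = planted$is_rct,
      phase = planted$phase,
      population_cuis = pop_sets,
      intervention_cuis = int_sets,
      significance = ifelse(planted$significant, "SIGNIFICANT",
                            "NOT_SIGNIFICANT")
    )

    # the "current" version recommends only the known intervention; the
    # updated version newly recommends the novel one. The search context
    # (mention index) reflects current practice, i.e. the old version.
    guideline_old <- synth_guideline(
      guideline_id = topic_id, topic_id = topic_id, version = "1.0",
      release_date = as.Date("2019-06-01"),
      recommendation_cuis = known_cui, background_cuis = pop_pool[1]
    )
    guideline_new <- synth_guideline(
      guideline_id = topic_id, topic_id = topic_id, version = "2.0",
      release_date = as.Date("2023-06-01"),
      recommendation_cuis = c(known_cui, new_cui),
      background_cuis = pop_pool[1]
    )
    index <- build_mention_index(guideline_old)

    log <- synth_screening_log(planted)
    lexicon <- data.frame(
      term = paste0("term ", tolower(all_cuis)),
      cui = all_cuis,
      stringsAsFactors = FALSE
    )
    crosswalk <- data.frame(
      vocabulary = "SYN",
      code = all_cuis,
      cui = all_cuis,
      stringsAsFactors = FALSE
    )
    list(records = records, planted = planted,
         guideline_old = guideline_old, guideline_new = guideline_new,
         index = index, population = population,
         pediatric_cuis = pediatric_cuis, stoplist = stoplist, log = log,
         lexicon = lexicon, crosswalk = crosswalk)
  })
}

# guideline with one recommendation and one background section whose mention
# offsets point at the listed concept terms
synth_guideline <- function(guideline_id, topic_id, version, release_date,
                            recommendation_cuis, background_cuis = character(),
                            confidences = NULL) {
  section_for <- function(type, cuis, confs) {
    terms <- paste0("term ", tolower(cuis))
    text <- paste(terms, collapse = "; ")
    starts <- cumsum(c(0L, utils::head(nchar(terms) + 2L, -1L)))
    mentions <- lapply(seq_along(cuis), function(i) {
      list(cui = cuis[i], surface = terms[i], start = starts[i],
           end = starts[i] + nchar(terms[i]), confidence = confs[i],
           semantic_types = character(0))
    })
    list(type = type, text = text, mentions = mentions)
  }
  sections <- list()
  if (length(recommendation_cuis) > 0L) {
    confs <- if (is.null(confidences)) rep(1, length(recommendation_cuis)) else
      rep_len(confidences, length(recommendation_cuis))
    sections <- c(sections, list(section_for("recommendation",
                                             recommendation_cuis, confs)))
  }
  if (length(background_cuis) > 0L) {
    sections <- c(sections, list(section_for("background", background_cuis,
                                             rep(1, length(background_cuis)))))
  }
  guideline_document(guideline_id, topic_id, version, release_date, sections)
}

# screening log derived from planted relevance labels
synth_screening_log <- function(planted) {
  screened <- planted[planted$relevance != "unknown", , drop = FALSE]
  n <- nrow(screened)
  if (n == 0L) {
    cols <- c("ref_id", "pmid", "doi", "title", "year", "duplicate",
              "ta_included", "ft_included", "already_in_guideline",
              "manual_decision", "is_rct")
    empty <- as.data.frame(stats::setNames(
      replicate(length(cols), character(), simplify = FALSE), cols))
    return(screening_log(empty))
  }
  df <- data.frame(
    ref_id = paste0("R", screened$record_id),
    pmid = screened$record_id,
    doi = "",
    title = paste("Synthetic trial report", screened$record_id),
    year = "2021",
    duplicate = "false",
    ta_included = "true",
    ft_included = ifelse(screened$relevance == "relevant", "true", "false"),
    already_in_guideline = "false",
    manual_decision = "none",
    is_rct = ifelse(screened$is_rct, "true", "false"),
    stringsAsFactors = FALSE
  )
  screening_log(df)
}

#' Write a synthetic corpus to disk in the documented source formats
#'
#' Emits the concept-graph tables, the publication subset as Medline XML
#' (with templated abstracts that the dictionary annotator can re-annotate),
#' registry CSV tables, the knowledge-base TSV, both guideline versions as
#' JSON, the screening log, the lexicon, the crosswalk and the full
#' harmonized record table.
#'
#' @param corpus a [generate_corpus()] result
#' @param graph_bundle the matching [generate_graph()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of written paths
#' @export
write_corpus <- function(corpus, graph_bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "registry"), showWarnings = FALSE)
  paths <- character()
  w <- function(p) {
    paths <<- c(paths, p)
    p
  }

  write_concept_graph(graph_bundle$graph,
                      w(file.path(dir, "concepts.tsv")),
                      w(file.path(dir, "hierarchy.tsv")))

  rec <- corpus$records
  pub <- rec[rec$source == "pubmed", , drop = FALSE]
  pub$abstract <- vapply(seq_len(nrow(pub)), function(i) {
    pops <- paste0("term ", tolower(pub$population_cuis[[i]]), collapse = ", ")
    ints <- paste0("term ", tolower(pub$intervention_cuis[[i]]),
                   collapse = ", ")
    paste0("PATIENTS: ", pops, ". INTERVENTION: ", ints, ".")
  }, character(1))
  pub$raw_publication_types <- lapply(pub$is_rct, function(r) {
    if (r) c("D016449", "Randomized Controlled Trial") else "Journal Article"
  })
  write_medline_xml(pub, w(file.path(dir, "pubmed.xml")))

  reg <- rec[rec$source == "registry", , drop = FALSE]
  reg_phase_str <- c(EARLY_1 = "Early Phase 1", P1 = "Phase 1",
                     P1_2 = "Phase 1/Phase 2", P2 = "Phase 2",
                     P2_3 = "Phase 2/Phase 3", P3 = "Phase 3", P4 = "Phase 4",
                     UNKNOWN = "N/A")
  utils::write.csv(data.frame(
    nct_id = reg$record_id,
    phase = unname(reg_phase_str[reg$phase]),
    start_date = as.character(reg$start_date),
    results_first_posted_date = as.character(reg$results_posted_date),
    brief_title = reg$title
  ), w(file.path(dir, "registry", "studies.csv")), row.names = FALSE, na = "")
  code_rows <- function(id, sets) {
    codes <- as.character(unlist(sets))
    data.frame(nct_id = rep(id, lengths(sets)),
               code = codes,
               vocabulary = rep("SYN", length(codes)),
               term = sprintf("term %s", tolower(codes)),
               stringsAsFactors = FALSE)
  }
  utils::write.csv(code_rows(reg$record_id, reg$population_cuis),
                   w(file.path(dir, "registry", "conditions.csv")),
                   row.names = FALSE)
  utils::write.csv(code_rows(reg$record_id, reg$intervention_cuis),
                   w(file.path(dir, "registry", "interventions.csv")),
                   row.names = FALSE)
  utils::write.csv(data.frame(
    nct_id = reg$record_id,
    p_value = ifelse(reg$significance == "SIGNIFICANT", "0.01", "0.50")
  ), w(file.path(dir, "registry", "outcome_analyses.csv")),
  row.names = FALSE)

  kb <- rec[rec$source == "pokb", , drop = FALSE]
  utils::write.table(data.frame(
    assertion_id = kb$record_id,
    disease_code = vapply(kb$population_cuis, function(x) {
      if (length(x) > 0L) paste0("SYN:", x[1]) else ""
    }, character(1)),
    phenotype_codes = vapply(kb$population_cuis, function(x) {
      if (length(x) > 1L) paste(paste0("SYN:", x[-1]), collapse = "|") else ""
    }, character(1)),
    therapy_codes = vapply(kb$intervention_cuis, function(x) {
      paste(paste0("SYN:", x), collapse = "|")
    }, character(1))
  ), w(file.path(dir, "pokb.tsv")), sep = "\t", quote = FALSE,
  row.names = FALSE)

  write_guideline_json(corpus$guideline_old,
                       w(file.path(dir, "guideline_old.json")))
  write_guideline_json(corpus$guideline_new,
                       w(file.path(dir, "guideline_new.json")))
  write_screening_log(corpus$log, w(file.path(dir, "screening_log.csv")))
  utils::write.table(corpus$lexicon, w(file.path(dir, "lexicon.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$crosswalk, w(file.path(dir, "crosswalk.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_records_tsv(rec, w(file.path(dir, "records.tsv")))
  invisible(paths)
}

#' Deterministic time-lag corpus with planted lags
#'
#' Builds, for each planted lag pair, one intervention concept with a single
#' trial whose start and publication dates are placed so that the
#' publication-to-recommendation and start-to-publication lags equal the
#' planted values exactly (lags in 365.25-day years; day counts are rounded
#' to whole days, so plant lags that are multiples of 0.004 years or accept
#' sub-day rounding).
#'
#' @param start_to_pub_years,pub_to_rec_years numeric vectors of equal
#'   length: planted lags per intervention
#' @param has_phase3 logical vector: whether the intervention's trial is
#'   phase III (default all `TRUE`)
#' @param recommendation_date release date of the new guideline version
#' @return list with `corpus` ([evidence_records()]), `guideline_old`,
#'   `guideline_new`, `graph`, `new_cuis` and `planted` (the lag table)
#' @export
generate_lag_corpus <- function(start_to_pub_years, pub_to_rec_years,
                                has_phase3 = TRUE,
                                recommendation_date = as.Date("2024-01-01")) {
  k <- length(start_to_pub_years)
  stopifnot(length(pub_to_rec_years) == k)
  has_phase3 <- rep_len(has_phase3, k)
  cuis <- sprintf("CLAG%03d", seq_len(k))
  pub_dates <- recommendation_date - round(pub_to_rec_years * 365.25)
  start_dates <- pub_dates - round(start_to_pub_years * 365.25)

  concepts <- data.frame(
    cui = c(cuis, "CPOPX"),
    preferred_term = c(paste0("new intervention ", seq_len(k)), "population"),
    semantic_types = c(rep("T121", k), "T047"),
    stringsAsFactors = FALSE
  )
  graph <- concept_graph(concepts)
  records <- evidence_records(
    record_id = sprintf("NCT%08d", seq_len(k)),
    source = "registry",
    title = paste("Planted lag trial", seq_len(k)),
    publication_date = pub_dates,
    start_date = start_dates,
    is_rct = TRUE,
    phase = ifelse(has_phase3, "P3", "P2"),
    population_cuis = replicate(k, "CPOPX", simplify = FALSE),
    intervention_cuis = as.list(cuis)
  )
  guideline_old <- synth_guideline("lag-topic", "lag-topic", "1.0",
                                   recommendation_date - 1460,
                                   recommendation_cuis = "CPOPX")
  guideline_new <- synth_guideline("lag-topic", "lag-topic", "2.0",
                                   recommendation_date,
                                   recommendation_cuis = c("CPOPX", cuis))
  planted <- tibble::tibble(
    cui = cuis,
    start_to_pub_years = as.numeric(pub_dates - start_dates) / 365.25,
    pub_to_rec_years = as.numeric(recommendation_date - pub_dates) / 365.25,
    has_phase3 = has_phase3
  )
  list(corpus = records, guideline_old = guideline_old,
       guideline_new = guideline_new, graph = graph, new_cuis = cuis,
       planted = planted)
}
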