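#' Bundled guideline-update evaluation benchmarks
#'
#' Constructs, fully in code and deterministically, the two benchmark
#' configurations used to evaluate signal retrieval: the completed
#' oesophageal-cancer guideline update and the ongoing Hodgkin-lymphoma
#' update. Each benchmark consists of a screening log replaying the
#' documented stage counts of the respective literature screening process
#' (e.g. 3147 screened references, 139 duplicates and 35 finally included
#' RCTs for the oesophageal update), a harmonized publication corpus whose
#' planted phase / significance / pediatric / intervention-context
#' attributes reproduce the published filter-cascade confusion counts, and
#' the query ladder, mention index, pediatric concept set and stoplist the
#' cascade needs. The construction is assignment, not sampling: the planted
#' counts are the benchmark.
#'
#' The screening logs are synthetic reconstructions: they reproduce the
#' published bookkeeping of the real (non-redistributable) screening
#' exports, with opaque synthetic identifiers.
#'
#' @return named list with elements `oesophageal` and `hodgkin`; each is a
#'   list with `log` ([screening_log()]), `records` ([evidence_records()]),
#'   `graph`, `population`, `index`, `pediatric_cuis`, `stoplist` and
#'   `ladder` (named list of nested [filter_query()] steps).
#' @export
benchmark_fixtures <- function() {
  graph <- concept_graph(
    data.frame(
      cui = c("C0TOPIC", "C0SUB", "C0OTHER", "C0PED",
              "C1KNOWN", "C1NEW", "C1GEN"),
      preferred_term = c("topic population", "topic subpopulation",
                         "unrelated population", "child",
                         "recommended drug", "novel drug",
                         "generic treatment"),
      semantic_types = c("T047", "T047", "T047", "T047",
                         "T121", "T121", "T061"),
      stringsAsFactors = FALSE
    ),
    data.frame(child_cui = "C0SUB", parent_cui = "C0TOPIC",
               stringsAsFactors = FALSE)
  )
  pediatric_cuis <- descendant_closure(graph, "C0PED")
  stoplist <- "C1GEN"

  list(
    oesophageal = oesophageal_benchmark(graph, pediatric_cuis, stoplist),
    hodgkin = hodgkin_benchmark(graph, pediatric_cuis, stoplist)
  )
}

# nested query ladder shared by both benchmarks
benchmark_ladder <- function(population, date_min, date_max) {
  q <- function(...) {
    filter_query(population, date_min = date_min, date_max = date_max,
                 sources = "pubmed", rct_only = TRUE, ...)
  }
  list(
    all_rcts = q(),
    phase_ge_2 = q(min_phase = "P2"),
    phase_ge_3 = q(min_phase = "P3"),
    excl_children = q(min_phase = "P3", exclude_children = TRUE),
    significant = q(min_phase = "P3", exclude_children = TRUE,
                    significant_only = TRUE),
    known_intervention = q(min_phase = "P3", exclude_children = TRUE,
                           significant_only = TRUE,
                           require_known_intervention = TRUE),
    unknown_intervention = q(min_phase = "P3", exclude_children = TRUE,
                             significant_only = TRUE,
                             require_known_intervention = TRUE,
                             require_unknown_intervention = TRUE)
  )
}

benchmark_index <- function(guideline_id, topic_id) {
  mention_index(guideline_id, topic_id,
                recommendation_cuis = "C1KNOWN",
                anywhere_cuis = c("C1KNOWN", "C1GEN"))
}

# log-row builder: one block of references sharing the same decisions
log_block <- function(pmids, ref_prefix, ta, ft, aig = FALSE,
                      manual = "none", rct = FALSE, duplicate = FALSE) {
  n <- length(pmids)
  if (n == 0L) return(NULL)
  data.frame(
    ref_id = paste0(ref_prefix, seq_len(n)),
    pmid = pmids,
    doi = "",
    title = paste("Reference", pmids),
    year = "2021",
    duplicate = if (duplicate) "true" else "false",
    ta_included = ta,
    ft_included = ft,
    already_in_guideline = if (aig) "true" else "false",
    manual_decision = manual,
    is_rct = if (rct) "true" else "false",
    stringsAsFactors = FALSE
  )
}

# record-block builder for the planted corpora
record_block <- function(pmids, phase, significance, interventions,
                         population, date) {
  n <- length(pmids)
  if (n == 0L) return(NULL)
  evidence_records(
    record_id = pmids,
    source = "pubmed",
    title = paste("Trial report", pmids),
    publication_date = date,
    is_rct = TRUE,
    phase = phase,
    population_cuis = replicate(n, population, simplify = FALSE),
    intervention_cuis = replicate(n, interventions, simplify = FALSE),
    significance = significance,
    raw_publication_types = replicate(n, "D016449", simplify = FALSE)
  )
}

pmid_seq <- function(base, from, to) {
  if (to < from) return(character())
  as.character(base + seq(from, to))
}

oesophageal_benchmark <- function(graph, pediatric_cuis, stoplist) {
  # identifier blocks: 5e6 relevant, 6e6 irrelevant, 7e6 unknown-relevance,
  # 4e6 never-RCT screening bulk
  rel <- function(a, b) pmid_seq(5000000, a, b)
  irr <- function(a, b) pmid_seq(6000000, a, b)
  unk <- function(a, b) pmid_seq(7000000, a, b)
  bulk <- function(base, a, b) pmid_seq(base, a, b)

  log <- do.call(rbind, list(
    # 139 duplicate rows (same references exported from a second source)
    log_block(bulk(4000000, 1, 139), "dup", ta = "", ft = "",
              duplicate = TRUE),
    # title-abstract exclusions: 190 RCTs + 2551 other
    log_block(irr(1, 190), "taR", ta = "false", ft = "", rct = TRUE),
    log_block(bulk(4000000, 1, 2551), "ta", ta = "false", ft = ""),
    # full-text exclusions: 100 RCTs + 86 other + 9 already-in-guideline
    log_block(irr(191, 290), "ftR", ta = "true", ft = "false", rct = TRUE),
    log_block(bulk(4100000, 10, 95), "ft", ta = "true", ft = "false"),
    log_block(bulk(4100000, 1, 9), "aig", ta = "true", ft = "false",
              aig = TRUE),
    # full-text inclusions: 26 RCTs + 46 other
    log_block(rel(1, 26), "incR", ta = "true", ft = "true", rct = TRUE),
    log_block(bulk(4200000, 1, 46), "inc", ta = "true", ft = "true"),
    # manual review of system results (RCTs after phase II)
    log_block(rel(27, 35), "manI", ta = "", ft = "", manual = "included",
              rct = TRUE),
    log_block(irr(291, 296), "manE", ta = "", ft = "", manual = "excluded",
              rct = TRUE)
  ))

  d <- as.Date("2020-06-15")
  pop <- "C0SUB"
  records <- bind_records(
    # relevant retrieved (31): 4 below phase II, 7 phase II, 20 phase III
    record_block(rel(1, 4), "P1", "UNKNOWN", "C1GEN", pop, d),
    record_block(rel(5, 11), "P2", "UNKNOWN", "C1GEN", pop, d),
    record_block(rel(12, 16), "P3", "NOT_SIGNIFICANT", "C1GEN", pop, d),
    record_block(rel(17, 17), "P3", "SIGNIFICANT", "C1NEW", pop, d),
    record_block(rel(18, 18), "P3", "SIGNIFICANT", "C1KNOWN", pop, d),
    record_block(rel(19, 19), "P3", "SIGNIFICANT", c("C1GEN", "C1KNOWN"),
                 pop, d),
    record_block(rel(20, 31), "P3", "SIGNIFICANT", c("C1KNOWN", "C1NEW"),
                 pop, d),
    # irrelevant retrieved (146)
    record_block(irr(1, 79), "P1", "UNKNOWN", "C1GEN", pop, d),
    record_block(irr(80, 111), "P2", "UNKNOWN", "C1GEN", pop, d),
    record_block(irr(112, 124), "P3", "NOT_SIGNIFICANT", "C1GEN", pop, d),
    record_block(irr(125, 129), "P3", "SIGNIFICANT", "C1NEW", pop, d),
    record_block(irr(130, 130), "P3", "SIGNIFICANT", "C1KNOWN", pop, d),
    record_block(irr(131, 146), "P3", "SIGNIFICANT", c("C1KNOWN", "C1NEW"),
                 pop, d),
    # retrieved results of unknown relevance (32), all early phase
    record_block(unk(1, 32), "P1", "UNKNOWN", "C1GEN", pop, d),
    # relevant but not retrievable: population never extracted (4)
    record_block(rel(32, 35), "P3", "SIGNIFICANT", c("C1KNOWN", "C1NEW"),
                 "C0OTHER", d)
  )

  population <- expand_population(graph, "oesophageal", "C0TOPIC")
  list(
    topic = "oesophageal",
    log = screening_log(log),
    records = records,
    graph = graph,
    population = population,
    index = benchmark_index("oesophageal-guideline", "oesophageal"),
    pediatric_cuis = pediatric_cuis,
    stoplist = stoplist,
    ladder = benchmark_ladder(population, as.Date("2019-01-09"),
                              as.Date("2022-04-03"))
  )
}

hodgkin_benchmark <- function(graph, pediatric_cuis, stoplist) {
  rel <- function(a, b) pmid_seq(8000000, a, b)
  irr <- function(a, b) pmid_seq(9000000, a, b)
  unk <- function(a, b) pmid_seq(9500000, a, b)
  bulk <- function(base, a, b) pmid_seq(base, a, b)

  # this log starts at full-text screening: title-abstract decisions were
  # not recorded, so ta_included stays empty throughout
  log <- do.call(rbind, list(
    # full-text exclusions: 24 RCTs + 79 other + 2 already-in-guideline
    log_block(irr(1, 24), "ftR", ta = "", ft = "false", rct = TRUE),
    log_block(bulk(9700000, 1, 79), "ft", ta = "", ft = "false"),
    log_block(bulk(9600000, 1, 2), "aig", ta = "", ft = "false", aig = TRUE),
    # full-text inclusions: 25 RCTs + 38 other
    log_block(rel(1, 25), "incR", ta = "", ft = "true", rct = TRUE),
    log_block(bulk(9800000, 1, 38), "inc", ta = "", ft = "true"),
    # manual review of system results
    log_block(rel(26, 31), "manI", ta = "", ft = "", manual = "included",
              rct = TRUE),
    log_block(irr(25, 35), "manE", ta = "", ft = "", manual = "excluded",
              rct = TRUE),
    # system results already cited in the current guideline version
    log_block(rel(32, 40), "raig", ta = "", ft = "", aig = TRUE, rct = TRUE)
  ))

  d <- as.Date("2020-06-15")
  pop <- "C0SUB"
  ped <- c("C0SUB", "C0PED")
  records <- bind_records(
    # relevant retrieved (40): 8 below phase II, 8 phase II, 24 phase III
    record_block(rel(1, 8), "P1", "UNKNOWN", "C1GEN", pop, d),
    record_block(rel(9, 16), "P2", "UNKNOWN", "C1GEN", pop, d),
    record_block(rel(17, 17), "P3", "NOT_SIGNIFICANT", "C1GEN", ped, d),
    record_block(rel(18, 27), "P3", "SIGNIFICANT", c("C1KNOWN", "C1NEW"),
                 pop, d),
    record_block(rel(28, 40), "P3", "NOT_SIGNIFICANT", "C1GEN", pop, d),
    # irrelevant retrieved (15)
    record_block(irr(1, 2), "P1", "UNKNOWN", "C1GEN", pop, d),
    record_block(irr(3, 11), "P2", "UNKNOWN", "C1GEN", pop, d),
    record_block(irr(12, 13), "P3", "NOT_SIGNIFICANT", "C1GEN", ped, d),
    record_block(irr(14, 15), "P3", "NOT_SIGNIFICANT", "C1GEN", pop, d),
    # retrieved results of unknown relevance (25), all early phase
    record_block(unk(1, 25), "P1", "UNKNOWN", "C1GEN", pop, d)
  )

  population <- expand_population(graph, "hodgkin", "C0TOPIC")
  list(
    topic = "hodgkin",
    log = screening_log(log),
    records = records,
    graph = graph,
    population = population,
    index = benchmark_index("hodgkin-guideline", "hodgkin"),
    pediatric_cuis = pediatric_cuis,
    stoplist = stoplist,
    ladder = benchmark_ladder(population, as.Date("2016-01-01"),
                              as.Date("2023-01-06"))
  )
}
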