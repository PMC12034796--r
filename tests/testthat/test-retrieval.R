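test_that("phase thresholds promote mixed designations and fail UNKNOWN", {
  expect_true(phase_at_least("P1_2", "P2"))
  expect_true(phase_at_least("P2_3", "P3"))
  expect_false(phase_at_least("P2", "P3"))
  expect_false(phase_at_least("UNKNOWN", "EARLY_1"))
  expect_true(all(phase_at_least(PHASE_LEVELS, "EARLY_1")))
  expect_equal(parse_registry_phase(c("PHASE3", "Early Phase 1", "N/A",
                                      "Phase 2/Phase 3")),
               c("P3", "EARLY_1", "UNKNOWN", "P2_3"))
})

test_that("population matching is set intersection with the expansion", {
  g <- tiny_graph()
  pop <- expand_population(g, "t", "B")
  expect_equal(match_population(c("E"), pop), character())
  # a record coded with a descendant of the seed is retrieved
  expect_equal(match_population(c("D", "E"), pop), "D")
})

test_that("an unfiltered query retrieves all dated source-matching records", {
  cfg <- synth_config(seed = 31, n_records = 80)
  gb <- generate_graph(cfg)
  co <- generate_corpus(cfg, gb)
  full <- expand_population(gb$graph, co$population$topic_id,
                            gb$graph$concepts$cui) # whole universe
  q <- filter_query(full)
  hits <- apply_cascade(co$records, q, index = co$index)
  expect_equal(sort(hits$record_id), sort(co$records$record_id))
  # every population in the universe matches, nothing else filters
  expect_true(all(vapply(hits$matched_population_cuis, length,
                         integer(1)) > 0))
})

test_that("the cascade equals the independent per-record predicate oracle", {
  set.seed(99)
  for (rep in 1:5) {
    cfg <- synth_config(seed = 100 + rep, n_records = 60)
    gb <- generate_graph(cfg)
    co <- generate_corpus(cfg, gb)
    mp <- sample(c(NA, "P2", "P3"), 1)
    q <- filter_query(
      co$population,
      date_min = if (rep %% 2) as.Date("2020-03-01") else NULL,
      date_max = as.Date("2021-10-01"),
      sources = sample(c("pubmed", "registry", "pokb"), sample(1:3, 1)),
      rct_only = rep %% 2 == 0,
      min_phase = if (is.na(mp)) NULL else mp,
      exclude_children = rep %% 2 == 1,
      significant_only = rep %% 3 == 0,
      require_known_intervention = rep %% 2 == 0,
      require_unknown_intervention = rep %% 3 == 1
    )
    hits <- apply_cascade(co$records, q, index = co$index,
                          pediatric_cuis = co$pediatric_cuis,
                          stoplist = co$stoplist)
    expect_equal(sort(hits$record_id),
                 cascade_oracle(co$records, q, co$index, co$pediatric_cuis,
                                co$stoplist))
    # every hit satisfies every active predicate (re-check via oracle on the
    # hit subset)
    expect_equal(cascade_oracle(hits, q, co$index, co$pediatric_cuis,
                                co$stoplist),
                 sort(hits$record_id))
  }
})

test_that("the final hit set is independent of filter order", {
  cfg <- synth_config(seed = 55, n_records = 60)
  gb <- generate_graph(cfg)
  co <- generate_corpus(cfg, gb)
  base <- filter_query(co$population, rct_only = TRUE, min_phase = "P2",
                       exclude_children = TRUE, significant_only = TRUE,
                       require_known_intervention = TRUE)
  all_at_once <- apply_cascade(co$records, base, index = co$index,
                               pediatric_cuis = co$pediatric_cuis,
                               stoplist = co$stoplist)$record_id
  # sequential application, one filter at a time in several random orders
  filters <- list(
    function(q) { q$rct_only <- TRUE; q },
    function(q) { q$min_phase <- "P2"; q },
    function(q) { q$exclude_children <- TRUE; q },
    function(q) { q$significant_only <- TRUE; q },
    function(q) { q$require_known_intervention <- TRUE; q }
  )
  set.seed(1)
  for (rep in 1:4) {
    q <- filter_query(co$population)
    recs <- co$records
    for (f in sample(filters)) {
      step <- filter_query(co$population)
      step <- f(step)
      recs <- recs[recs$record_id %in%
                     apply_cascade(recs, step, index = co$index,
                                   pediatric_cuis = co$pediatric_cuis,
                                   stoplist = co$stoplist)$record_id, ]
    }
    expect_setequal(recs$record_id, all_at_once)
  }
})

test_that("query/index topic mismatch and missing index are usage errors", {
  fx <- benchmark_fixtures()
  expect_error(
    apply_cascade(fx$oesophageal$records, fx$oesophageal$ladder$all_rcts,
                  index = fx$hodgkin$index),
    "does not match"
  )
  expect_error(
    apply_cascade(fx$oesophageal$records,
                  fx$oesophageal$ladder$known_intervention, index = NULL),
    "mention index"
  )
  expect_error(filter_query(fx$oesophageal$population,
                            date_min = "2022-01-01", date_max = "2020-01-01"),
               "date_min")
})

test_that("trial timelines order milestones and guideline markers", {
  records <- bind_records(
    evidence_records("NCT00000001", "registry", title = "trial",
                     start_date = as.Date("2015-02-01"),
                     results_posted_date = as.Date("2019-03-01"),
                     is_rct = TRUE, phase = "P3",
                     population_cuis = list("C1"),
                     intervention_cuis = list("C2")),
    evidence_records(c("11", "12"), "pubmed",
                     publication_date = as.Date(c("2019-08-01", "2021-01-01")),
                     is_rct = TRUE,
                     linked_registry_ids = list("NCT00000001", "NCT00000001")),
    evidence_records("13", "pubmed", publication_date = as.Date("2018-01-01"),
                     is_rct = TRUE) # not linked
  )
  expect_error(build_timeline("NCT99999999", records), "unknown registry id")

  tl0 <- build_timeline("NCT00000001", records[1, ])
  expect_equal(nrow(tl0), 2L)
  expect_equal(tl0$event, c("trial_start", "results_posted"))

  versions <- list(
    guideline_document("g", "t", "3.1", "2018-06-01"),
    guideline_document("g", "t", "4.0", "2022-06-01")
  )
  tl <- build_timeline("NCT00000001", records, versions)
  expect_equal(sum(tl$event == "publication"), 2L)
  expect_equal(sum(tl$event == "guideline_release"), 2L)
  expect_false("13" %in% tl$record_id)
  expect_true(all(diff(tl$date) >= 0))
})
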