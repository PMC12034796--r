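medline_fixture <- function(n = 3, rct = TRUE) {
  rec <- evidence_records(
    record_id = as.character(100 + seq_len(n)),
    source = "pubmed",
    title = paste("Article", seq_len(n)),
    publication_date = as.Date("2021-03-01") + seq_len(n),
    is_rct = rct,
    linked_registry_ids = lapply(seq_len(n), function(i) {
      sprintf("NCT%08d", i)
    }),
    raw_publication_types = replicate(
      n, if (rct) c("D016449", "Randomized Controlled Trial") else
        "Journal Article",
      simplify = FALSE),
    raw_mesh_uis = replicate(n, c("D000001", "D000002"), simplify = FALSE)
  )
  rec$abstract <- paste("Abstract text for article", seq_len(n))
  rec
}

test_that("medline reader handles empty sets and flags RCTs", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet></PubmedArticleSet>", p)
  expect_equal(nrow(read_medline_xml(p)), 0L)

  writeLines(c(
    "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
    "<PMID>123</PMID><Article><ArticleTitle>T</ArticleTitle>",
    "<PublicationTypeList>",
    "<PublicationType>Randomized Controlled Trial</PublicationType>",
    "</PublicationTypeList>",
    "<Journal><JournalIssue><PubDate><Year>2020</Year><Month>May</Month>",
    "</PubDate></JournalIssue></Journal>",
    "</Article></MedlineCitation></PubmedArticle></PubmedArticleSet>"
  ), p)
  rec <- read_medline_xml(p)
  expect_true(rec$is_rct)
  # missing day completed to the first of the period; month name parsed
  expect_equal(rec$publication_date, as.Date("2020-05-01"))

  # same article without the RCT publication type
  writeLines(c(
    "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
    "<PMID>124</PMID><Article><ArticleTitle>T</ArticleTitle>",
    "<PublicationTypeList>",
    "<PublicationType>Journal Article</PublicationType>",
    "</PublicationTypeList></Article>",
    "</MedlineCitation></PubmedArticle></PubmedArticleSet>"
  ), p)
  expect_false(read_medline_xml(p)$is_rct)
})

test_that("articles without a PMID are skipped with a count", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<PubmedArticleSet>",
    "<PubmedArticle><MedlineCitation>",
    "<Article><ArticleTitle>No id</ArticleTitle></Article>",
    "</MedlineCitation></PubmedArticle>",
    "<PubmedArticle><MedlineCitation><PMID>7</PMID>",
    "<Article><ArticleTitle>Ok</ArticleTitle></Article>",
    "</MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"
  ), p)
  expect_warning(rec <- read_medline_xml(p), "without PMID")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "n_skipped"), 1L)
})

test_that("medline writer/reader round trip is field-identical", {
  rec <- medline_fixture(25)
  p <- withr::local_tempfile(fileext = ".xml")
  write_medline_xml(rec, p)
  back <- read_medline_xml(p)
  for (col in c("record_id", "title", "abstract", "publication_date",
                "is_rct", "linked_registry_ids", "raw_publication_types",
                "raw_mesh_uis")) {
    expect_equal(back[[col]], rec[[col]], label = col)
  }
})

test_that("coded sources map through the crosswalk and count unmapped codes", {
  dir <- withr::local_tempdir()
  reg <- file.path(dir, "registry")
  dir.create(reg)
  write.csv(data.frame(nct_id = c("NCT00000001", "NCT00000002"),
                       phase = c("Phase 3", "Phase 1/Phase 2"),
                       start_date = c("2015-01-01", ""),
                       results_first_posted_date = c("2019-05-01", "")),
            file.path(reg, "studies.csv"), row.names = FALSE)
  write.csv(data.frame(nct_id = c("NCT00000001", "NCT00000002"),
                       code = c("MSH001", "MSH404"),
                       vocabulary = "MSH",
                       term = c("disease one", "unmapped disease")),
            file.path(reg, "conditions.csv"), row.names = FALSE)
  write.csv(data.frame(nct_id = "NCT00000001", code = "MSH002",
                       vocabulary = "MSH", term = "drug one"),
            file.path(reg, "interventions.csv"), row.names = FALSE)
  write.csv(data.frame(nct_id = c("NCT00000001", "NCT00000001"),
                       p_value = c("0.30", "0.049")),
            file.path(reg, "outcome_analyses.csv"), row.names = FALSE)
  kb <- file.path(dir, "pokb.tsv")
  writeLines(c("assertion_id\tdisease_code\tphenotype_codes\ttherapy_codes",
               "AID1\tDO:1\tHPO:2\tNCIT:3"), kb)
  crosswalk <- data.frame(
    vocabulary = c("MSH", "MSH", "DO", "HPO", "NCIT"),
    code = c("MSH001", "MSH002", "1", "2", "3"),
    cui = c("C10", "C20", "C30", "C40", "C50")
  )
  rec <- read_coded_sources(reg, kb, crosswalk)
  expect_equal(nrow(rec), 3L)
  r1 <- rec[rec$record_id == "NCT00000001", ]
  expect_true("C10" %in% r1$population_cuis[[1]])
  expect_equal(r1$intervention_cuis[[1]], "C20")
  expect_equal(r1$phase, "P3")
  expect_equal(r1$significance, "SIGNIFICANT")
  expect_equal(rec$phase[rec$record_id == "NCT00000002"], "P1_2")
  # one disease + one phenotype -> 2 population cuis; one therapy -> 1
  a1 <- rec[rec$record_id == "AID1", ]
  expect_setequal(a1$population_cuis[[1]], c("C30", "C40"))
  expect_equal(a1$intervention_cuis[[1]], "C50")
  # MSH404 has no crosswalk entry
  expect_equal(attr(rec, "n_unmapped"), 1L)

  file.remove(file.path(reg, "conditions.csv"))
  write.csv(data.frame(nct_id = "NCT00000001", vocabulary = "MSH"),
            file.path(reg, "conditions.csv"), row.names = FALSE)
  expect_error(read_coded_sources(reg, NULL, crosswalk), "code")
})

test_that("unmapped-code counting scales with the number of misses", {
  dir <- withr::local_tempdir()
  kb <- file.path(dir, "pokb.tsv")
  n <- 100
  codes <- ifelse(seq_len(n) <= 10, paste0("XX:", seq_len(n)),
                  paste0("DO:", seq_len(n)))
  writeLines(c("assertion_id\tdisease_code\tphenotype_codes\ttherapy_codes",
               paste0("AID", seq_len(n), "\t", codes, "\t\t")), kb)
  crosswalk <- data.frame(vocabulary = "DO", code = as.character(seq_len(n)),
                          cui = paste0("C", seq_len(n)))
  rec <- read_coded_sources(NULL, kb, crosswalk)
  expect_equal(attr(rec, "n_unmapped"), 10L)
})

test_that("guideline documents validate offsets and round-trip", {
  doc0 <- guideline_document("g1", "t1", "1.0", "2020-01-01")
  expect_equal(length(doc0$sections), 0L)

  expect_error(
    guideline_document("g1", "t1", "1.0", "2020-01-01", sections = list(
      list(type = "recommendation", text = "short",
           mentions = list(list(cui = "C1", surface = "x", start = 2L,
                                end = 99L, confidence = 1,
                                semantic_types = character())))
    )),
    "out of range"
  )

  sections <- list(
    list(type = "recommendation", text = "give drug alpha",
         mentions = list(list(cui = "C1", surface = "drug alpha", start = 5L,
                              end = 15L, confidence = 0.9,
                              semantic_types = "T121"))),
    list(type = "background", text = "alpha history",
         mentions = list(list(cui = "C1", surface = "alpha", start = 0L,
                              end = 5L, confidence = 0.4,
                              semantic_types = "T121")))
  )
  doc <- guideline_document("g1", "t1", "2.0", "2021-06-01", sections)
  p <- withr::local_tempfile(fileext = ".json")
  write_guideline_json(doc, p)
  back <- read_guideline_json(p)
  expect_equal(back$release_date, doc$release_date)
  # mention count equals the fixture manifest
  expect_equal(sum(lengths(lapply(back$sections, `[[`, "mentions"))), 2L)
  expect_equal(back$sections[[1]]$mentions[[1]]$cui, "C1")
})

test_that("screening logs normalize identifiers and reject contradictions", {
  df <- data.frame(
    ref_id = c("r1", "r2", "r3"),
    pmid = c("PMID: 123", "", ""),
    doi = c("", "10.1000/ABC", ""),
    title = c("A", "B", "C"), year = "2021",
    duplicate = c("false", "false", "true"),
    ta_included = c("true", "false", ""),
    ft_included = c("true", "", ""),
    already_in_guideline = "false",
    manual_decision = c("none", "none", "none"),
    is_rct = c("true", "false", "false")
  )
  log <- screening_log(df)
  expect_equal(log$pmid[1], "123")
  expect_equal(log$doi[2], "10.1000/abc")
  expect_true(log$duplicate[3])
  expect_equal(nrow(log), 3L)

  df2 <- rbind(df, within(df[1, ], {
    ref_id <- "r4"
    ta_included <- "false"
  }))
  expect_error(screening_log(df2), "contradictory ta")

  # empty log
  expect_equal(nrow(screening_log(df[0, ])), 0L)

  # round trip
  p <- withr::local_tempfile(fileext = ".csv")
  write_screening_log(log, p)
  back <- read_screening_log(p)
  expect_equal(as.data.frame(back), as.data.frame(log))
})

test_that("results export writes context class tokens and reads back", {
  fx <- benchmark_fixtures()$hodgkin
  hits <- apply_cascade(fx$records, fx$ladder$significant, index = fx$index,
                        pediatric_cuis = fx$pediatric_cuis,
                        stoplist = fx$stoplist)
  p <- withr::local_tempfile(fileext = ".csv")
  write_results_export(hits, p)
  back <- read_results_export(p)
  expect_equal(nrow(back), nrow(hits))
  expect_equal(back$identifier, hits$record_id)
  # a hit carrying one recommended and one absent intervention shows both
  row1 <- back$interventions[[1]]
  expect_setequal(row1$context[row1$cui %in% c("C1KNOWN", "C1NEW")],
                  c("IN_RECOMMENDATION", "ABSENT"))

  # empty export: header only
  write_results_export(hits[0, ], p)
  expect_equal(nrow(read_results_export(p)), 0L)
})

test_that("corpus statistics use total vs distinct concept semantics", {
  empty <- evidence_records(character(), character())
  st0 <- corpus_statistics(empty)
  expect_true(all(st0$documents == 0))
  expect_true(all(st0$population_total == 0))

  rec <- evidence_records(
    record_id = c("1", "2", "3"), source = "pubmed",
    population_cuis = list("C1", "C1", "C1"),
    intervention_cuis = list(c("C2", "C3"), "C2", character())
  )
  st <- corpus_statistics(rec)
  pub <- st[st$source == "pubmed", ]
  expect_equal(pub$population_total, 3L)
  expect_equal(pub$population_unique, 1L)
  expect_equal(pub$intervention_total, 3L)
  expect_equal(pub$intervention_unique, 2L)

  # brute-force oracle on a synthetic corpus; unique <= total everywhere
  cfg <- synth_config(seed = 12, n_records = 200)
  co <- generate_corpus(cfg, generate_graph(cfg))
  st2 <- corpus_statistics(co$records)
  for (src in c("pubmed", "registry", "pokb")) {
    sub <- co$records[co$records$source == src, ]
    expect_equal(st2$population_total[st2$source == src],
                 length(unlist(sub$population_cuis)))
    expect_equal(st2$population_unique[st2$source == src],
                 length(unique(unlist(sub$population_cuis))))
  }
  expect_true(all(st2$population_unique <= st2$population_total))
  expect_true(all(st2$intervention_unique <= st2$intervention_total))
})

test_that("harmonized record TSV round trip is lossless", {
  cfg <- synth_config(seed = 9, n_records = 40)
  co <- generate_corpus(cfg, generate_graph(cfg))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_records_tsv(co$records, p)
  back <- read_records_tsv(p)
  a <- as.data.frame(co$records)
  b <- as.data.frame(back)[names(as.data.frame(co$records))]
  expect_equal(b, a, ignore_attr = TRUE)
})
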