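make_dataset <- function(relevant, irrelevant) {
  structure(list(relevant_ids = relevant, irrelevant_ids = irrelevant,
                 stages = list()), class = "evaluation_dataset")
}

test_that("scoring splits retrieved items three ways", {
  ds <- make_dataset(c("a", "b", "c"), c("x", "y"))
  corpus <- c("a", "b", "c", "x", "y", "u1", "u2")

  perfect <- score_retrieval(c("a", "b", "c"), ds, corpus)
  expect_equal(perfect$fp, 0L)
  expect_equal(perfect$fn, 0L)
  expect_equal(perfect$tn, 2L)

  none <- score_retrieval(character(), ds, corpus)
  expect_equal(none$tp, 0L)
  expect_equal(none$fp, 0L)
  expect_equal(none$fn, 3L)

  mixed <- score_retrieval(c("a", "x", "u1"), ds, corpus)
  expect_equal(mixed$tp, 1L)
  expect_equal(mixed$fp, 1L)
  expect_equal(mixed$unknown_retrieved, 1L)
  expect_equal(mixed$retrieved_total, 3L)

  expect_error(score_retrieval("nope", ds, corpus), "subset")
})

test_that("scoring equals the set-algebra oracle on random id sets", {
  set.seed(14)
  for (rep in 1:20) {
    universe <- paste0("id", 1:100)
    rel <- sample(universe, 20)
    irr <- sample(setdiff(universe, rel), 30)
    retrieved <- sample(universe, sample(0:60, 1))
    cm <- score_retrieval(retrieved, make_dataset(rel, irr), universe)
    expect_equal(cm$tp, length(intersect(retrieved, rel)))
    expect_equal(cm$fp, length(intersect(retrieved, irr)))
    expect_equal(cm$unknown_retrieved,
                 length(setdiff(retrieved, c(rel, irr))))
    expect_equal(cm$fn, length(setdiff(rel, retrieved)))
    expect_equal(cm$tn, length(setdiff(irr, retrieved)))
    # identities
    expect_equal(cm$tp + cm$unknown_retrieved + cm$fp, cm$retrieved_total)
    expect_equal(cm$tp + cm$fn, length(rel))
  }
})

test_that("metrics exclude unknown-relevance items from precision", {
  cm <- structure(list(tp = 31L, unknown_retrieved = 32L, fp = 146L,
                       tn = 150L, fn = 4L, retrieved_total = 209L),
                  class = "confusion_matrix")
  m <- retrieval_metrics(cm)
  # 31/(31+146), NOT 31/209
  expect_equal(round_display(m$precision), 0.18)
  expect_equal(round_display(m$recall), 0.89)
  expect_equal(round_display(m$f1), 0.29)

  cm2 <- structure(list(tp = 10L, unknown_retrieved = 0L, fp = 0L, tn = 35L,
                        fn = 30L, retrieved_total = 10L),
                   class = "confusion_matrix")
  m2 <- retrieval_metrics(cm2)
  expect_equal(round_display(m2$precision), 1.00)
  expect_equal(round_display(m2$recall), 0.25)
  expect_equal(round_display(m2$f1), 0.40)

  undef <- structure(list(tp = 0L, unknown_retrieved = 5L, fp = 0L, tn = 1L,
                          fn = 2L, retrieved_total = 5L),
                     class = "confusion_matrix")
  expect_true(is.na(retrieval_metrics(undef)$precision))

  # f1 lies between precision and recall when defined
  set.seed(8)
  for (rep in 1:20) {
    cm3 <- structure(list(tp = sample(1:50, 1), unknown_retrieved = 0L,
                          fp = sample(0:50, 1), tn = 0L,
                          fn = sample(0:50, 1), retrieved_total = 0L),
                     class = "confusion_matrix")
    m3 <- retrieval_metrics(cm3)
    expect_gte(m3$f1, min(m3$precision, m3$recall))
    expect_lte(m3$f1, max(m3$precision, m3$recall))
  }
})

test_that("display rounding is two decimals, half away from zero", {
  expect_equal(round_display(0.185), 0.19)
  expect_equal(round_display(0.125), 0.13)
  expect_equal(round_display(-0.125), -0.13)
  expect_equal(round_display(0.4), 0.4)
})

test_that("dataset construction replays the screening pipeline", {
  empty <- screening_log(data.frame(
    ref_id = character(), pmid = character(), doi = character(),
    title = character(), year = character(), duplicate = character(),
    ta_included = character(), ft_included = character(),
    already_in_guideline = character(), manual_decision = character(),
    is_rct = character()
  ))
  ds0 <- construct_dataset(empty)
  expect_equal(length(ds0$relevant_ids), 0L)
  expect_true(all(unlist(ds0$stages) == 0))

  log <- screening_log(data.frame(
    ref_id = paste0("r", 1:6),
    pmid = as.character(1:6),
    doi = "", title = paste("t", 1:6), year = "2021",
    duplicate = c("false", "false", "false", "false", "false", "true"),
    ta_included = c("true", "true", "false", "true", "", ""),
    ft_included = c("true", "false", "", "false", "", ""),
    already_in_guideline = c("false", "false", "false", "true", "false",
                             "false"),
    manual_decision = c("none", "none", "none", "none", "included", "none"),
    is_rct = c("true", "true", "false", "false", "true", "false")
  ))
  ds <- construct_dataset(log)
  # r1 included RCT, r5 manually included RCT; r4 excluded but reinstated
  # (non-RCT, so outside the RCT ground truth); r2 excluded RCT
  expect_setequal(ds$relevant_ids, c("pmid:1", "pmid:5"))
  expect_setequal(ds$irrelevant_ids, "pmid:2")
  expect_equal(ds$stages$screened, 5L)
  expect_equal(ds$stages$duplicates, 1L)
  expect_equal(ds$stages$reinstated_already_in_guideline, 1L)

  full <- construct_dataset(log, restrict_to_rct = FALSE)
  expect_true("pmid:4" %in% full$relevant_ids)
  expect_true("pmid:3" %in% full$irrelevant_ids)
})

test_that("cascade report composes scoring and metrics per ladder step", {
  fx <- benchmark_fixtures()$hodgkin
  ds <- construct_dataset(fx$log)
  one <- cascade_report(fx$records, fx$ladder["all_rcts"], ds,
                        index = fx$index, pediatric_cuis = fx$pediatric_cuis,
                        stoplist = fx$stoplist)
  hits <- apply_cascade(fx$records, fx$ladder$all_rcts, index = fx$index,
                        pediatric_cuis = fx$pediatric_cuis,
                        stoplist = fx$stoplist)
  cm <- score_retrieval(sprintf("pmid:%s", hits$record_id), ds,
                        sprintf("pmid:%s", fx$records$record_id))
  m <- retrieval_metrics(cm)
  expect_equal(one$tp, cm$tp)
  expect_equal(one$precision, round_display(m$precision))
  expect_equal(one$f1_raw, m$f1)
})

test_that("each added filter shrinks the hit set and never raises recall", {
  set.seed(77)
  for (rep in 1:5) {
    cfg <- synth_config(seed = 200 + rep, n_records = 60)
    gb <- generate_graph(cfg)
    co <- generate_corpus(cfg, gb)
    ds <- construct_dataset(co$log)
    q <- function(...) filter_query(co$population, ...)
    ladder <- list(
      base = q(),
      rct = q(rct_only = TRUE),
      phase = q(rct_only = TRUE, min_phase = "P2"),
      children = q(rct_only = TRUE, min_phase = "P2",
                   exclude_children = TRUE),
      sig = q(rct_only = TRUE, min_phase = "P2", exclude_children = TRUE,
              significant_only = TRUE)
    )
    prev <- NULL
    prev_recall <- Inf
    for (step in ladder) {
      ids <- apply_cascade(co$records, step, index = co$index,
                           pediatric_cuis = co$pediatric_cuis,
                           stoplist = co$stoplist)$record_id
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      cm <- score_retrieval(sprintf("pmid:%s", ids), ds,
                            sprintf("pmid:%s", co$records$record_id))
      m <- retrieval_metrics(cm)
      if (!is.na(m$recall)) {
        expect_lte(m$recall, prev_recall)
        prev_recall <- m$recall
      }
      prev <- ids
    }
  }
})
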