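#' Construct an evaluation dataset from a screening log
#'
#' Replays the manual screening pipeline to obtain ground-truth relevance
#' labels: duplicates are removed; title–abstract and then full-text
#' exclusions are applied; excluded references already cited in a previous
#' guideline version are moved back to the included side; references added
#' through manual review of system results, and system results already cited
#' in the current guideline, enter with their manual labels; finally both
#' sides are optionally restricted to randomized controlled trials (the
#' ground truth used for retrieval evaluation). References that never
#' received a decision have unknown relevance and belong to neither set.
#'
#' @param log a [screening_log()]
#' @param restrict_to_rct restrict the relevant/irrelevant sets to RCTs
#' @return object of class `evaluation_dataset`: `relevant_ids`,
#'   `irrelevant_ids` (dedup keys as in the log) and `stages`, a named list
#'   of per-stage counts (screened, duplicates, unique references,
#'   title–abstract and full-text exclusions, reinstated references, manual
#'   additions, and the final RCT counts).
#' @export
construct_dataset <- function(log, restrict_to_rct = TRUE) {
  stopifnot(inherits(log, "screening_log"))
  refs <- log[!log$duplicate, , drop = FALSE]
  refs <- refs[!duplicated(refs$dedup_key), , drop = FALSE]

  screened_mask <- !is.na(refs$ta_included) | !is.na(refs$ft_included)
  screened <- refs[screened_mask, , drop = FALSE]
  extra <- refs[!screened_mask, , drop = FALSE]

  ta_excluded <- !is.na(screened$ta_included) & !screened$ta_included
  ta_surv <- screened[!ta_excluded, , drop = FALSE]
  ft_excluded <- !is.na(ta_surv$ft_included) & !ta_surv$ft_included
  ft_surv <- ta_surv[!ft_excluded, , drop = FALSE]

  # excluded references already cited in a previous guideline version are
  # reinstated as included
  excluded_refs <- rbind(screened[ta_excluded, , drop = FALSE],
                         ta_surv[ft_excluded, , drop = FALSE])
  reinstated <- excluded_refs[excluded_refs$already_in_guideline, ,
                              drop = FALSE]
  excluded_refs <- excluded_refs[!excluded_refs$already_in_guideline, ,
                                 drop = FALSE]
  included_refs <- rbind(ft_surv, reinstated)

  # system results outside the screening set: manual review decisions, and
  # results already cited in the current guideline version
  manual_included <- extra[extra$manual_decision == "included", , drop = FALSE]
  manual_excluded <- extra[extra$manual_decision == "excluded", , drop = FALSE]
  retrieved_in_guideline <- extra[extra$manual_decision == "none" &
                                    extra$already_in_guideline, , drop = FALSE]

  final_included <- rbind(included_refs, manual_included,
                          retrieved_in_guideline)
  final_excluded <- rbind(excluded_refs, manual_excluded)

  both <- intersect(final_included$dedup_key, final_excluded$dedup_key)
  if (length(both) > 0L) {
    stop("reference both included and excluded after all steps: ", both[1],
         call. = FALSE)
  }

  # "screened" counts the rows of the screening process itself (including
  # duplicate rows); system results added afterwards (manual review, already
  # cited in the guideline) carry no screening decision and are not screened
  stages <- list(
    screened = sum(log$duplicate | !is.na(log$ta_included) |
                     !is.na(log$ft_included)),
    duplicates = sum(log$duplicate),
    unique_references = sum(screened_mask),
    ta_excluded = sum(ta_excluded),
    ta_included = nrow(ta_surv),
    ft_excluded = sum(ft_excluded),
    reinstated_already_in_guideline = nrow(reinstated),
    included_evaluation = nrow(included_refs),
    rcts_included = sum(included_refs$is_rct),
    manual_included = nrow(manual_included),
    retrieved_already_in_guideline = nrow(retrieved_in_guideline),
    rcts_included_final = sum(final_included$is_rct),
    other_included = sum(!final_included$is_rct),
    excluded_evaluation = nrow(excluded_refs),
    rcts_excluded = sum(excluded_refs$is_rct),
    manual_excluded = nrow(manual_excluded),
    rcts_excluded_final = sum(final_excluded$is_rct),
    other_excluded = sum(!final_excluded$is_rct)
  )

  if (restrict_to_rct) {
    final_included <- final_included[final_included$is_rct, , drop = FALSE]
    final_excluded <- final_excluded[final_excluded$is_rct, , drop = FALSE]
  }
  structure(
    list(relevant_ids = sort(final_included$dedup_key),
         irrelevant_ids = sort(final_excluded$dedup_key),
         stages = stages),
    class = "evaluation_dataset"
  )
}

#' @export
print.evaluation_dataset <- function(x, ...) {
  cat("<evaluation_dataset> ", length(x$relevant_ids), " relevant / ",
      length(x$irrelevant_ids), " irrelevant references\n", sep = "")
  invisible(x)
}

#' Confusion accounting with an unknown-relevance category
#'
#' Screening logs label only the references that were screened; a retrieval
#' system can return results outside that set. Retrieved items are therefore
#' split three ways: true positives (relevant), false positives
#' (irrelevant), and retrieved items of unknown relevance. Non-retrieved
#' items are counted against the labelled sets only (false negatives among
#' the relevant, true negatives among the irrelevant).
#'
#' @param retrieved_ids identifiers retrieved by the system
#' @param dataset an [construct_dataset()] result
#' @param corpus_ids identifiers of the searchable corpus; `retrieved_ids`
#'   must be a subset
#' @return object of class `confusion_matrix` with `tp`, `unknown_retrieved`,
#'   `fp`, `tn`, `fn` and `retrieved_total`
#' @export
score_retrieval <- function(retrieved_ids, dataset, corpus_ids) {
  stopifnot(inherits(dataset, "evaluation_dataset"))
  retrieved_ids <- unique(as.character(retrieved_ids))
  corpus_ids <- unique(as.character(corpus_ids))
  if (length(setdiff(retrieved_ids, corpus_ids)) > 0L) {
    stop("retrieved ids are not a subset of the corpus", call. = FALSE)
  }
  rel <- dataset$relevant_ids
  irr <- dataset$irrelevant_ids
  cm <- list(
    tp = length(intersect(retrieved_ids, rel)),
    unknown_retrieved = length(setdiff(retrieved_ids, c(rel, irr))),
    fp = length(intersect(retrieved_ids, irr)),
    tn = length(setdiff(irr, retrieved_ids)),
    fn = length(setdiff(rel, retrieved_ids)),
    retrieved_total = length(retrieved_ids)
  )
  structure(cm, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> retrieved ", x$retrieved_total, " (TP ", x$tp,
      ", ? ", x$unknown_retrieved, ", FP ", x$fp, "); TN ", x$tn, ", FN ",
      x$fn, "\n", sep = "")
  invisible(x)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Retrieved items of unknown relevance are excluded from the precision
#' denominator: precision = TP / (TP + FP). This is forced by the
#' three-way accounting — an unlabelled retrieved item is not evidence of a
#' retrieval error. Undefined metrics (empty denominators) are returned as
#' `NA`, never silently zeroed.
#'
#' @param cm a [score_retrieval()] result
#' @return list of class `retrieval_metrics` with `precision`, `recall`,
#'   `f1` (raw, unrounded)
#' @export
retrieval_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  precision <- if (cm$tp + cm$fp == 0L) NA_real_ else cm$tp / (cm$tp + cm$fp)
  recall <- if (cm$tp + cm$fn == 0L) NA_real_ else cm$tp / (cm$tp + cm$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "retrieval_metrics")
}

#' Round for display: two decimals, half away from zero
#'
#' Matches the rounding used in the reported evaluation tables (applied to
#' the double-precision value of the ratio).
#' @param x numeric
#' @param digits decimal places
#' @return numeric
#' @export
round_display <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Evaluate a nested filter ladder
#'
#' Runs [apply_cascade()] for each query of a ladder (typically each query
#' adds one filter on top of the previous one), scores every step against
#' the evaluation dataset, and tabulates the three-way confusion counts and
#' metrics — one row per ladder step. Raw metric values are kept alongside
#' 2-decimal display values.
#'
#' @param records [evidence_records()] (the searchable corpus); record ids
#'   are matched to the dataset via `id_map`
#' @param ladder named list of [filter_query()] objects
#' @param dataset an [construct_dataset()] result
#' @param index,pediatric_cuis,stoplist passed to [apply_cascade()]
#' @param id_map function mapping record ids to the dataset's identifier
#'   space (default: screening-log PMID keys, `pmid:<record_id>`)
#' @return tibble with columns `filter`, `retrieved`, `tp`, `unknown`, `fp`,
#'   `tn`, `fn`, `precision`, `recall`, `f1` (display-rounded) and
#'   `precision_raw`, `recall_raw`, `f1_raw`
#' @export
cascade_report <- function(records, ladder, dataset, index = NULL,
                           pediatric_cuis = character(),
                           stoplist = character(),
                           id_map = function(id) sprintf("pmid:%s", id)) {
  stopifnot(is.list(ladder), length(ladder) > 0L)
  corpus_ids <- id_map(records$record_id)
  rows <- vector("list", length(ladder))
  labels <- names(ladder)
  if (is.null(labels)) labels <- paste0("step_", seq_along(ladder))
  for (i in seq_along(ladder)) {
    hits <- apply_cascade(records, ladder[[i]], index = index,
                          pediatric_cuis = pediatric_cuis,
                          stoplist = stoplist)
    cm <- score_retrieval(id_map(hits$record_id), dataset, corpus_ids)
    mt <- retrieval_metrics(cm)
    rows[[i]] <- tibble::tibble(
      filter = labels[i],
      retrieved = cm$retrieved_total,
      tp = cm$tp, unknown = cm$unknown_retrieved, fp = cm$fp,
      tn = cm$tn, fn = cm$fn,
      precision = round_display(mt$precision),
      recall = round_display(mt$recall),
      f1 = round_display(mt$f1),
      precision_raw = mt$precision,
      recall_raw = mt$recall,
      f1_raw = mt$f1
    )
  }
  do.call(rbind, rows)
}
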