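# Independent oracles used across tests. These deliberately avoid the
# package's own data structures and algorithms: closures are recomputed by
# plain breadth-first search over the raw edge table, predicates by direct
# per-record evaluation.

# reflexive descendant closure by BFS over the raw child/parent edge rows
bfs_closure <- function(edges, seeds) {
  out <- unique(seeds)
  frontier <- out
  while (length(frontier) > 0L) {
    kids <- edges$child_cui[edges$parent_cui %in% frontier]
    frontier <- setdiff(kids, out)
    out <- union(out, frontier)
  }
  sort(out)
}

# random DAG as raw tables: node i may only point to earlier nodes
random_dag_tables <- function(n, p_edge = 0.08) {
  cui <- sprintf("N%03d", seq_len(n))
  types <- sample(c("T047", "T121", "T061", ""), n, replace = TRUE)
  child <- character()
  parent <- character()
  if (n > 1L) {
    for (i in 2:n) {
      for (j in seq_len(i - 1L)) {
        if (stats::runif(1) < p_edge) {
          child <- c(child, cui[i])
          parent <- c(parent, cui[j])
        }
      }
    }
  }
  list(
    concepts = data.frame(cui = cui, preferred_term = cui,
                          semantic_types = types, stringsAsFactors = FALSE),
    edges = data.frame(child_cui = child, parent_cui = parent,
                       stringsAsFactors = FALSE)
  )
}

# direct per-record re-evaluation of every active cascade predicate
cascade_oracle <- function(records, query, index, pediatric_cuis = character(),
                           stoplist = character()) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    d <- r$publication_date
    if (is.na(d)) d <- r$results_posted_date
    if (is.na(d)) d <- r$start_date
    ok <- r$source %in% query$sources
    if (!is.null(query$date_min)) ok <- ok && !is.na(d) && d >= query$date_min
    if (!is.null(query$date_max)) ok <- ok && !is.na(d) && d <= query$date_max
    ok <- ok && length(intersect(r$population_cuis[[1]],
                                 query$population$expanded_cuis)) > 0L
    if (query$rct_only) ok <- ok && r$is_rct
    if (!is.null(query$min_phase)) {
      ok <- ok && isTRUE(phase_at_least(r$phase, query$min_phase))
    }
    if (query$exclude_children) {
      ok <- ok && !any(r$population_cuis[[1]] %in% pediatric_cuis)
    }
    if (query$significant_only) ok <- ok && r$significance == "SIGNIFICANT"
    ints <- r$intervention_cuis[[1]]
    known <- ints[ints %in% index$anywhere_cuis]
    absent <- setdiff(ints, index$anywhere_cuis)
    if (query$require_known_intervention) ok <- ok && length(known) > 0L
    if (query$require_unknown_intervention) {
      ok <- ok && length(setdiff(absent, stoplist)) > 0L
    }
    keep[i] <- ok
  }
  sort(records$record_id[keep])
}

# small fixture graph shared by several tests
tiny_graph <- function() {
  concept_graph(
    data.frame(
      cui = c("A", "B", "C", "D", "E"),
      preferred_term = c("root", "left", "right", "shared leaf", "isolated"),
      semantic_types = c("T047", "T047", "T047", "T047", "T121"),
      stringsAsFactors = FALSE
    ),
    # child -> parent: D sits below both B and C (multi-parent leaf)
    data.frame(child_cui = c("B", "C", "D", "D"),
               parent_cui = c("A", "A", "B", "C"),
               stringsAsFactors = FALSE)
  )
}
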