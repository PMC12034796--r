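#' Build a validated concept graph
#'
#' A concept graph is a directed acyclic graph over opaque concept
#' identifiers (CUIs). Edges are stored child -> parent, following the
#' convention of vocabulary hierarchy files; population expansion walks the
#' edges in the opposite direction (parent -> children) to collect the
#' subtree rooted at a seed concept. A child may have several parents, so
#' subtrees of different guideline topics can overlap (e.g. tumours of the
#' oesophagogastric junction sit below both the gastric and the oesophageal
#' cancer topic concepts).
#'
#' @param concepts data frame with columns `cui`, `preferred_term` and
#'   `semantic_types` (character; pipe-joined type tokens such as
#'   `"T121|T061"`, may be empty).
#' @param edges data frame with columns `child_cui`, `parent_cui`. Duplicate
#'   rows are collapsed.
#'
#' @return An object of class `concept_graph` with elements `concepts`
#'   (tibble), `edges` (tibble) and a parent -> children adjacency list.
#'   Dangling edge endpoints and cycles are hard errors: the hierarchy files
#'   this models are curated, and silently repairing them hides data bugs.
#' @export
concept_graph <- function(concepts, edges = NULL) {
  stopifnot(is.data.frame(concepts), all(c("cui") %in% names(concepts)))
  cui <- as.character(concepts$cui)
  if (any(!nzchar(cui)) || anyNA(cui)) {
    stop("concept table contains empty or missing cui", call. = FALSE)
  }
  if (anyDuplicated(cui)) {
    stop("duplicate cui in concept table: ",
         cui[duplicated(cui)][1], call. = FALSE)
  }
  if (is.null(concepts$preferred_term)) concepts$preferred_term <- cui
  if (is.null(concepts$semantic_types)) concepts$semantic_types <- ""
  concepts <- tibble::tibble(
    cui = cui,
    preferred_term = as.character(concepts$preferred_term),
    semantic_types = as.character(concepts$semantic_types)
  )

  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble::tibble(child_cui = character(), parent_cui = character())
  } else {
    stopifnot(all(c("child_cui", "parent_cui") %in% names(edges)))
    edges <- unique(tibble::tibble(
      child_cui = as.character(edges$child_cui),
      parent_cui = as.character(edges$parent_cui)
    ))
  }
  unknown <- setdiff(c(edges$child_cui, edges$parent_cui), concepts$cui)
  if (length(unknown) > 0L) {
    stop("edge endpoint not in concept table: ", unknown[1], call. = FALSE)
  }
  cyc <- find_cycle_member(concepts$cui, edges)
  if (!is.null(cyc)) {
    stop("concept graph contains a cycle through ", cyc, call. = FALSE)
  }

  children <- split(edges$child_cui, factor(edges$parent_cui,
                                            levels = concepts$cui))
  structure(
    list(concepts = concepts, edges = edges, children = children),
    class = "concept_graph"
  )
}

# Kahn's algorithm on the child->parent edge list; returns one node on a
# cycle, or NULL when the graph is acyclic.
find_cycle_member <- function(nodes, edges) {
  if (nrow(edges) == 0L) return(NULL)
  indeg <- table(factor(edges$parent_cui, levels = nodes))
  indeg <- stats::setNames(as.integer(indeg), nodes)
  parents_of <- split(edges$parent_cui, factor(edges$child_cui, levels = nodes))
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (p in parents_of[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(nodes)) names(indeg)[indeg > 0L][1] else NULL
}

#' @export
print.concept_graph <- function(x, ...) {
  cat("<concept_graph> ", nrow(x$concepts), " concepts, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Read a concept graph from hierarchy and concept tables
#'
#' @param edge_path TSV with header `child_cui<TAB>parent_cui`.
#' @param concept_path TSV with header
#'   `cui<TAB>preferred_term<TAB>semantic_types` (pipe-joined types).
#' @return A [concept_graph()].
#' @export
read_concept_graph <- function(concept_path, edge_path) {
  concepts <- utils::read.delim(concept_path, sep = "\t",
                                colClasses = "character")
  edges <- utils::read.delim(edge_path, sep = "\t", colClasses = "character")
  concept_graph(concepts, edges)
}

#' Write the two concept-graph tables
#' @param graph a [concept_graph()]
#' @param concept_path,edge_path output TSV paths
#' @return invisibly, the two paths
#' @export
write_concept_graph <- function(graph, concept_path, edge_path) {
  utils::write.table(graph$concepts, concept_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(graph$edges, edge_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(concept_path, edge_path))
}

#' Reflexive-transitive descendant closure
#'
#' Returns every concept that is a seed or has some seed as an ancestor
#' (walking parent -> child edges). This is the population-expansion
#' primitive: guideline-topic seed concepts are expanded to the full set of
#' population concepts they subsume.
#'
#' @param graph a [concept_graph()]
#' @param seeds character vector of seed CUIs (must exist in `graph`)
#' @return character vector of CUIs (sorted, unique), a superset of `seeds`.
#' @export
descendant_closure <- function(graph, seeds) {
  stopifnot(inherits(graph, "concept_graph"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) return(character())
  unknown <- setdiff(seeds, graph$concepts$cui)
  if (length(unknown) > 0L) {
    stop("unknown seed cui: ", unknown[1], call. = FALSE)
  }
  out <- new.env(parent = emptyenv())
  queue <- seeds
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    if (!is.null(out[[v]])) next
    out[[v]] <- TRUE
    kids <- graph$children[[v]]
    if (length(kids) > 0L) queue <- c(queue, kids)
  }
  sort(ls(out))
}

#' Expand guideline-topic seeds into a population set
#'
#' @param graph a [concept_graph()]
#' @param topic_id guideline-topic token
#' @param seed_cuis character vector of seed CUIs (may be empty)
#' @return A `population_set`: list with `topic_id`, `seed_cuis`,
#'   `expanded_cuis` (= [descendant_closure()] of the seeds).
#' @export
expand_population <- function(graph, topic_id, seed_cuis) {
  expanded <- descendant_closure(graph, seed_cuis)
  structure(
    list(topic_id = as.character(topic_id),
         seed_cuis = sort(unique(as.character(seed_cuis))),
         expanded_cuis = expanded),
    class = "population_set"
  )
}

#' @export
print.population_set <- function(x, ...) {
  cat("<population_set> topic ", x$topic_id, ": ", length(x$seed_cuis),
      " seeds -> ", length(x$expanded_cuis), " concepts\n", sep = "")
  invisible(x)
}

#' Keep only concepts carrying an allowed semantic type
#'
#' Used e.g. to restrict candidate interventions to pharmacologic substances
#' (type token T121) and therapeutic or preventive procedures (T061).
#'
#' @param graph a [concept_graph()]
#' @param cuis character vector of CUIs present in `graph`
#' @param allowed_types non-empty character vector of semantic-type tokens
#' @return the subset of `cuis` whose concept has at least one type in
#'   `allowed_types` (input order preserved).
#' @export
filter_by_semantic_type <- function(graph, cuis, allowed_types) {
  stopifnot(inherits(graph, "concept_graph"), length(allowed_types) > 0L)
  cuis <- as.character(cuis)
  unknown <- setdiff(cuis, graph$concepts$cui)
  if (length(unknown) > 0L) {
    stop("unknown cui: ", unknown[1], call. = FALSE)
  }
  types <- semantic_types_of(graph, cuis)
  cuis[vapply(types, function(tt) any(tt %in% allowed_types), logical(1))]
}

# named list: cui -> character vector of semantic-type tokens
semantic_types_of <- function(graph, cuis) {
  idx <- match(cuis, graph$concepts$cui)
  raw <- graph$concepts$semantic_types[idx]
  out <- strsplit(ifelse(is.na(raw), "", raw), "|", fixed = TRUE)
  out <- lapply(out, function(x) x[nzchar(x)])
  names(out) <- cuis
  out
}

#' Read topic seed concepts
#' @param path TSV with header `topic_id<TAB>seed_cui`, one row per seed
#' @return named list: topic_id -> character vector of seed CUIs
#' @export
read_topic_seeds <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  stopifnot(all(c("topic_id", "seed_cui") %in% names(df)))
  lapply(split(df$seed_cui, df$topic_id), unique)
}
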