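# End-to-end orchestration: query -> lexical match -> semantic expansion
# -> formal context -> lattice -> coverage pruning -> refined HOI, plus
# the sensitivity/specificity evaluation harness and JSON serialization.

#' Session configuration for a refinement run
#'
#' @param threshold Pruning threshold in \[0, 1\]; an attribute is pruned
#'   when the covered fraction of its sub-concepts falls strictly below
#'   it.  Default 0.75.
#' @param hop_mode `"closure"` (a derivation round yields the full
#'   sub-concept closure; default) or `"edge"` (single-edge hops).
#' @param seed Integer seed recorded with the session (the pipeline is
#'   deterministic; the seed feeds only auxiliary sampling such as
#'   [verify_galois()]).
#' @param max_cells Context-size guard passed to [enumerate_concepts()].
#' @return A list of class `session_config`.
#' @export
session_config <- function(threshold = 0.75,
                           hop_mode = c("closure", "edge"),
                           seed = 1L, max_cells = 1e6) {
  hop_mode <- match.arg(hop_mode)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("session_config: threshold must be a number in [0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("session_config: seed must be a single integer", call. = FALSE)
  }
  structure(list(threshold = threshold, hop_mode = hop_mode,
                 seed = as.integer(seed), max_cells = max_cells),
            class = "session_config")
}

#' Refine a free-text Health Outcome of Interest query
#'
#' The full semi-automatic pipeline: the query is matched lexically
#' against every concept synonym, the matches are expanded by two rounds
#' of sub-concept derivation across the merged ontologies, a formal
#' context is built over the matched + derived concepts with their
#' super-concepts as attributes, the concept lattice is enumerated and
#' traversed top-down, and super-concepts are pruned by sub-concept
#' coverage or confirmed/rejected through the feedback oracle.  The run
#' is deterministic given the graph, configuration and oracle.
#'
#' @param query Free-text query string (e.g. `"pituitary cancer"`).
#' @param graph A merged, acyclic [ontology_graph].
#' @param config A [session_config()].
#' @param oracle `NULL` or a feedback function; see [gold_oracle()].
#' @param closure Optionally a precomputed [compute_closure()] result
#'   for `graph` (recomputed when `NULL`).
#' @param index Optionally a prebuilt [build_index()] result.
#' @return An object of class `refinement_result` with the matched,
#'   derived, potential and remaining concept sets, every pruning
#'   decision (attribute, ratio, counts, status), the rejected and
#'   eliminated ids, and the final accepted concept set.  An empty match
#'   yields an empty result with a warning, not an error.
#' @export
refine_hoi <- function(query, graph, config = session_config(),
                       oracle = NULL, closure = NULL, index = NULL) {
  stopifnot(inherits(graph, "ontology_graph"),
            inherits(config, "session_config"))
  if (is.null(closure)) closure <- compute_closure(graph)
  if (is.null(index)) index <- build_index(graph)
  mres <- match_query(query, index)
  if (!length(mres$matched_ids)) {
    warning("refine_hoi: no lexical match for query \"", query, "\"",
            call. = FALSE)
    out <- classify_roles(character(0))
    out$query <- query
    out$config <- config
    return(out)
  }
  expansion <- two_hop(mres$matched_ids, closure, graph,
                       mode = config$hop_mode)
  objects <- expansion$second_hop
  K <- build_context(objects, closure)
  lattice <- enumerate_concepts(K, max_cells = config$max_cells)
  pruning <- traverse_and_prune(lattice, objects, closure,
                                threshold = config$threshold,
                                oracle = oracle)
  out <- classify_roles(mres$matched_ids, expansion, pruning)
  out$query <- query
  out$tokens <- mres$tokens
  out$config <- config
  out$n_formal_concepts <- length(lattice$concepts)
  out
}

#' Serialize a refinement result to canonical JSON
#'
#' Field order, array order (sorted ids) and number formatting are fixed,
#' so identical sessions produce byte-identical JSON.
#'
#' @param result A `refinement_result`.
#' @param path Optional output file; when given, the JSON is written
#'   there and the path returned invisibly.
#' @return The JSON string (class `json`), or the path invisibly.
#' @export
refinement_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "refinement_result"))
  dec <- result$decisions
  dec <- dec[order(dec$attribute), , drop = FALSE]
  payload <- list(
    schema = "hoilattice/refinement/v1",
    query = if (is.null(result$query)) "" else result$query,
    threshold = if (is.null(result$config)) NA else result$config$threshold,
    matched = as.list(result$matched),
    derived = as.list(result$derived),
    potential = as.list(result$potential),
    pruned = as.list(sort(dec$attribute[dec$status == "pruned"])),
    rejected = as.list(result$rejected),
    decisions = lapply(seq_len(nrow(dec)), function(i) {
      list(attribute = dec$attribute[i], ratio = dec$ratio[i],
           n_sub = dec$n_sub[i], n_covered = dec$n_covered[i],
           status = dec$status[i])
    }),
    final = as.list(result$final))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path, useBytes = TRUE)
    return(invisible(path))
  }
  js
}

#' Sensitivity and specificity of a predicted concept set
#'
#' Confusion counts over a declared universe of concepts:
#' TP = predicted and gold, FN = gold only, FP = predicted only,
#' TN = neither.  Sensitivity = TP/(TP+FN) (0 when the gold set is
#' empty); specificity = TN/(TN+FP) (1 when there are no negatives).
#'
#' @param predicted Character vector of predicted concept ids.
#' @param gold_positive Character vector of gold-standard ids
#'   (subset of `universe`).
#' @param universe Character vector: every concept considered.
#' @param condition Label for the row (default `"condition"`).
#' @return A one-row data frame of class `hoi_evaluation`:
#'   condition, tp, fn, tn, fp, sensitivity, specificity.
#' @export
evaluate <- function(predicted, gold_positive, universe,
                     condition = "condition") {
  predicted <- unique(as.character(predicted))
  gold_positive <- unique(as.character(gold_positive))
  universe <- unique(as.character(universe))
  if (!all(gold_positive %in% universe)) {
    stop("evaluate: gold_positive must be a subset of universe",
         call. = FALSE)
  }
  if (!all(predicted %in% universe)) {
    stop("evaluate: predicted must be a subset of universe", call. = FALSE)
  }
  tp <- length(intersect(predicted, gold_positive))
  fn <- length(setdiff(gold_positive, predicted))
  fp <- length(setdiff(predicted, gold_positive))
  tn <- length(universe) - tp - fn - fp
  se <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 1
  out <- data.frame(condition = condition, tp = tp, fn = fn, tn = tn,
                    fp = fp, sensitivity = se, specificity = sp,
                    stringsAsFactors = FALSE)
  class(out) <- c("hoi_evaluation", class(out))
  out
}

#' Summarize an evaluation report over several conditions
#'
#' @param rows One or more [evaluate()] rows (rbind-ed data frame).
#' @return The input with an `Average` row appended (unweighted means of
#'   sensitivity and specificity).
#' @export
evaluation_report <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  avg <- data.frame(condition = "Average", tp = NA_integer_,
                    fn = NA_integer_, tn = NA_integer_, fp = NA_integer_,
                    sensitivity = mean(rows$sensitivity),
                    specificity = mean(rows$specificity),
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(rows), avg)
  class(out) <- c("hoi_evaluation", "data.frame")
  out
}
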