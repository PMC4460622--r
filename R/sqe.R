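# Semantic Query Expansion: downward derivation of sub-concepts across
# the merged multi-ontology graph ("2-hop"), and upward navigation to a
# minimal set of covering super-concepts.

#' Derive the sub-concepts of a concept set (one round)
#'
#' One derivation round over the merged graph.  In the default
#' `"closure"` mode a round yields all strict descendants of the input
#' set (full sub-concept closure); in `"edge"` mode it yields only the
#' direct children, the alternative reading of an incremental hop.
#'
#' @param C Character vector of seed concept ids.
#' @param closure A [closure_table] computed on the merged graph.
#' @param graph The [ontology_graph]; required only for `mode = "edge"`.
#' @param mode `"closure"` (default) or `"edge"`.
#' @return Sorted character vector of derived concept ids (may overlap
#'   `C` when members subsume one another).
#' @export
expand_down <- function(C, closure, graph = NULL, mode = c("closure", "edge")) {
  mode <- match.arg(mode)
  if (!length(C)) return(character(0))
  if (mode == "closure") return(descendants_of(C, closure))
  stopifnot(!is.null(graph))
  kids <- names(graph$concepts)[vapply(graph$concepts, function(co) {
    any(co$parent_ids %in% C)
  }, logical(1))]
  sort(unique(kids))
}

#' Two rounds of sub-concept derivation ("2-hop")
#'
#' From a seed set C, derives sub-concepts C' in a first round, then a
#' second round over C' gives C'' = C + C' + derivations of C'.  Because
#' equivalent concepts are merged across ontologies, each round hops
#' across every ontology containing the current set; two rounds capture
#' concepts from adjacent ontologies while deliberately stopping short
#' of fixpoint recursion, which is unsafe when merging induces cycles.
#'
#' @inheritParams expand_down
#' @return An object of class `expansion_result`: list with `seed`,
#'   `first_hop` (C'), `second_hop` (C'', includes the seeds) and `cover`
#'   (the minimal ancestor cover of the seeds, see
#'   [minimal_ancestor_cover]).
#' @export
two_hop <- function(C, closure, graph = NULL, mode = c("closure", "edge")) {
  mode <- match.arg(mode)
  C <- sort(unique(C))
  C1 <- expand_down(C, closure, graph, mode)
  C2 <- sort(unique(c(C, C1, expand_down(C1, closure, graph, mode))))
  structure(list(seed = C,
                 first_hop = C1,
                 second_hop = C2,
                 cover = minimal_ancestor_cover(C, closure)),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat("Semantic expansion: |C| = ", length(x$seed),
      ", |C'| = ", length(x$first_hop),
      ", |C''| = ", length(x$second_hop),
      "; ancestor cover of size ", length(x$cover), "\n", sep = "")
  invisible(x)
}

#' Minimal ancestor cover of a set of matched concepts
#'
#' Navigates to super-concepts until a small set covers every lexical
#' match: every match with at least one parent gets at least one strict
#' ancestor in the cover, and parentless matches stand for themselves.
#' Exact minimum set cover is NP-hard, so a deterministic deepest-first
#' greedy is used: candidates (strict ancestors of the matches) are
#' chosen by greatest depth first — preferring the most specific
#' super-concepts — breaking ties by number of newly covered matches,
#' then by id.  The cover never exceeds the number of matches.
#'
#' @param matches Character vector of matched concept ids.
#' @param closure A [closure_table].
#' @return Sorted character vector: the covering super-concepts plus any
#'   parentless matches.
#' @export
minimal_ancestor_cover <- function(matches, closure) {
  matches <- sort(unique(matches))
  if (!length(matches)) return(character(0))
  anc <- closure$ancestors[matches]
  rootless <- matches[vapply(anc, length, integer(1)) == 0L]
  todo <- setdiff(matches, rootless)
  cands <- sort(unique(unlist(anc, use.names = FALSE)))
  cover <- character(0)
  while (length(todo)) {
    covers <- lapply(cands, function(a) intersect(todo, closure$descendants[[a]]))
    n_cov <- vapply(covers, length, integer(1))
    ok <- n_cov > 0L
    cands <- cands[ok]; covers <- covers[ok]; n_cov <- n_cov[ok]
    if (!length(cands)) break  # unreachable: every todo has an ancestor
    dep <- closure$depth[cands]
    best <- order(-dep, -n_cov, cands)[1]
    cover <- c(cover, cands[best])
    todo <- setdiff(todo, covers[[best]])
  }
  sort(unique(c(cover, rootless)))
}
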