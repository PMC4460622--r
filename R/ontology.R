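# Ontology loading, merging and subsumption-closure machinery.
#
# Concepts are CUI-like nodes of a multi-ontology is-a DAG.  Each concept
# carries a preferred label, a synonym set (always including the label),
# the ids of its direct super-concepts, and cross-ontology mapping keys
# (xrefs) used to merge equivalent concepts across source vocabularies.

#' Construct an ontology graph from a list of concepts
#'
#' Low-level constructor used by the loaders and the synthetic generators.
#' Validates referential integrity (every parent id must exist), uniqueness
#' of concept ids, and the absence of self-loops.
#'
#' @param concepts A list of concept records, each a list with elements
#'   `concept_id`, `ontology_ids`, `preferred_label`, `synonyms`,
#'   `parent_ids` and `xrefs` (character vectors; scalars for the first
#'   and third).
#' @return An object of class `ontology_graph`: a list with `concepts`
#'   (named by concept id, in load order) and `root_ids` (ids with no
#'   parents).
#' @export
ontology_graph <- function(concepts) {
  ids <- vapply(concepts, function(co) co$concept_id, character(1))
  if (any(!nzchar(ids))) {
    stop("ontology_graph: empty concept_id", call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("ontology_graph: duplicate concept_id: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  concepts <- lapply(concepts, function(co) {
    co$ontology_ids <- unique(as.character(co$ontology_ids))
    co$preferred_label <- as.character(co$preferred_label)[1]
    co$synonyms <- unique(c(co$preferred_label, as.character(co$synonyms)))
    co$synonyms <- co$synonyms[nzchar(co$synonyms)]
    co$parent_ids <- unique(as.character(co$parent_ids))
    co$parent_ids <- co$parent_ids[nzchar(co$parent_ids)]
    co$xrefs <- unique(as.character(if (is.null(co$xrefs)) character(0) else co$xrefs))
    co$xrefs <- co$xrefs[nzchar(co$xrefs)]
    if (co$concept_id %in% co$parent_ids) {
      stop("ontology_graph: concept '", co$concept_id,
           "' lists itself as a parent", call. = FALSE)
    }
    co
  })
  names(concepts) <- ids
  for (co in concepts) {
    missing <- setdiff(co$parent_ids, ids)
    if (length(missing)) {
      stop("ontology_graph: concept '", co$concept_id,
           "' references unknown parent(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  roots <- ids[vapply(concepts, function(co) length(co$parent_ids) == 0L,
                      logical(1))]
  structure(list(concepts = concepts, root_ids = roots),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("Ontology graph: ", length(x$concepts), " concepts, ",
      length(x$root_ids), " root(s) [",
      paste(utils::head(x$root_ids, 5), collapse = ", "),
      if (length(x$root_ids) > 5) ", ..." else "", "]\n", sep = "")
  onts <- sort(unique(unlist(lapply(x$concepts, `[[`, "ontology_ids"))))
  cat("Source ontologies: ", paste(onts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

split_multi <- function(x) {
  # pipe-separated multi-value field; empty string is the empty set
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

#' Load an ontology from the tab-separated dialect
#'
#' The file must be UTF-8, tab-separated, with the exact header
#' `concept_id  ontology_id  label  synonyms  parents  xrefs`.
#' Multi-valued fields (`synonyms`, `parents`, `xrefs`) are
#' pipe-separated; an empty field denotes the empty set.  Synonyms always
#' include the preferred label.
#'
#' @param path Path to the TSV file.
#' @return An [ontology_graph].
#' @export
load_ontology_tsv <- function(path) {
  if (!file.exists(path)) stop("load_ontology_tsv: no such file: ", path,
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("load_ontology_tsv: empty file: ", path,
                           call. = FALSE)
  want <- c("concept_id", "ontology_id", "label", "synonyms", "parents",
            "xrefs")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(header), want)) {
    stop("load_ontology_tsv: bad header; expected: ",
         paste(want, collapse = "\t"), call. = FALSE)
  }
  rows <- lapply(seq_along(lines[-1]) + 1L, function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    length(f) <- 6L  # right-pad missing trailing fields
    f[is.na(f)] <- ""
    list(concept_id = trimws(f[1]),
         ontology_ids = trimws(f[2]),
         preferred_label = trimws(f[3]),
         synonyms = split_multi(f[4]),
         parent_ids = split_multi(f[5]),
         xrefs = split_multi(f[6]),
         row = i)
  })
  ids <- vapply(rows, `[[`, character(1), "concept_id")
  dup <- which(duplicated(ids))
  if (length(dup)) {
    stop("load_ontology_tsv: duplicate concept_id '", ids[dup[1]],
         "' at row ", rows[[dup[1]]]$row, call. = FALSE)
  }
  for (r in rows) {
    missing <- setdiff(r$parent_ids, ids)
    if (length(missing)) {
      stop("load_ontology_tsv: row ", r$row, " (", r$concept_id,
           ") references unknown parent '", missing[1], "'", call. = FALSE)
    }
  }
  ontology_graph(lapply(rows, function(r) r[setdiff(names(r), "row")]))
}

#' Load an ontology from an OBO file
#'
#' Parses `[Term]` stanzas of OBO 1.2/1.4 flat files: `id:`, `name:`,
#' `synonym:` (the quoted text), `is_a:` (parent ids; trailing `!`
#' comments stripped) and `xref:`.  Terms with `is_obsolete: true` are
#' skipped; a message reports how many.  The ontology label is taken from
#' the header `ontology:` tag, falling back to the file name.
#'
#' @param path Path to the `.obo` file.
#' @return An [ontology_graph] equivalent to what the TSV loader yields
#'   for the same content.
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) stop("load_obo: no such file: ", path,
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ont <- sub("\\.obo$", "", basename(path))
  in_term <- FALSE
  terms <- list()
  cur <- NULL
  n_obsolete <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    if (isTRUE(cur$obsolete)) {
      n_obsolete <<- n_obsolete + 1L
    } else {
      if (is.null(cur$concept_id)) {
        stop("load_obo: [Term] stanza without id near line ", cur$line,
             call. = FALSE)
      }
      if (is.null(cur$preferred_label)) cur$preferred_label <- cur$concept_id
      terms[[length(terms) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- sub("\\s*!.*$", "", lines[[i]])  # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur <- list(concept_id = NULL, ontology_ids = ont,
                  preferred_label = NULL, synonyms = character(0),
                  parent_ids = character(0), xrefs = character(0),
                  obsolete = FALSE, line = i)
      next
    }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) {
      if (!in_term && grepl("^ontology:", ln)) {
        ont <- trimws(sub("^ontology:", "", ln))
      }
      next
    }
    if (!grepl("^[A-Za-z_-]+:", ln)) {
      stop("load_obo: malformed line ", i, ": ", lines[[i]], call. = FALSE)
    }
    tag <- sub(":.*$", "", ln)
    val <- trimws(sub("^[A-Za-z_-]+:", "", ln))
    if (tag == "id") cur$concept_id <- val
    else if (tag == "name") cur$preferred_label <- val
    else if (tag == "is_a") cur$parent_ids <- c(cur$parent_ids, val)
    else if (tag == "xref") cur$xrefs <- c(cur$xrefs, val)
    else if (tag == "is_obsolete" && tolower(val) == "true")
      cur$obsolete <- TRUE
    else if (tag == "synonym") {
      m <- regmatches(val, regexec('^"((?:[^"\\\\]|\\\\.)*)"', val))[[1]]
      if (length(m) < 2) {
        stop("load_obo: malformed synonym at line ", i, call. = FALSE)
      }
      cur$synonyms <- c(cur$synonyms, gsub('\\\\(.)', "\\1", m[2]))
    }
    # other tags (def:, comment:, relationship: ...) are ignored
  }
  flush()
  if (n_obsolete > 0L) {
    message("load_obo: skipped ", n_obsolete, " obsolete term(s)")
  }
  ids <- vapply(terms, `[[`, character(1), "concept_id")
  # drop is_a references to obsolete/absent terms only if they point at
  # skipped obsolete ids; unknown live parents are still an error
  terms <- lapply(terms, function(tm) {
    tm$parent_ids <- intersect(tm$parent_ids, ids)
    tm[setdiff(names(tm), c("obsolete", "line"))]
  })
  ontology_graph(terms)
}

#' Merge ontology graphs on cross-reference keys
#'
#' Cross-ontology mapping keys (xrefs, CUI-style shared identifiers) and
#' concept ids are treated as one key space; concepts connected through
#' shared keys form one merged node whose parents, synonyms, xrefs and
#' source-ontology labels are the unions over members.  The preferred
#' label and the merged id come from the first-loaded member, so the
#' result is deterministic in load order.  Graphs with no xrefs merge to
#' their disjoint union.
#'
#' @param graphs A list of [ontology_graph] objects, in load order.
#' @return A single merged [ontology_graph].
#' @export
merge_on_xrefs <- function(graphs) {
  if (inherits(graphs, "ontology_graph")) graphs <- list(graphs)
  all_concepts <- unlist(lapply(graphs, `[[`, "concepts"), recursive = FALSE)
  ids <- vapply(all_concepts, `[[`, character(1), "concept_id")
  if (anyDuplicated(ids)) {
    stop("merge_on_xrefs: concept id '", ids[duplicated(ids)][1],
         "' appears in more than one input graph", call. = FALSE)
  }
  # union-find over the shared key space (concept ids + xref keys)
  keys <- unique(c(ids, unlist(lapply(all_concepts, `[[`, "xrefs"))))
  parent <- stats::setNames(seq_along(keys), keys)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(match(a, keys)); rb <- find(match(b, keys))
    if (ra != rb) parent[[max(ra, rb)]] <<- min(ra, rb)
  }
  for (co in all_concepts) {
    for (x in co$xrefs) unite(co$concept_id, x)
  }
  comp_of <- vapply(match(ids, keys), find, integer(1))
  # representative id per component: the first-loaded member concept
  merged <- list()
  for (comp in unique(comp_of)) {
    members <- all_concepts[comp_of == comp]
    rep_id <- members[[1]]$concept_id
    merged[[rep_id]] <- list(
      concept_id = rep_id,
      ontology_ids = unique(unlist(lapply(members, `[[`, "ontology_ids"))),
      preferred_label = members[[1]]$preferred_label,
      synonyms = unique(unlist(lapply(members, `[[`, "synonyms"))),
      parent_ids = unique(unlist(lapply(members, `[[`, "parent_ids"))),
      xrefs = unique(unlist(lapply(members, `[[`, "xrefs"))))
  }
  # remap parent ids to component representatives
  rep_by_id <- stats::setNames(
    vapply(comp_of, function(cc) {
      all_concepts[[which(comp_of == cc)[1]]]$concept_id
    }, character(1)), ids)
  merged <- lapply(merged, function(co) {
    co$parent_ids <- unique(unname(rep_by_id[co$parent_ids]))
    # a merge of a parent with its child would create a self-loop; drop it
    co$parent_ids <- setdiff(co$parent_ids, co$concept_id)
    co
  })
  ontology_graph(unname(merged))
}

graph_to_igraph <- function(graph) {
  ids <- names(graph$concepts)
  edges <- do.call(rbind, lapply(graph$concepts, function(co) {
    if (!length(co$parent_ids)) return(NULL)
    cbind(co$concept_id, co$parent_ids)
  }))
  g <- igraph::make_empty_graph(n = length(ids), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges))  # child -> parent
  }
  g
}

#' Detect subsumption cycles
#'
#' Cross-ontology merging can fold differing abstraction levels into
#' cycles even when every source ontology is acyclic, which is why the
#' expansion stops at two derivation rounds instead of recursing to a
#' fixpoint.  This check must pass before the transitive closure is
#' materialized.
#'
#' @param graph An [ontology_graph].
#' @return A list of witness cycles (each a character vector of concept
#'   ids, first id repeated at the end); empty if and only if the graph
#'   is a DAG.
#' @export
detect_cycles <- function(graph) {
  ig <- graph_to_igraph(graph)
  if (igraph::is_dag(ig)) return(list())
  ids <- names(graph$concepts)
  parents <- lapply(graph$concepts, `[[`, "parent_ids")
  color <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new 1 open 2 done
  stack_ids <- character(0)
  cycles <- list()
  visit <- function(v) {
    color[[v]] <<- 1L
    stack_ids <<- c(stack_ids, v)
    for (p in parents[[v]]) {
      if (color[[p]] == 0L) visit(p)
      else if (color[[p]] == 1L && !length(cycles)) {
        at <- match(p, stack_ids)
        cycles[[1]] <<- c(stack_ids[at:length(stack_ids)], p)
      }
    }
    color[[v]] <<- 2L
    stack_ids <<- stack_ids[-length(stack_ids)]
  }
  for (v in ids) if (color[[v]] == 0L && !length(cycles)) visit(v)
  cycles
}

#' Materialize the subsumption transitive closure
#'
#' Stores, for every concept, its full set of strict ancestors
#' (super-concepts at any distance) and strict descendants
#' (sub-concepts), plus the depth of each concept (longest is-a path
#' from a root).  Strictness means a concept is never its own ancestor
#' or descendant; callers needing the reflexive closure add the concept
#' explicitly.
#'
#' @param graph An acyclic [ontology_graph] (check with [detect_cycles]).
#' @return An object of class `closure_table` with named lists
#'   `ancestors` and `descendants` (character vectors per concept id)
#'   and a named integer vector `depth`.
#' @export
compute_closure <- function(graph) {
  cyc <- detect_cycles(graph)
  if (length(cyc)) {
    stop("compute_closure: graph is cyclic, e.g. ",
         paste(cyc[[1]], collapse = " -> "), call. = FALSE)
  }
  ig <- graph_to_igraph(graph)
  ids <- names(graph$concepts)
  # topological order child-before-parent along child->parent edges
  topo <- names(igraph::topo_sort(ig, mode = "out"))
  parents <- lapply(graph$concepts, `[[`, "parent_ids")
  anc <- stats::setNames(vector("list", length(ids)), ids)
  for (v in rev(topo)) {  # parents first
    anc[[v]] <- sort(unique(c(parents[[v]],
                              unlist(anc[parents[[v]]], use.names = FALSE))))
  }
  desc <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (v in ids) {
    for (a in anc[[v]]) desc[[a]] <- c(desc[[a]], v)
  }
  desc <- lapply(desc, function(d) sort(unique(d)))
  depth <- stats::setNames(integer(length(ids)), ids)
  for (v in rev(topo)) {
    depth[[v]] <- if (!length(parents[[v]])) 0L
                  else max(depth[parents[[v]]]) + 1L
  }
  structure(list(ancestors = anc, descendants = desc, depth = depth),
            class = "closure_table")
}

#' @export
print.closure_table <- function(x, ...) {
  cat("Subsumption closure over ", length(x$ancestors), " concepts; ",
      "max depth ", max(c(0L, x$depth)), "\n", sep = "")
  invisible(x)
}

#' Strict ancestors / descendants of a concept set
#'
#' Convenience accessors over a [closure_table]; the union over the given
#' ids, excluding the ids themselves unless `reflexive = TRUE`.
#'
#' @param ids Character vector of concept ids.
#' @param closure A [closure_table].
#' @param reflexive Include the input ids themselves?
#' @return Sorted character vector of concept ids.
#' @export
ancestors_of <- function(ids, closure, reflexive = FALSE) {
  out <- unlist(closure$ancestors[ids], use.names = FALSE)
  if (reflexive) out <- c(out, ids)
  sort(unique(out))
}

#' @rdname ancestors_of
#' @export
descendants_of <- function(ids, closure, reflexive = FALSE) {
  out <- unlist(closure$descendants[ids], use.names = FALSE)
  if (reflexive) out <- c(out, ids)
  sort(unique(out))
}
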