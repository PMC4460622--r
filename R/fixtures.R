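# Deterministic synthetic fixtures: seeded random DAG ontologies with
# synonyms, planted gold outcome subtrees for end-to-end evaluation,
# random formal contexts, and a 4x4 hypertriglyceridemia
# context extract with its generating chain ontology.

#' Generate a random DAG ontology
#'
#' Concepts are assigned to levels 0..`depth` (level 0 is the single
#' root); each non-root concept draws 1..`max_parents` parents uniformly
#' from strictly shallower levels, which guarantees acyclicity without
#' rejection sampling.  Synonyms are synthetic strings
#' (`"term <id> <k>"`) unique to their concept, since lexical matching is
#' exact-string and imitation vocabulary would only invite accidental
#' ambiguity.  Byte-for-byte reproducible under `seed`.
#'
#' @param n_concepts Total number of concepts (>= 2).
#' @param max_parents Maximum parents per non-root concept.
#' @param depth Number of levels below the root.
#' @param synonyms_per_concept Extra synonyms per concept (labels are
#'   always synonyms too).
#' @param xref_rate Fraction of concepts carrying a shared cross-ontology
#'   mapping key (`"XR<i>"`), for merge fixtures.
#' @param seed Integer seed.
#' @param ontology_id Source-ontology label.
#' @param prefix Concept-id prefix.
#' @return An [ontology_graph].
#' @export
generate_dag_ontology <- function(n_concepts, max_parents = 2L, depth = 4L,
                                  synonyms_per_concept = 1L,
                                  xref_rate = 0, seed = 1L,
                                  ontology_id = "synth",
                                  prefix = "C") {
  stopifnot(n_concepts >= 2L, max_parents >= 1L, depth >= 1L,
            xref_rate >= 0, xref_rate <= 1)
  set.seed(seed)
  ids <- sprintf("%s%04d", prefix, seq_len(n_concepts))
  lev <- integer(n_concepts)
  lev[1] <- 0L
  # at least one concept per level, remainder spread at random
  n_rest <- n_concepts - 1L
  depth <- min(depth, n_rest)
  lev[1L + seq_len(depth)] <- seq_len(depth)
  if (n_rest > depth) {
    lev[(depth + 2L):n_concepts] <- sample(seq_len(depth),
                                           n_rest - depth, replace = TRUE)
  }
  lev <- c(0L, sort(lev[-1]))  # shallow ids first, keeps ids readable
  concepts <- vector("list", n_concepts)
  xr <- 0L
  for (i in seq_len(n_concepts)) {
    if (lev[i] == 0L) {
      parents <- character(0)
    } else {
      pool <- ids[lev < lev[i]]
      k <- sample.int(min(max_parents, length(pool)), 1L)
      parents <- sample(pool, k)
    }
    syns <- if (synonyms_per_concept > 0) {
      sprintf("term %s %d", tolower(ids[i]), seq_len(synonyms_per_concept))
    } else character(0)
    xref <- if (xref_rate > 0 && stats::runif(1) < xref_rate) {
      xr <- xr + 1L
      sprintf("XR%d", xr)
    } else character(0)
    concepts[[i]] <- list(concept_id = ids[i],
                          ontology_ids = ontology_id,
                          preferred_label = paste("concept", tolower(ids[i])),
                          synonyms = syns,
                          parent_ids = parents,
                          xrefs = xref)
  }
  ontology_graph(concepts)
}

#' Plant a gold Health Outcome of Interest subtree
#'
#' Picks an internal concept `h`; the gold set is `h` plus all of its
#' strict sub-concepts.  A unique multi-word synonym is attached to `h`
#' and to a seeded sample of other gold members, and those synonyms are
#' returned as the query vocabulary, emulating the term list of an
#' annotated condition.  `h` is chosen so the planted outcome is
#' well-separated: every strict super-concept of a gold member lying
#' outside the gold set has sub-concept coverage below `threshold`, so
#' the refinement pipeline can in principle isolate the subtree exactly.
#'
#' @param graph An [ontology_graph] with at least 3 levels.
#' @param seed Integer seed.
#' @param threshold Separation threshold (matches the pruning threshold
#'   the ontology will be refined with; default 0.75).
#' @param min_gold,max_gold Bounds on the gold-set size.
#' @param n_extra_terms How many gold members besides `h` receive query
#'   synonyms.
#' @return A list with `hoi` (the planted root id), `gold` (sorted id
#'   set, downward closed), `terms` (the planted synonyms) and `query`
#'   (the terms joined into one query string).  The graph is returned
#'   modified in `graph`.
#' @export
plant_hoi <- function(graph, seed = 1L, threshold = 0.75,
                      min_gold = 3L, max_gold = 40L, n_extra_terms = 3L) {
  closure <- compute_closure(graph)
  ids <- names(graph$concepts)
  set.seed(seed)
  cand <- sample(ids)  # seeded candidate order
  pick <- NULL
  for (h in cand) {
    golds <- c(h, closure$descendants[[h]])
    if (length(golds) < min_gold || length(golds) > max_gold) next
    outside <- setdiff(ancestors_of(golds, closure), golds)
    sep <- all(vapply(outside, function(a) {
      d <- closure$descendants[[a]]
      length(intersect(d, golds)) / length(d) < threshold
    }, logical(1)))
    if (sep) { pick <- h; break }
  }
  if (is.null(pick)) {
    stop("plant_hoi: no well-separated internal concept found; ",
         "use a larger or deeper graph", call. = FALSE)
  }
  h <- pick
  gold <- sort(unique(c(h, closure$descendants[[h]])))
  carriers <- setdiff(gold, h)
  carriers <- if (length(carriers)) {
    sample(carriers, min(n_extra_terms, length(carriers)))
  } else character(0)
  terms <- c(sprintf("planted outcome %d root", seed),
             sprintf("planted outcome %d sign %d", seed,
                     seq_along(carriers)))
  graph$concepts[[h]]$synonyms <- c(graph$concepts[[h]]$synonyms, terms[1])
  for (i in seq_along(carriers)) {
    co <- carriers[i]
    graph$concepts[[co]]$synonyms <- c(graph$concepts[[co]]$synonyms,
                                       terms[i + 1L])
  }
  list(graph = graph, hoi = h, gold = gold, terms = terms,
       query = paste(terms, collapse = " "))
}

#' The hypertriglyceridemia context extract
#'
#' The 4x4 binary context over internal concept identifiers — objects
#' 10365 (hyperlipoproteinemia type IV), 12115, 10406 and 191723,
#' attributes 0 (the repository's top concept), 19118, 740154 and 6260 —
#' with the 10 incidences of the printed extract.  Column 6260 is empty
#' on these rows and is retained for file-format fidelity;
#' [build_context()] never generates empty attribute columns.
#'
#' @return A [formal_context] with |G| = 4, |M| = 4, |I| = 10.
#' @export
hypertriglyceridemia_context <- function() {
  objects <- c("10365", "12115", "10406", "191723")
  attributes <- c("0", "19118", "740154", "6260")
  inc <- rbind(c(1, 1, 1, 0),
               c(1, 1, 1, 0),
               c(1, 1, 0, 0),
               c(1, 1, 0, 0))
  formal_context(objects, attributes, inc)
}

#' Chain ontology generating the hypertriglyceridemia context extract
#'
#' The subsumption fragment behind [hypertriglyceridemia_context()]: 10365 and 12115
#' under 740154, which sits with 10406 and 191723 under 19118, all under
#' the top concept 0; concept 6260 hangs elsewhere (directly under 0),
#' which is why its column is empty on the printed rows.
#' `build_context` of the four objects over this ontology reproduces the
#' three non-empty columns of the extract exactly.
#'
#' @return An [ontology_graph].
#' @export
hypertriglyceridemia_ontology <- function() {
  mk <- function(id, label, parents) {
    list(concept_id = id, ontology_ids = "demo", preferred_label = label,
         synonyms = character(0), parent_ids = parents, xrefs = character(0))
  }
  ontology_graph(list(
    mk("0", "top concept", character(0)),
    mk("19118", "lipid metabolism disorder", "0"),
    mk("740154", "hyperlipoproteinemia", "19118"),
    mk("10365", "hyperlipoproteinemia type IV", "740154"),
    mk("12115", "hypertriglyceridemia", "740154"),
    mk("10406", "hyperlipidemia nos", "19118"),
    mk("191723", "hyperglyceridemia", "19118"),
    mk("6260", "unrelated disorder", "0")))
}

#' Generate a random formal context
#'
#' Each cell is incident independently with probability `density`;
#' deterministic under `seed`.
#'
#' @param nG,nM Numbers of objects and attributes.
#' @param density Incidence probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A [formal_context] with objects `g1..gnG`, attributes
#'   `m1..mnM`.
#' @export
generate_random_context <- function(nG, nM, density = 0.5, seed = 1L) {
  stopifnot(nG >= 0, nM >= 0, density >= 0, density <= 1)
  set.seed(seed)
  inc <- matrix(stats::runif(nG * nM) < density, nrow = nG, ncol = nM)
  formal_context(if (nG) sprintf("g%02d", seq_len(nG)) else character(0),
                 if (nM) sprintf("m%02d", seq_len(nM)) else character(0),
                 inc)
}

#' Write an ontology graph in the TSV dialect
#'
#' Inverse of [load_ontology_tsv()]; used by the `simulate` CLI
#' subcommand and by round-trip tests.
#'
#' @param graph An [ontology_graph].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ontology_tsv <- function(graph, path) {
  join <- function(v) paste(v, collapse = "|")
  rows <- vapply(graph$concepts, function(co) {
    paste(co$concept_id, join(co$ontology_ids), co$preferred_label,
          join(setdiff(co$synonyms, co$preferred_label)),
          join(co$parent_ids), join(co$xrefs), sep = "\t")
  }, character(1))
  writeLines(c(paste(c("concept_id", "ontology_id", "label", "synonyms",
                       "parents", "xrefs"), collapse = "\t"),
               unname(rows)), path, useBytes = TRUE)
  invisible(path)
}
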