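# Shared fixtures and independent oracles.  Oracles are deliberately
# naive (fixpoint iteration, exhaustive enumeration, triple loops) so
# they stay independent of the implementation paths they check.

mk_concept <- function(id, parents = character(0), syn = character(0),
                       ont = "toy", label = tolower(id),
                       xrefs = character(0)) {
  list(concept_id = id, ontology_ids = ont, preferred_label = label,
       synonyms = syn, parent_ids = parents, xrefs = xrefs)
}

# ROOT; A, B under ROOT; A1, A2 under A.  A1 carries two synonyms used
# by the lexical tests.
toy_graph <- function() {
  ontology_graph(list(
    mk_concept("ROOT"),
    mk_concept("A", "ROOT"),
    mk_concept("B", "ROOT"),
    mk_concept("A1", "A", syn = c("hypertension", "high blood pressure")),
    mk_concept("A2", "A")))
}

toy_tsv_lines <- function() {
  c("concept_id\tontology_id\tlabel\tsynonyms\tparents\txrefs",
    "ROOT\ttoy\troot\t\t\t",
    "A\ttoy\ta\t\tROOT\t",
    "B\ttoy\tb\t\tROOT\t",
    "A1\ttoy\ta1\thypertension|high blood pressure\tA\t",
    "A2\ttoy\ta2\t\tA\t")
}

# ont1: ROOT > A > {A1, A2}; ont2: XTOP > X1 > X1a > X1aa.
# A1 and X1 are linked by the shared key CUI1.
dual_ontology_graphs <- function() {
  g1 <- ontology_graph(list(
    mk_concept("ROOT", ont = "ont1"),
    mk_concept("A", "ROOT", ont = "ont1"),
    mk_concept("A1", "A", ont = "ont1", xrefs = "CUI1"),
    mk_concept("A2", "A", ont = "ont1")))
  g2 <- ontology_graph(list(
    mk_concept("XTOP", ont = "ont2"),
    mk_concept("X1", "XTOP", ont = "ont2", xrefs = "CUI1"),
    mk_concept("X1a", "X1", ont = "ont2"),
    mk_concept("X1aa", "X1a", ont = "ont2")))
  list(g1, g2)
}

# strict ancestors by repeated one-step parent expansion to fixpoint
oracle_ancestors <- function(graph, id) {
  cur <- graph$concepts[[id]]$parent_ids
  repeat {
    nxt <- sort(unique(c(cur, unlist(lapply(cur, function(p) {
      graph$concepts[[p]]$parent_ids
    })))))
    if (identical(nxt, sort(unique(cur)))) break
    cur <- nxt
  }
  sort(unique(cur))
}

oracle_descendants <- function(graph, id) {
  ids <- names(graph$concepts)
  sort(ids[vapply(ids, function(v) id %in% oracle_ancestors(graph, v),
                  logical(1))])
}

# exhaustive formal-concept enumeration over all 2^|G| object subsets
brute_force_concepts <- function(K) {
  nG <- length(K$objects)
  seen <- character(0)
  out <- list()
  for (mask in 0:(2^nG - 1)) {
    A <- K$objects[as.logical(intToBits(mask))[seq_len(nG)]]
    B <- derive_intent(A, K)
    E <- derive_extent(B, K)
    key <- paste(paste(E, collapse = ","), paste(B, collapse = ","),
                 sep = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(extent = E, intent = B)
    }
  }
  out
}

concept_keys <- function(concepts) {
  sort(vapply(concepts, function(cc) {
    paste(paste(sort(cc$extent), collapse = ","),
          paste(sort(cc$intent), collapse = ","), sep = "|")
  }, character(1)))
}

# transitive reduction by the definitional triple loop
oracle_hasse <- function(lattice) {
  k <- length(lattice$concepts)
  edges <- NULL
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j || !lattice$leq[i, j]) next
      between <- any(vapply(seq_len(k), function(h) {
        h != i && h != j && lattice$leq[i, h] && lattice$leq[h, j]
      }, logical(1)))
      if (!between) edges <- rbind(edges, c(i, j))
    }
  }
  if (is.null(edges)) matrix(integer(0), ncol = 2) else
    edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# every concept id whose synonym occurs as a contiguous token span
oracle_all_span_hits <- function(query, index) {
  tokens <- normalize_text(query)
  hits <- character(0)
  for (i in seq_along(tokens)) {
    for (j in i:length(tokens)) {
      key <- paste(tokens[i:j], collapse = " ")
      if (!is.null(index[[key]])) hits <- c(hits, index[[key]])
    }
  }
  sort(unique(hits))
}

random_session <- function(seed, n = 40L) {
  g <- generate_dag_ontology(n, max_parents = 2L, depth = 4L, seed = seed)
  cl <- compute_closure(g)
  set.seed(seed + 7L)
  objs <- sort(sample(names(g$concepts)[-1], sample(4:8, 1)))
  K <- build_context(objs, cl)
  list(graph = g, closure = cl, objects = objs,
       lattice = enumerate_concepts(K))
}
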