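test_that("TSV loader transcribes the toy hierarchy and finds its root", {
  f <- withr::local_tempfile(lines = toy_tsv_lines(), fileext = ".tsv")
  g <- load_ontology_tsv(f)
  expect_s3_class(g, "ontology_graph")
  expect_length(g$concepts, 5)
  expect_identical(g$root_ids, "ROOT")
  expect_setequal(g$concepts$A1$synonyms,
                  c("a1", "hypertension", "high blood pressure"))
  expect_identical(g$concepts$A1$parent_ids, "A")
})

test_that("TSV loader rejects dangling parents, duplicates and bad headers", {
  bad_parent <- c(toy_tsv_lines(), "Z\ttoy\tz\t\tNOPE\t")
  f1 <- withr::local_tempfile(lines = bad_parent, fileext = ".tsv")
  expect_error(load_ontology_tsv(f1), "NOPE")

  dup <- c(toy_tsv_lines(), "A1\ttoy\tagain\t\tA\t")
  f2 <- withr::local_tempfile(lines = dup, fileext = ".tsv")
  expect_error(load_ontology_tsv(f2), "A1")

  f3 <- withr::local_tempfile(lines = c("id\tname", "x\ty"),
                              fileext = ".tsv")
  expect_error(load_ontology_tsv(f3), "header")
})

test_that("OBO loader parses terms, synonyms and skips obsolete stanzas", {
  obo <- c("format-version: 1.2", "ontology: toyobo", "",
           "[Term]", "id: A", "name: alpha", "",
           "[Term]", "id: B", "name: beta", "is_a: A ! alpha",
           'synonym: "b one" EXACT []', 'synonym: "b two" RELATED []', "",
           "[Term]", "id: C", "name: gamma", "is_a: A", "",
           "[Term]", "id: D", "name: gone", "is_obsolete: true")
  f <- withr::local_tempfile(lines = obo, fileext = ".obo")
  expect_message(g <- load_obo(f), "obsolete")
  expect_length(g$concepts, 3)
  expect_identical(g$root_ids, "A")
  expect_setequal(g$concepts$B$synonyms, c("beta", "b one", "b two"))
  expect_identical(g$concepts$B$parent_ids, "A")
})

test_that("OBO and TSV encodings of the same hierarchy yield identical closures", {
  tsv <- withr::local_tempfile(lines = toy_tsv_lines(), fileext = ".tsv")
  obo_lines <- c("format-version: 1.2", "ontology: toy",
    "", "[Term]", "id: ROOT", "name: root",
    "", "[Term]", "id: A", "name: a", "is_a: ROOT",
    "", "[Term]", "id: B", "name: b", "is_a: ROOT",
    "", "[Term]", "id: A1", "name: a1", "is_a: A",
    'synonym: "hypertension" EXACT []',
    'synonym: "high blood pressure" EXACT []',
    "", "[Term]", "id: A2", "name: a2", "is_a: A")
  obo <- withr::local_tempfile(lines = obo_lines, fileext = ".obo")
  c1 <- compute_closure(load_ontology_tsv(tsv))
  c2 <- compute_closure(load_obo(obo))
  expect_identical(c1$ancestors, c2$ancestors)
  expect_identical(c1$descendants, c2$descendants)
})

test_that("xref merging unions members and connects hierarchies", {
  gs <- dual_ontology_graphs()
  gm <- merge_on_xrefs(gs)
  # A1 and X1 collapse into one node named after the first-loaded member
  expect_true("A1" %in% names(gm$concepts))
  expect_false("X1" %in% names(gm$concepts))
  expect_setequal(gm$concepts$A1$parent_ids, c("A", "XTOP"))
  expect_setequal(gm$concepts$A1$ontology_ids, c("ont1", "ont2"))
  cl <- compute_closure(gm)
  expect_true(all(c("X1a", "X1aa") %in% cl$descendants$A1))
  expect_true("X1aa" %in% cl$descendants$A)
})

test_that("graphs without xrefs merge to their disjoint union", {
  g1 <- ontology_graph(list(mk_concept("P"), mk_concept("Q", "P")))
  g2 <- ontology_graph(list(mk_concept("R"), mk_concept("S", "R")))
  gm <- merge_on_xrefs(list(g1, g2))
  expect_length(gm$concepts, 4)
  expect_setequal(gm$root_ids, c("P", "R"))
})

test_that("xref chains merge transitively into one node", {
  g1 <- ontology_graph(list(mk_concept("a", xrefs = "k1")))
  g2 <- ontology_graph(list(mk_concept("b", xrefs = c("k1", "k2"))))
  g3 <- ontology_graph(list(mk_concept("c", xrefs = "k2")))
  gm <- merge_on_xrefs(list(g1, g2, g3))
  expect_length(gm$concepts, 1)
  expect_identical(names(gm$concepts), "a")
})

test_that("merging preserves every input synonym exactly once", {
  gs <- dual_ontology_graphs()
  gm <- merge_on_xrefs(gs)
  all_in <- unlist(lapply(gs, function(g) {
    lapply(g$concepts, `[[`, "synonyms")
  }))
  counts <- table(unlist(lapply(gm$concepts, `[[`, "synonyms")))
  for (s in unique(all_in)) {
    expect_identical(unname(counts[[s]]), 1L)
  }
})

test_that("closure produces strict ancestor/descendant sets with inverse symmetry", {
  g <- toy_graph()
  cl <- compute_closure(g)
  expect_identical(cl$ancestors$A1, c("A", "ROOT"))
  expect_identical(cl$ancestors$ROOT, character(0))
  expect_setequal(cl$descendants$ROOT, c("A", "B", "A1", "A2"))
  for (a in names(g$concepts)) {
    expect_false(a %in% cl$ancestors[[a]])
    for (b in cl$descendants[[a]]) {
      expect_true(a %in% cl$ancestors[[b]])
    }
    for (b in cl$ancestors[[a]]) {
      expect_true(a %in% cl$descendants[[b]])
    }
  }
})

test_that("closure agrees with one-step fixpoint expansion on random DAGs", {
  for (seed in c(11, 42, 99)) {
    g <- generate_dag_ontology(60, max_parents = 3L, depth = 4L, seed = seed)
    cl <- compute_closure(g)
    ids <- names(g$concepts)
    for (v in ids[seq(1, length(ids), by = 5)]) {
      expect_identical(cl$ancestors[[v]], oracle_ancestors(g, v))
    }
    # transitivity: ancestors of ancestors are ancestors
    for (v in ids) {
      expect_true(all(unlist(cl$ancestors[cl$ancestors[[v]]]) %in%
                        cl$ancestors[[v]]))
    }
  }
})

test_that("cycle detection returns a witness and merging can induce cycles", {
  expect_identical(detect_cycles(toy_graph()), list())

  cyc <- ontology_graph(list(
    mk_concept("ROOT", "A1"), mk_concept("A", "ROOT"),
    mk_concept("B", "ROOT"), mk_concept("A1", "A"), mk_concept("A2", "A")))
  found <- detect_cycles(cyc)
  expect_gt(length(found), 0)
  expect_true(all(c("ROOT", "A", "A1") %in% found[[1]]))
  expect_error(compute_closure(cyc), "cyclic")

  # u below v in ont1, the mapped copies the other way round in ont2
  g1 <- ontology_graph(list(mk_concept("v", ont = "o1", xrefs = "KV"),
                            mk_concept("u", "v", ont = "o1", xrefs = "KU")))
  g2 <- ontology_graph(list(mk_concept("u2", ont = "o2", xrefs = "KU"),
                            mk_concept("v2", "u2", ont = "o2",
                                       xrefs = "KV")))
  expect_identical(detect_cycles(g1), list())
  expect_identical(detect_cycles(g2), list())
  gm <- merge_on_xrefs(list(g1, g2))
  expect_gt(length(detect_cycles(gm)), 0)
})

test_that("constructor rejects self-loops and unknown parents", {
  expect_error(ontology_graph(list(mk_concept("X", "X"))), "itself")
  expect_error(ontology_graph(list(mk_concept("X", "Y"))), "unknown parent")
  expect_error(ontology_graph(list(mk_concept("X"), mk_concept("X"))),
               "duplicate")
})
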