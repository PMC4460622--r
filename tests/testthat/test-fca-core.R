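test_that("derivation operators reproduce the hypertriglyceridemia context extract", {
  K <- hypertriglyceridemia_context()
  expect_identical(derive_intent("10365", K), c("0", "19118", "740154"))
  expect_identical(derive_intent(character(0), K),
                   c("0", "19118", "6260", "740154"))
  expect_identical(derive_intent(c("10365", "10406"), K), c("0", "19118"))
  expect_identical(derive_extent(c("0", "19118", "740154"), K),
                   c("10365", "12115"))
  expect_identical(derive_extent(character(0), K),
                   c("10365", "10406", "12115", "191723"))
  expect_identical(derive_extent("6260", K), character(0))
})

test_that("formal-concept membership requires both derivations to close", {
  K <- hypertriglyceridemia_context()
  expect_true(is_formal_concept(c("10365", "12115"),
                                c("0", "19118", "740154"), K))
  expect_false(is_formal_concept("10365", c("0", "19118", "740154"), K))
  expect_true(is_formal_concept(K$objects, derive_intent(K$objects, K), K))
})

test_that("the hypertriglyceridemia 4x4 extract yields exactly the three chain concepts", {
  lat <- enumerate_concepts(hypertriglyceridemia_context())
  expect_length(lat$concepts, 3)
  keys <- concept_keys(lat$concepts)
  expect_identical(keys, sort(c(
    "|0,19118,6260,740154",
    "10365,12115|0,19118,740154",
    "10365,10406,12115,191723|0,19118")))
  # a 3-chain: two cover edges, total order
  expect_identical(nrow(lat$hasse), 2L)
  expect_true(all(lat$leq[lat$bottom, ]))
  expect_true(all(lat$leq[, lat$top]))
  expect_identical(sort(lat$level), c(0L, 1L, 2L))
})

test_that("degenerate contexts have the expected single concept", {
  empty <- formal_context(character(0), character(0),
                          matrix(logical(0), 0, 0))
  lat0 <- enumerate_concepts(empty)
  expect_length(lat0$concepts, 1)
  expect_identical(lat0$concepts[[1]]$extent, character(0))
  expect_identical(lat0$concepts[[1]]$intent, character(0))

  full <- generate_random_context(4, 3, density = 1, seed = 1)
  latf <- enumerate_concepts(full)
  expect_length(latf$concepts, 1)
  expect_identical(latf$concepts[[1]]$extent, full$objects)
  expect_identical(latf$concepts[[1]]$intent, full$attributes)

  none <- generate_random_context(3, 4, density = 0, seed = 1)
  latn <- enumerate_concepts(none)
  expect_length(latn$concepts, 2)
})

test_that("the enumeration size guard names the limit flag", {
  K <- generate_random_context(10, 10, 0.5, seed = 2)
  expect_error(enumerate_concepts(K, max_cells = 50), "max_cells")
})

test_that("NextClosure agrees with exhaustive brute force on random contexts", {
  set.seed(2024)
  sizes <- cbind(sample(2:8, 60, replace = TRUE),
                 sample(2:8, 60, replace = TRUE))
  dens <- stats::runif(60, 0.15, 0.85)
  for (i in seq_len(60)) {
    K <- generate_random_context(sizes[i, 1], sizes[i, 2], dens[i],
                                 seed = 5000 + i)
    lat <- enumerate_concepts(K)
    expect_identical(concept_keys(lat$concepts),
                     concept_keys(brute_force_concepts(K)))
    expect_lte(length(lat$concepts),
               2^min(length(K$objects), length(K$attributes)))
  }
})

test_that("every pair of concepts has a meet and a join", {
  for (seed in c(31, 32, 33)) {
    K <- generate_random_context(6, 6, 0.4, seed = seed)
    lat <- enumerate_concepts(K)
    k <- length(lat$concepts)
    expect_length(lat$top, 1)
    expect_length(lat$bottom, 1)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        lower <- which(lat$leq[, i] & lat$leq[, j])
        meet <- lower[vapply(lower, function(h) {
          all(lat$leq[lower, h])
        }, logical(1))]
        expect_length(meet, 1)
        upper <- which(lat$leq[i, ] & lat$leq[j, ])
        join <- upper[vapply(upper, function(h) {
          all(lat$leq[h, upper])
        }, logical(1))]
        expect_length(join, 1)
      }
    }
  }
})

test_that("lattice order is a partial order matching order_leq", {
  K <- generate_random_context(5, 7, 0.5, seed = 77)
  lat <- enumerate_concepts(K)
  k <- length(lat$concepts)
  for (i in seq_len(k)) {
    expect_true(lat$leq[i, i])
    for (j in seq_len(k)) {
      expect_identical(lat$leq[i, j],
                       order_leq(lat$concepts[[i]], lat$concepts[[j]]))
      if (i != j && lat$leq[i, j]) expect_false(lat$leq[j, i])
    }
  }
})

test_that("Hasse edges equal the definitional transitive reduction", {
  for (seed in c(8, 18, 28)) {
    K <- generate_random_context(6, 5, 0.45, seed = seed)
    lat <- enumerate_concepts(K)
    got <- hasse_edges(lat)
    want <- oracle_hasse(lat)
    expect_identical(unname(got[, 1:2, drop = FALSE]),
                     unname(want))
  }
})

test_that("closure laws hold for sampled subsets (Galois connection)", {
  contexts <- c(list(hypertriglyceridemia_context()),
                lapply(1:5, function(s) {
                  generate_random_context(8, 8, 0.4, seed = 900 + s)
                }))
  set.seed(99)
  for (K in contexts) {
    for (rep in 1:20) {
      A2 <- K$objects[stats::runif(length(K$objects)) < 0.5]
      A1 <- A2[stats::runif(length(A2)) < 0.6]
      # extensivity and idempotence
      A1cc <- derive_extent(derive_intent(A1, K), K)
      expect_true(all(A1 %in% A1cc))
      expect_identical(derive_intent(A1cc, K), derive_intent(A1, K))
      # antitonicity
      expect_true(all(derive_intent(A2, K) %in% derive_intent(A1, K)))
    }
    expect_true(verify_galois(K, n_samples = 50, seed = 42))
  }
})

test_that("a corrupted derivation operator is caught by the Galois laws", {
  K <- hypertriglyceridemia_context()
  # dropping one attribute from A' breaks extensivity of B -> B''
  broken_intent <- function(A, K) setdiff(derive_intent(A, K), "740154")
  A <- c("10365", "12115")
  B <- broken_intent(A, K)
  expect_false(setequal(derive_extent(B, K), A) &&
                 setequal(broken_intent(derive_extent(B, K), K), B) &&
                 all(derive_intent(A, K) %in% B))
})

test_that("build_context uses strict ancestry and reproduces the extract", {
  cl <- compute_closure(hypertriglyceridemia_ontology())
  K <- build_context(c("10365", "12115", "10406", "191723"), cl)
  expect_identical(K$attributes, c("0", "19118", "740154"))
  T1 <- hypertriglyceridemia_context()
  expect_identical(K$incidence,
                   T1$incidence[K$objects, K$attributes])
  # objects never appear among their own attributes
  expect_length(intersect(K$objects, K$attributes), 0)

  cl_toy <- compute_closure(toy_graph())
  K_root <- build_context("ROOT", cl_toy)
  expect_length(K_root$attributes, 0)
  expect_length(enumerate_concepts(K_root)$concepts, 1)
  expect_error(build_context(character(0), cl_toy), "non-empty")
})

test_that("disjoint chains give a block-diagonal incidence", {
  g <- ontology_graph(list(
    mk_concept("p"), mk_concept("p1", "p"), mk_concept("p2", "p1"),
    mk_concept("q"), mk_concept("q1", "q"), mk_concept("q2", "q1")))
  cl <- compute_closure(g)
  K <- build_context(c("p2", "q2"), cl)
  expect_false(any(K$incidence["p2", c("q", "q1")]))
  expect_false(any(K$incidence["q2", c("p", "p1")]))
  expect_true(all(K$incidence["p2", c("p", "p1")]))
})

test_that("context matrices round-trip through the TSV format", {
  T1 <- hypertriglyceridemia_context()
  expect_identical(sum(T1$incidence), 10L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_context_matrix(T1, f)
  back <- read_context_matrix(f)
  expect_identical(back$objects, T1$objects)
  expect_identical(back$attributes, T1$attributes)
  expect_identical(back$incidence, T1$incidence)

  for (seed in c(4, 44)) {
    K <- generate_random_context(6, 9, 0.3, seed = seed)
    write_context_matrix(K, f)
    expect_identical(read_context_matrix(f)$incidence, K$incidence)
  }

  bad <- withr::local_tempfile(
    lines = c("object_id\tm1\tm2", "g1\t1\t2"), fileext = ".tsv")
  expect_error(read_context_matrix(bad), "invalid cell")
})
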