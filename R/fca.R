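# Formal Concept Analysis: formal contexts K = (G, M, I), the derivation
# operators A' and B', formal-concept enumeration by NextClosure, the
# concept-lattice order and its Hasse diagram, and a sampling check of
# the Galois-connection laws.
#
# A formal concept (A, B) is a maximal rectangle of the incidence
# matrix: A' = B and B' = A.  Concepts are ordered by
# (A1,B1) <= (A2,B2)  <=>  A1 subset A2  <=>  B2 subset B1.

#' Construct a formal context
#'
#' @param objects Character vector of object ids (G).
#' @param attributes Character vector of attribute ids (M).
#' @param incidence Logical (or 0/1) matrix of dimension |G| x |M|;
#'   rows are objects, columns attributes.
#' @return An object of class `formal_context`: list with sorted
#'   `objects`, sorted `attributes`, and the logical `incidence` matrix
#'   with dimnames.  Orderings are deterministic (sorted ids) so lattice
#'   output is stable across runs.
#' @export
formal_context <- function(objects, attributes, incidence) {
  objects <- as.character(objects)
  attributes <- as.character(attributes)
  stopifnot(!anyDuplicated(objects), !anyDuplicated(attributes))
  incidence <- matrix(as.logical(incidence),
                      nrow = length(objects), ncol = length(attributes),
                      dimnames = list(objects, attributes))
  oo <- order(objects); ao <- order(attributes)
  structure(list(objects = objects[oo],
                 attributes = attributes[ao],
                 incidence = incidence[oo, ao, drop = FALSE]),
            class = "formal_context")
}

#' @export
print.formal_context <- function(x, ...) {
  cat("Formal context: |G| = ", length(x$objects),
      ", |M| = ", length(x$attributes),
      ", |I| = ", sum(x$incidence), "\n", sep = "")
  invisible(x)
}

#' Derivation operators
#'
#' `derive_intent(A)` returns A' = the attributes shared by every object
#' in A; `derive_extent(B)` returns B' = the objects having every
#' attribute in B.  The empty set derives to the full opposite side
#' (vacuous universal quantification).
#'
#' @param A Character vector of object ids (subset of G).
#' @param B Character vector of attribute ids (subset of M).
#' @param K A [formal_context].
#' @return Sorted character vector.
#' @export
derive_intent <- function(A, K) {
  stopifnot(all(A %in% K$objects))
  if (!length(A)) return(K$attributes)
  sub <- K$incidence[A, , drop = FALSE]
  K$attributes[colSums(sub) == length(A)]
}

#' @rdname derive_intent
#' @export
derive_extent <- function(B, K) {
  stopifnot(all(B %in% K$attributes))
  if (!length(B)) return(K$objects)
  sub <- K$incidence[, B, drop = FALSE]
  K$objects[rowSums(sub) == length(B)]
}

#' Test whether (A, B) is a formal concept of K
#'
#' True iff both derivations close: A' = B and B' = A.
#'
#' @inheritParams derive_intent
#' @return Logical scalar.
#' @export
is_formal_concept <- function(A, B, K) {
  setequal(derive_intent(A, K), B) && setequal(derive_extent(B, K), A)
}

# attribute-set closure B -> (B')' on logical index vectors
close_attrs <- function(b, inc) {
  if (any(b)) {
    ext <- rowSums(inc[, b, drop = FALSE]) == sum(b)
  } else {
    ext <- rep(TRUE, nrow(inc))
  }
  if (any(ext)) {
    colSums(inc[ext, , drop = FALSE]) == sum(ext)
  } else {
    rep(TRUE, ncol(inc))
  }
}

#' Enumerate all formal concepts of a context
#'
#' Primary enumerator is NextClosure: attribute sets are generated in
#' lectic order by the closure operator B -> (B')', which visits every
#' closed intent exactly once with memory linear in |M|.  The resulting
#' concepts are re-sorted deterministically (extent size, then extent
#' ids) and the order relation and Hasse cover edges are attached.
#'
#' @param K A [formal_context].
#' @param max_cells Size guard: refuse contexts with more than this many
#'   cells (default 1e6); raise it explicitly for larger contexts.
#' @return An object of class `concept_lattice`: list with `concepts`
#'   (each a list with sorted `extent` and `intent`), `leq` (logical
#'   matrix, `leq[i, j]` iff concept i <= concept j), `hasse` (two-column
#'   integer matrix of cover edges, lower -> upper), `top` and `bottom`
#'   indices, and `level` (integer BFS depth from the top along cover
#'   edges).
#' @export
enumerate_concepts <- function(K, max_cells = 1e6) {
  stopifnot(inherits(K, "formal_context"))
  ncells <- length(K$objects) * length(K$attributes)
  if (ncells > max_cells) {
    stop("enumerate_concepts: context has ", ncells,
         " cells, exceeding max_cells = ", max_cells,
         "; pass a larger max_cells to proceed", call. = FALSE)
  }
  inc <- K$incidence
  m <- ncol(inc)
  intents <- list()
  b <- close_attrs(rep(FALSE, m), inc)
  intents[[1]] <- b
  if (m > 0) {
    repeat {
      nxt <- NULL
      for (i in seq(m, 1)) {
        if (b[i]) next
        cand <- b & (seq_len(m) < i)
        cand[i] <- TRUE
        d <- close_attrs(cand, inc)
        # lectic successor test: no new element below i
        if (!any(d[seq_len(i - 1L)] & !b[seq_len(i - 1L)])) {
          nxt <- d
          break
        }
      }
      if (is.null(nxt)) break
      b <- nxt
      intents[[length(intents) + 1L]] <- b
    }
  }
  concepts <- lapply(intents, function(bi) {
    B <- K$attributes[bi]
    A <- derive_extent(B, K)
    list(extent = A, intent = B)
  })
  # deterministic order: extent size, then extent ids
  key <- vapply(concepts, function(cc) {
    sprintf("%06d|%s", length(cc$extent), paste(cc$extent, collapse = ","))
  }, character(1))
  concepts <- concepts[order(key)]
  build_lattice(concepts, K)
}

build_lattice <- function(concepts, K) {
  k <- length(concepts)
  ext <- matrix(FALSE, nrow = k, ncol = length(K$objects),
                dimnames = list(NULL, K$objects))
  for (i in seq_len(k)) ext[i, concepts[[i]]$extent] <- TRUE
  leq <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      leq[i, j] <- !any(ext[i, ] & !ext[j, ])
    }
  }
  strict <- leq & !t(leq) & !diag(TRUE, k)
  # also drop reflexive in the k = 1 case
  diag(strict) <- FALSE
  # transitive reduction: keep i < j with no intermediate
  reach2 <- (strict %*% strict) > 0
  cover <- strict & !reach2
  hasse <- which(cover, arr.ind = TRUE)
  hasse <- hasse[order(hasse[, 1], hasse[, 2]), , drop = FALSE]
  colnames(hasse) <- c("lower", "upper")
  top <- which(vapply(seq_len(k), function(i) all(leq[, i]), logical(1)))
  bottom <- which(vapply(seq_len(k), function(i) all(leq[i, ]), logical(1)))
  # BFS level from the top along downward cover edges
  level <- rep(NA_integer_, k)
  if (k > 0) {
    level[top] <- 0L
    frontier <- top
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        below <- hasse[hasse[, "upper"] == u, "lower"]
        new <- below[is.na(level[below])]
        level[new] <- level[u] + 1L
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
  }
  structure(list(concepts = concepts, leq = leq, hasse = hasse,
                 top = top, bottom = bottom, level = level,
                 objects = K$objects, attributes = K$attributes),
            class = "concept_lattice")
}

#' @export
print.concept_lattice <- function(x, ...) {
  cat("Concept lattice: ", length(x$concepts), " formal concepts, ",
      nrow(x$hasse), " cover edges, ", max(c(0L, x$level), na.rm = TRUE) + 1L,
      " levels\n", sep = "")
  invisible(x)
}

#' Lattice order on formal concepts
#'
#' (A1,B1) <= (A2,B2) iff A1 is a subset of A2 and B2 a subset of B1;
#' for concepts of one context the two subset tests are equivalent, but
#' both are checked.
#'
#' @param F1,F2 Formal concepts (lists with `extent` and `intent`).
#' @return Logical scalar.
#' @export
order_leq <- function(F1, F2) {
  all(F1$extent %in% F2$extent) && all(F2$intent %in% F1$intent)
}

#' Cover edges of the concept lattice
#'
#' The Hasse diagram: (F1, F2) is an edge iff F1 < F2 with no concept
#' strictly between — the transitive reduction of the order.
#'
#' @param lattice A [enumerate_concepts] result.
#' @return Two-column integer matrix (`lower`, `upper`) of concept
#'   indices.
#' @export
hasse_edges <- function(lattice) {
  lattice$hasse
}

#' Spot-check the Galois-connection laws on a context
#'
#' Samples random object and attribute subsets and asserts the three
#' laws of the derivation pair: antitonicity in both directions
#' (X1 subset X2 implies X2' subset X1') and extensivity
#' (X subset X'').  These hold for every formal context; the check
#' exists to guard the implementation, not the theory.
#'
#' @param K A [formal_context].
#' @param n_samples Number of sampled subset pairs.
#' @param seed Integer seed for reproducible sampling.
#' @return TRUE if every sampled law held, otherwise FALSE.
#' @export
verify_galois <- function(K, n_samples = 100, seed = 1) {
  set.seed(seed)
  rsub <- function(universe) {
    if (!length(universe)) return(character(0))
    universe[stats::runif(length(universe)) < 0.5]
  }
  for (s in seq_len(n_samples)) {
    A2 <- rsub(K$objects); A1 <- rsub(A2)
    B2 <- rsub(K$attributes); B1 <- rsub(B2)
    ok <- all(derive_intent(A2, K) %in% derive_intent(A1, K)) &&
      all(derive_extent(B2, K) %in% derive_extent(B1, K)) &&
      all(A1 %in% derive_extent(derive_intent(A1, K), K)) &&
      all(B1 %in% derive_intent(derive_extent(B1, K), K))
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Build the formal context of an object set over its super-concepts
#'
#' Objects are ontology concepts (the matched and derived set) and
#' attributes are their strict super-concepts from the subsumption
#' closure; (g, m) is incident iff m is a strict ancestor of g.  An
#' object is never its own attribute.
#'
#' @param objects Non-empty character vector of concept ids.
#' @param closure A [closure_table] covering the objects.
#' @return A [formal_context].
#' @export
build_context <- function(objects, closure) {
  objects <- sort(unique(as.character(objects)))
  if (!length(objects)) {
    stop("build_context: objects must be non-empty", call. = FALSE)
  }
  M <- ancestors_of(objects, closure)
  inc <- matrix(FALSE, nrow = length(objects), ncol = length(M),
                dimnames = list(objects, M))
  for (g in objects) {
    inc[g, intersect(closure$ancestors[[g]], M)] <- TRUE
  }
  formal_context(objects, M, inc)
}

#' Read / write a context matrix file
#'
#' Tab-separated: header row is `object_id` followed by the attribute
#' ids; each body row is an object id followed by 0/1 cells.  Any cell
#' other than 0 or 1 is a parse error.  `write_context_matrix` and
#' `read_context_matrix` are mutually inverse.
#'
#' @param path File path.
#' @param K A [formal_context].
#' @return `read_context_matrix` returns a [formal_context];
#'   `write_context_matrix` returns `path` invisibly.
#' @export
read_context_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("read_context_matrix: empty file", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  attrs <- header[-1]
  body <- lapply(lines[-1], function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]])
  objs <- vapply(body, `[[`, character(1), 1L)
  inc <- matrix(FALSE, nrow = length(objs), ncol = length(attrs),
                dimnames = list(objs, attrs))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    if (length(cells) != length(attrs)) {
      stop("read_context_matrix: row ", i + 1L, " has ", length(cells),
           " cells, expected ", length(attrs), call. = FALSE)
    }
    bad <- !cells %in% c("0", "1")
    if (any(bad)) {
      stop("read_context_matrix: invalid cell value '",
           cells[bad][1], "' at row ", i + 1L, call. = FALSE)
    }
    inc[i, ] <- cells == "1"
  }
  formal_context(objs, attrs, inc)
}

#' @rdname read_context_matrix
#' @export
write_context_matrix <- function(K, path) {
  stopifnot(inherits(K, "formal_context"))
  header <- paste(c("object_id", K$attributes), collapse = "\t")
  rows <- vapply(K$objects, function(g) {
    paste(c(g, as.integer(K$incidence[g, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Export a lattice as a JSON-ready structure
#'
#' @param lattice A [enumerate_concepts] result.
#' @return A list with `concepts` (extent/intent id vectors) and `edges`
#'   (lower/upper index pairs, 1-based), suitable for
#'   [jsonlite::toJSON()].
#' @export
lattice_to_list <- function(lattice) {
  list(concepts = lapply(lattice$concepts, function(cc) {
         list(extent = as.list(cc$extent), intent = as.list(cc$intent))
       }),
       edges = lapply(seq_len(nrow(lattice$hasse)), function(i) {
         as.list(unname(lattice$hasse[i, ]))
       }))
}
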