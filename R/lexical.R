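# Purely lexical matching of a free-text query against concept synonyms.
# No semantics is used at this stage: matching is exact equality of
# normalized synonym strings with contiguous token spans of the query.

#' Normalize free text to a token sequence
#'
#' Lowercases, replaces every punctuation character with a space, and
#' collapses whitespace.  Deterministic; the same normalization is applied
#' to synonyms at indexing time and to queries at match time.
#'
#' @param text A character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(text)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(x)
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

norm_key <- function(text) paste(normalize_text(text), collapse = " ")

#' Build a synonym index over an ontology graph
#'
#' Every synonym of every concept (preferred labels included) is indexed
#' under its normalized full string.  Ambiguity is preserved: a synonym
#' shared by several concepts maps to all of them.
#'
#' @param graph An [ontology_graph].
#' @return An object of class `synonym_index`: a named list mapping
#'   normalized synonym strings to character vectors of concept ids.
#' @export
build_index <- function(graph) {
  keys <- list()
  for (co in graph$concepts) {
    for (s in co$synonyms) {
      k <- norm_key(s)
      if (!nzchar(k)) next
      keys[[k]] <- c(keys[[k]], co$concept_id)
    }
  }
  keys <- lapply(keys, function(v) sort(unique(v)))
  structure(keys, class = "synonym_index")
}

#' @export
print.synonym_index <- function(x, ...) {
  cat("Synonym index: ", length(x), " normalized strings over ",
      length(unique(unlist(x))), " concepts\n", sep = "")
  invisible(x)
}

#' Match a free-text query against the synonym index
#'
#' The query is tokenized and matched against all indexed synonyms.
#' A concept matches if one of its normalized synonyms equals the whole
#' normalized query or a contiguous token sub-sequence of it.  Spans are
#' selected longest-match, left-to-right, non-overlapping, which makes
#' multi-concept queries deterministic.  This step uses no semantics.
#'
#' @param query A character scalar.
#' @param index A [build_index] result.
#' @return An object of class `match_result`: list with `query`, `tokens`,
#'   `matched_ids` (sorted) and `per_synonym_hits` (named list).
#' @export
match_query <- function(query, index) {
  stopifnot(inherits(index, "synonym_index"))
  tokens <- normalize_text(query)
  hits <- list()
  n <- length(tokens)
  i <- 1L
  while (i <= n) {
    found <- FALSE
    for (j in seq(n, i)) {
      key <- paste(tokens[i:j], collapse = " ")
      if (!is.null(index[[key]])) {
        hits[[key]] <- index[[key]]
        i <- j + 1L
        found <- TRUE
        break
      }
    }
    if (!found) i <- i + 1L
  }
  structure(list(query = query,
                 tokens = tokens,
                 matched_ids = sort(unique(as.character(
                   unlist(hits, use.names = FALSE)))),
                 per_synonym_hits = hits),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Query: \"", x$query, "\" (", length(x$tokens), " tokens)\n", sep = "")
  cat("Matched concepts (", length(x$matched_ids), "): ",
      paste(utils::head(x$matched_ids, 10), collapse = ", "),
      if (length(x$matched_ids) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}
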