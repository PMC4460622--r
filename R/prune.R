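# Coverage-ratio pruning of the concept lattice.
#
# During a top-down, breadth-first traversal of the lattice, every
# attribute (super-concept) encountered in an intent is scored by how
# well its sub-concept closure is covered by the sub-concept closure of
# the matched/derived object set:
#
#   LiA = strict sub-concepts of the attribute
#   LiO = union over the objects of {object} + its strict sub-concepts
#   ratio = |LiA intersect LiO| / |LiA|       (1 when LiA is empty)
#
# Attributes whose ratio falls below the pruning threshold have too many
# sub-concepts unrelated to the matches and are pruned; the rest are
# candidates proposed to the user.  One feedback question is asked per
# lattice level — on the lowest-ratio candidate of that level — and a
# rejection eliminates everything the rejected concept subsumes.

#' Coverage ratio of an attribute concept against an object set
#'
#' @param a An attribute concept id.
#' @param objects Character vector of object concept ids.
#' @param closure A [closure_table].
#' @param threshold Pruning threshold in \[0, 1\] used to set the status;
#'   a ratio exactly at the threshold satisfies it (status `candidate`).
#' @return An object of class `pruning_decision`: list with
#'   `attribute_id`, `ratio`, `n_sub` (|LiA|), `n_covered`
#'   (|LiA intersect LiO|) and `status` (`"pruned"` or `"candidate"`).
#'   An attribute with no sub-concepts is vacuously covered (ratio 1).
#' @export
coverage_ratio <- function(a, objects, closure, threshold = 0.75) {
  stopifnot(length(a) == 1L, a %in% names(closure$ancestors))
  LiA <- closure$descendants[[a]]
  LiO <- descendants_of(objects, closure, reflexive = TRUE)
  n_sub <- length(LiA)
  n_covered <- length(intersect(LiA, LiO))
  ratio <- if (n_sub > 0L) n_covered / n_sub else 1
  structure(list(attribute_id = a, ratio = ratio, n_sub = n_sub,
                 n_covered = n_covered,
                 status = if (ratio < threshold) "pruned" else "candidate"),
            class = "pruning_decision")
}

#' @export
print.pruning_decision <- function(x, ...) {
  cat(sprintf("%s: ratio %.3f (%d/%d sub-concepts covered) -> %s\n",
              x$attribute_id, x$ratio, x$n_covered, x$n_sub, x$status))
  invisible(x)
}

decisions_df <- function(decisions) {
  if (!length(decisions)) {
    return(data.frame(attribute = character(0), ratio = numeric(0),
                      n_sub = integer(0), n_covered = integer(0),
                      status = character(0), level = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(attribute = vapply(decisions, `[[`, character(1), "attribute_id"),
             ratio = vapply(decisions, `[[`, numeric(1), "ratio"),
             n_sub = vapply(decisions, `[[`, integer(1), "n_sub"),
             n_covered = vapply(decisions, `[[`, integer(1), "n_covered"),
             status = vapply(decisions, `[[`, character(1), "status"),
             level = vapply(decisions, function(d) as.integer(d$level),
                            integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Top-down lattice traversal with coverage pruning and user feedback
#'
#' Breadth-first from the top concept, by lattice level; within a level,
#' concepts are visited in sorted-extent order and concepts whose intent
#' is fully decided are skipped.  Every intent attribute gets exactly one
#' decision: `pruned` when its coverage ratio is below the threshold,
#' otherwise `candidate`.  If a feedback oracle is supplied, one question
#' is asked per level — on that level's lowest-ratio new candidate —
#' keeping the user burden minimal.  An accepted candidate becomes
#' `confirmed`; a rejected one becomes `rejected` and every concept it
#' subsumes is eliminated from the refinement (attributes among them are
#' marked `rejected` as well, and matched or derived descendants are
#' dropped from the final set by [classify_roles]).
#'
#' @param lattice A [enumerate_concepts] result built from
#'   `build_context(objects, closure)`.
#' @param objects The object concept ids of the context.
#' @param closure A [closure_table].
#' @param threshold Pruning threshold in \[0, 1\] (default 0.75).
#' @param oracle `NULL`, or a function `function(concept_id)` returning
#'   `TRUE` (accept) or `FALSE` (reject); see [gold_oracle()].
#' @return A list with `decisions` (a data frame: attribute, ratio,
#'   n_sub, n_covered, status, level), `rejected` (ids rejected by the
#'   oracle) and `eliminated` (rejected ids plus everything they
#'   subsume).
#' @export
traverse_and_prune <- function(lattice, objects, closure, threshold = 0.75,
                               oracle = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("traverse_and_prune: threshold must be a number in [0, 1]",
         call. = FALSE)
  }
  M <- lattice$attributes
  decided <- stats::setNames(rep(FALSE, length(M)), M)
  decisions <- stats::setNames(vector("list", length(M)), M)
  rejected <- character(0)
  eliminated <- character(0)
  LiO <- descendants_of(objects, closure, reflexive = TRUE)
  levels_present <- sort(unique(lattice$level))
  for (lv in levels_present) {
    at_level <- which(lattice$level == lv)
    # sorted-extent order within the level
    keys <- vapply(at_level, function(i) {
      paste(lattice$concepts[[i]]$extent, collapse = ",")
    }, character(1))
    at_level <- at_level[order(keys)]
    new_candidates <- character(0)
    for (ci in at_level) {
      intent <- lattice$concepts[[ci]]$intent
      todo <- intent[!decided[intent]]
      if (!length(todo)) next  # intent fully decided: skip this concept
      for (a in sort(todo)) {
        d <- coverage_ratio(a, objects, closure, threshold)
        d$level <- lv
        decisions[[a]] <- d
        decided[[a]] <- TRUE
        if (d$status == "candidate") new_candidates <- c(new_candidates, a)
      }
    }
    if (!is.null(oracle) && length(new_candidates)) {
      ratios <- vapply(decisions[new_candidates], `[[`, numeric(1), "ratio")
      ask <- new_candidates[order(ratios, new_candidates)][1]
      if (isTRUE(oracle(ask))) {
        decisions[[ask]]$status <- "confirmed"
      } else {
        decisions[[ask]]$status <- "rejected"
        rejected <- c(rejected, ask)
        subsumed <- closure$descendants[[ask]]
        eliminated <- sort(unique(c(eliminated, ask, subsumed)))
        # everything subsumed is eliminated without further questions
        for (s in intersect(subsumed, M)) {
          if (decided[[s]] && decisions[[s]]$status == "pruned") next
          if (decided[[s]]) {
            decisions[[s]]$status <- "rejected"
          } else {
            d <- coverage_ratio(s, objects, closure, threshold)
            d$level <- lv
            d$status <- "rejected"
            decisions[[s]] <- d
            decided[[s]] <- TRUE
          }
        }
      }
    }
  }
  list(decisions = decisions_df(decisions[M[decided[M]]]),
       rejected = sort(rejected),
       eliminated = eliminated)
}

#' Classify concepts into matched / derived / potential / remaining roles
#'
#' Combines the lexical matches, the semantic expansion and the pruning
#' decisions of one refinement session into the four concept roles:
#' `matched` (lexical hits), `derived` (expansion concepts that were
#' neither matched nor decided as attributes), `potential`
#' (super-concepts surviving the threshold, i.e. status `candidate` or
#' `confirmed`), and `remaining` (pruned or rejected super-concepts).
#' The final accepted set is matched + derived + potential minus
#' everything eliminated by an oracle rejection.
#'
#' @param matched Character vector of matched concept ids.
#' @param expansion An [two_hop] result (or `NULL` for no expansion).
#' @param pruning A [traverse_and_prune] result (or `NULL`).
#' @return An object of class `refinement_result`; see [refine_hoi()].
#' @export
classify_roles <- function(matched, expansion = NULL, pruning = NULL) {
  matched <- sort(unique(matched))
  expanded <- if (is.null(expansion)) character(0) else expansion$second_hop
  dec <- if (is.null(pruning)) decisions_df(list()) else pruning$decisions
  eliminated <- if (is.null(pruning)) character(0) else pruning$eliminated
  rejected <- if (is.null(pruning)) character(0) else pruning$rejected
  potential <- sort(setdiff(
    dec$attribute[dec$status %in% c("candidate", "confirmed")], matched))
  remaining <- sort(setdiff(
    dec$attribute[dec$status %in% c("pruned", "rejected")], matched))
  derived <- sort(setdiff(expanded, c(matched, potential, remaining)))
  derived <- setdiff(derived, eliminated)
  potential <- setdiff(potential, eliminated)
  final <- sort(setdiff(unique(c(matched, derived, potential)), eliminated))
  structure(list(matched = matched,
                 derived = derived,
                 potential = potential,
                 remaining = remaining,
                 rejected = sort(rejected),
                 eliminated = sort(eliminated),
                 decisions = dec,
                 final = final),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("HOI refinement result\n")
  if (!is.null(x$query)) cat("  query:     \"", x$query, "\"\n", sep = "")
  cat("  matched:   ", length(x$matched),
      "\n  derived:   ", length(x$derived),
      "\n  potential: ", length(x$potential),
      "\n  remaining: ", length(x$remaining),
      "\n  rejected:  ", length(x$rejected),
      "\n  final set: ", length(x$final), " concept(s)\n", sep = "")
  pr <- x$decisions[x$decisions$status == "pruned", , drop = FALSE]
  if (nrow(pr)) {
    cat("  pruned attributes (ratio): ",
        paste(sprintf("%s (%.2f)", utils::head(pr$attribute, 8),
                      utils::head(pr$ratio, 8)), collapse = ", "),
        if (nrow(pr) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Gold-standard feedback oracle
#'
#' Returns a feedback function that accepts a concept iff it belongs to
#' the given gold set — the automated stand-in for physician feedback in
#' evaluation runs.
#'
#' @param gold Character vector of accepted concept ids.
#' @return A `function(concept_id) -> logical`.
#' @export
gold_oracle <- function(gold) {
  gold <- as.character(gold)
  function(concept_id) concept_id %in% gold
}
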