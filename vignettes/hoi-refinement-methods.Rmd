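---
title: "Defining Health Outcomes of Interest with SQE and FCA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining Health Outcomes of Interest with SQE and FCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoilattice)
```

## The problem

A Health Outcome of Interest — say *myocardial infarction* or
*hypercholesterolemia* — is operationalized, for record selection or
text mining, as a set of ontology concepts whose terms count as
evidence of the condition.  Assembling such a set by hand across many
overlapping vocabularies is slow and error-prone: broad queries drown
the user in candidates, narrow ones miss synonymous and subsumed
concepts.  `hoilattice` aims for broad coverage first (lexical matching
plus semantic expansion), then restores relevance by pruning a concept
lattice, asking the user only a few well-chosen questions.

## The model

### Merged multi-ontology graph

Each ontology contributes concepts with a preferred label, synonyms and
is-a parents.  Cross-ontology mappings are CUI-style shared keys
(`xrefs`); at load time, xref-connected components are collapsed into
single nodes whose parents, synonyms and source labels are unions over
members (`merge_on_xrefs()`).  Traversing "across ontologies" then
reduces to ordinary graph traversal.  Design choices:

* merged node identity and preferred label come from the first-loaded
  member; all other labels survive as synonyms (deterministic and
  lossless);
* multiple roots are allowed and no virtual top is injected — if a top
  concept (id 0 in the worked examples) is wanted, it must be in the
  data;
* the subsumption closure (`compute_closure()`) is **strict**: a
  concept is not its own ancestor or descendant.  Callers add
  reflexivity where the semantics require it (the object side of the
  coverage ratio does; the attribute side does not).

Merging can create cycles even from individually acyclic sources,
because different ontologies place "the same" concept at different
abstraction levels.  `detect_cycles()` must return an empty list before
the closure is materialized; this is also why the expansion below never
recurses to a fixpoint.

### Lexical matching

Matching is purely lexical: the query and every synonym are normalized
(lowercase, punctuation to spaces, whitespace collapsed) and a concept
matches when one of its synonyms equals the whole normalized query or a
contiguous token sub-span of it.  Spans are consumed longest-match,
left-to-right, non-overlapping, which makes multi-concept queries
deterministic.  No stemming, spelling correction or edit distance: the
division of labour is deliberate — recall is the expansion's job,
precision the pruning's, and a fuzzier matcher would blur
accountability between stages.  Ambiguous synonyms return every
carrier; disambiguation is left to pruning and feedback.

### Semantic Query Expansion

Downward, the seed set C derives its sub-concepts C′, and a second
round over C′ gives C″ (the "2-hop" scheme).  One derivation round is
interpreted as the **full sub-concept closure within the merged graph**
(`hop_mode = "closure"`, the default): on a merged graph a single round
already reaches everything reachable, and the second round exists for
the regime where mapping-mediated merging reveals new descendants.  The
alternative single-edge reading is kept behind `hop_mode = "edge"`
since the increment granularity of the original description is
genuinely ambiguous.  Never more than two rounds.

Upward, `minimal_ancestor_cover()` finds a small set of super-concepts
covering the matches.  Exact minimum set cover is NP-hard, so a greedy
is used; it is **deepest-first** (greatest depth, then coverage, then
id).  A pure max-coverage greedy would always pick the ontology top —
it covers everything — which is useless as a description of the
matches; preferring the deepest candidates yields the most *specific*
covering super-concepts, at the cost of sometimes using more of them
(never more than the number of matches).  Parentless matches stand for
themselves.

### FCA and the coverage ratio

The formal context takes the matched + derived concepts as objects G,
their strict super-concepts as attributes M, and subsumption as
incidence.  `enumerate_concepts()` uses NextClosure (lectic order over
attribute sets): deterministic, memory-light, standard; an exhaustive
2^|G| enumerator lives in the test suite as an independent oracle, and
the Galois laws (antitonicity, extensivity, idempotence of the
derivation operators) are property-checked on sampled subsets.
Concepts, extents and intents are kept in sorted-id order everywhere so
that lattice output — and the refinement JSON — is byte-stable.

Attributes with an empty extent are representable when a context is
read from a file (the reference extract has such a column) but are
never *generated* by `build_context()`, which does not invent
incidence.

During the top-down breadth-first traversal, each attribute *a* gets a
coverage ratio |L_A ∩ L_O| / |L_A| with L_A the strict sub-concept
closure of *a* and L_O the union of the objects' reflexive sub-concept
closures (an object trivially covers itself; L^O is a union over the
objects, the only reading consistent with the worked 16-versus-4
arithmetic).  Numerical conventions:

* empty L_A ⇒ ratio 1 (vacuous coverage; avoids 0/0);
* a ratio **exactly at** the threshold is kept as candidate — the
  worked example's 75 % "satisfies" the 75 % threshold;
* threshold pruning decides the attribute itself only.  Its
  sub-concepts still get their own decisions further down: pruning a
  concept means "too broad", not "wrong", and the method drills down
  past it.  Only explicit rejection eliminates a subtree;
* each attribute is decided exactly once; concepts whose intent is
  fully decided are skipped (an artifact choice — the original
  description does not say whether pruned attributes remove lattice
  nodes from the traversal or only mark them).

One feedback question is asked per lattice level, on that level's
lowest-ratio new candidate — the cheapest place to learn the most,
keeping user burden minimal.  Acceptance confirms; rejection eliminates
the concept and everything it subsumes from the final and potential
sets, including previously decided candidates below it.

### Roles and evaluation

The session partitions concepts into matched (lexical hits), derived
(expansion results that were not matched and not decided as
attributes), potential (candidates and confirmed super-concepts) and
remaining (pruned or rejected).  The final set is matched + derived +
potential minus everything eliminated.  `evaluate()` computes
sensitivity TP/(TP+FN) and specificity TN/(TN+FP) against a gold set
over an **explicit universe** argument — the negative space of a
term-recognition evaluation is a modelling decision, not something the
package can guess.

## Synthetic data: what it emulates and what it does not

`generate_dag_ontology()` builds single-root random DAGs with
level-stratified parent sampling (acyclicity by construction, no
rejection sampling), seeded synonyms and optional xref keys.  Synonym
text is synthetic (`"term c0012 1"`): matching is exact-string, so
imitation medical vocabulary would add nothing but accidental
ambiguity.  Default shape — a few hundred concepts, up to two parents,
depth four to five — mirrors the working scale of a single condition's
neighbourhood rather than a full 2M-CUI metathesaurus.

`plant_hoi()` emulates an annotated condition: it picks an internal
concept *h*, defines the gold set as *h* plus all sub-concepts
(downward closed by construction), and attaches unique multi-word
synonyms to *h* and a seeded sample of gold members as the query
vocabulary.  *h* is chosen **well-separated**: every strict
super-concept of a gold member outside the gold set has sub-concept
coverage below the pruning threshold.  This encodes the regime the
method targets — an outcome that is a coherent subtree, not 80 % of its
parent — and is what makes exact recovery a meaningful end-to-end
property: with a gold-standard feedback oracle, refinement attains
sensitivity and specificity 1.0 on every planted session in the suite.

Passing those tests shows the machinery is sound, not that real HOIs
are this clean: real vocabularies have lexical ambiguity across
unrelated branches, mappings of uneven quality (merged nodes with
conflicting parents, cycles), outcomes that straddle subtrees, and
queries whose terms miss the outcome root.  Full-scale evaluations
against restricted clinical-notes corpora over large multi-ontology
repositories live in exactly that regime and are not reproducible at
desk scale; this package reproduces the documented worked examples and
the method's invariants instead.

## Problem sizes and costs

NextClosure is output-sensitive; the suite enumerates contexts up to
10×10 against the brute-force oracle (200 random contexts), checks
lattice laws exhaustively on small lattices, runs 50 random pruning
sessions for threshold monotonicity, and 20 planted-recovery sessions
on ontologies of 150–300 concepts — all comfortably inside a couple of
minutes on one core.  The context-size guard (`max_cells`, default
10^6 cells) fails fast with a pointer to the flag rather than
attempting a lattice that cannot be enumerated interactively.

## Known limitations

* Only is-a subsumption is used; part-of and other relations, and
  description-logic reasoning, are out of scope.
* Matching has no abbreviation expansion or negation handling; clinical
  notes are not parsed — the package defines concept sets, it does not
  annotate text.
* The feedback policy (one lowest-ratio question per level) is a fixed
  heuristic; active-learning orderings are future work.
* `evaluate()` is only as meaningful as the universe it is given.
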