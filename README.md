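# hoilattice

Semi-automatic definition of **Health Outcomes of Interest (HOIs)** —
clinical conditions expressed as sets of ontology concepts for patient
selection, pharmacovigilance signal detection, or clinical-text mining —
from a plain free-text query over a repository of merged biomedical
ontologies.

Writing a good HOI by hand means sifting through thousands of candidate
terms across many vocabularies. `hoilattice` automates the sift and asks
the user only a handful of questions:

1. **Lexical matching.** The query is tokenized and matched, purely
   lexically, against every synonym of every concept (longest
   contiguous token span, case- and punctuation-insensitive).
2. **Semantic Query Expansion (SQE).** Matches are expanded along the
   subsumption hierarchy: two rounds of sub-concept derivation
   (*C → C′ → C″*, the "2-hop" scheme) across all ontologies at once —
   cross-ontology mappings (xrefs / shared CUIs) are merged into single
   nodes at load time, so hopping across ontologies is plain graph
   traversal.  Deliberately **no** fixpoint recursion: merging distinct
   abstraction levels can create cycles.  Upward, a deepest-first greedy
   finds a minimal set of super-concepts covering the matches.
3. **Formal Concept Analysis (FCA).** Over the formal context
   K = (G, M, I) — objects G the matched + derived concepts, attributes
   M their super-concepts, (g, m) ∈ I iff m subsumes g — all formal
   concepts (A, B) with A′ = B, B′ = A are enumerated by NextClosure and
   ordered into the concept lattice
   (A₁,B₁) ≤ (A₂,B₂) ⇔ A₁ ⊆ A₂ ⇔ B₂ ⊆ B₁.
4. **Coverage pruning with feedback.** The lattice is traversed
   top-down.  Each attribute *a* is scored by the coverage ratio
   |L_A ∩ L_O| / |L_A|, where L_A is the sub-concept closure of *a* and
   L_O the union of the objects' (reflexive) sub-concept closures.
   Ratios below the pruning threshold (default **75 %**) are pruned —
   too many unrelated sub-concepts; the rest are candidates.  One
   question per lattice level (the lowest-ratio candidate) goes to the
   user; a rejection automatically eliminates everything the rejected
   concept subsumes.

The result partitions the vocabulary into **matched**, **derived**,
**potential** and **remaining** concepts, and a final accepted HOI set.
A sensitivity/specificity harness (`evaluate()`) scores predicted sets
against a gold standard over a declared concept universe.

## Worked example

The package ships a reference 4×4 hypertriglyceridemia context
extract and the subsumption chain behind it (`hypertriglyceridemia_context()`,
`hypertriglyceridemia_ontology()`): objects 10365 (hyperlipoproteinemia type IV),
12115 (hypertriglyceridemia), 10406, 191723 under the super-concepts
740154 ⊑ 19118 ⊑ 0 (the repository top).

```r
library(hoilattice)
graph <- hypertriglyceridemia_ontology()
res <- refine_hoi("hyperlipoproteinemia type IV and hypertriglyceridemia",
                  graph)
print(res)
#> HOI refinement result
#>   query:     "hyperlipoproteinemia type IV and hypertriglyceridemia"
#>   matched:   2
#>   derived:   0
#>   potential: 1
#>   remaining: 2
#>   rejected:  0
#>   final set: 3 concept(s)
#>   pruned attributes (ratio): 0 (0.29), 19118 (0.40)
res$decisions
#>   attribute     ratio n_sub n_covered    status level
#> 1         0 0.2857143     7         2    pruned     0
#> 2     19118 0.4000000     5         2    pruned     0
#> 3    740154 1.0000000     2         2 candidate     0
```

Both lexical matches sit under 740154, whose two sub-concepts are fully
covered (ratio 1.0) — it survives as a *potential* concept and the final
HOI set is {10365, 12115, 740154}.  The broader 19118 and the top
concept 0 subsume mostly unrelated concepts (ratios 0.40 and 0.29,
below the 75 % threshold) and are pruned.  Enumerating the printed
extract itself gives its three formal concepts in a chain:

```r
enumerate_concepts(hypertriglyceridemia_context())
#> Concept lattice: 3 formal concepts, 2 cover edges, 3 levels
```

Synthetic end-to-end sessions are one call away: `simulate` plants a
gold HOI subtree in a random DAG ontology and the gold-oracle refinement
recovers it exactly (`Se = Sp = 1`):

```sh
./exec/hoilattice simulate --seed 3 --n 80 --out-dir session3
./exec/hoilattice refine --query "$(cat session3/query.txt)" \
    --ontology session3/ontology.tsv \
    --oracle gold:session3/gold.txt --out result.json
```

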