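---
title: "Mining frequent structural patterns in SBML reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining frequent structural patterns in SBML reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlpatterns)
```

## The problem

Biochemical models exchanged in SBML encode reaction networks: species
transformed, consumed or catalysed by reactions.  Across a repository of
curated models, the same small wiring motifs recur — chains of reactions
coupled through shared species, branches around a central species,
production/degradation cycles.  `sbmlpatterns` finds these recurring
structures automatically: it reduces every model to a labelled bipartite
digraph, mines all connected subgraphs that occur in a user-chosen number of
networks, and post-processes the resulting patterns into diagrams, database
queries and per-model occurrence counts that can serve as structural feature
vectors.

## The graph model

Each model becomes a directed bipartite graph:

* **Nodes** are reactions (`SBML_REACTION`) and species (`SBML_SPECIES`).
* **Edges** carry the participation role.  Reactants and modifiers point
  *into* the reaction (`IS_REACTANT`, `IS_MODIFIER`); products point *out*
  of it (`HAS_PRODUCT`).

Ingest works from SBML Level 2/3 files, from JSON edge lists
(`read_edge_json()`), or from DOT files (`read_dot()`).  Three rules shape
the extraction:

* One edge per **distinct** `(reaction, role, species)` participation.
  Stoichiometry and repeated `speciesReference` entries carry no structural
  information in this graph model, so they collapse; a species that is both
  reactant and product of one reaction keeps both edges (the labels differ).
* Species and reactions connected only through SBML *rules* yield no edges:
  only explicitly encoded reaction participations count, so rules-only
  models contribute empty networks.
* After orientation, the graph is split into **weakly connected
  components** (`split_components()`); each component is an independent
  mining transaction.  Weak connectivity is the right notion because an
  ingoing reactant edge and an outgoing product edge meeting at one species
  must join their reactions into one network.  Components of one model are
  never re-associated, but model provenance is retained for model-level
  support counting and the feature matrix.

## Frequent subgraph mining

`mine()` implements an extension-based search in the gSpan family over
canonical DFS codes.  A pattern is *frequent* when it occurs in at least
`min_support` and at most `max_support` of the graphs; a graph counts once
no matter how many embeddings it contains.  The miner returns **all**
frequent connected subgraphs up to `max_edges` edges — not only maximal
ones — including frequent single-node patterns, which are seeded from
frequent node labels before edge growth begins (plain gSpan starts from
edges).

Key design points, fixed for reproducibility:

* **DFS codes for digraphs.**  Textbook gSpan is undirected.  Each DFS edge
  tuple here is `(i, j, l_i, l_e, dir, l_j)` where `dir` records whether the
  stored graph edge runs `i -> j` or `j -> i`; the flag is ordered *after*
  the edge label in the lexicographic code comparison.  Equal minimum codes
  are exactly label-preserving digraph isomorphism, which the test suite
  checks against brute-force isomorphism search.
* **Label order.**  Node labels compare in C-locale order, so
  `SBML_REACTION < SBML_SPECIES`, and SBO-refined labels (`KIND|SBO:...`)
  order by kind then term.  Edge labels order
  `IS_REACTANT < IS_MODIFIER < HAS_PRODUCT`.  Any fixed total order is
  admissible; this one is documented so runs are comparable.
* **Pruning.**  Support is anti-monotone, so branches below `min_support`
  are cut; `max_support` is *not* anti-monotone, so over-frequent codes are
  still grown (their extensions may fall back into range) but not emitted.
  Non-minimal codes are pruned whole, which is safe because every prefix of
  a minimum DFS code is itself minimal.
* **Support units.**  `support_unit = "network"` counts connected networks
  (the miner's native transaction, and the default); `"model"` counts
  distinct source models, so several components of one model count once.
  Corpus-level statements about "models sharing a pattern" use the model
  unit; both are always recorded on each pattern.
* **Capacity.**  Subgraph isomorphism is NP-complete and low thresholds can
  make the output explode.  `max_edges` defaults to 10 (patterns of at most
  11 entities) and a `max_patterns` guard raises a typed capacity error
  instead of exhausting memory.

Determinism: for a fixed corpus and configuration two runs produce
byte-identical pattern files; output order is the DFS-lexicographic
discovery order.

## Counting occurrences per model

Mining answers "in how many graphs"; the distribution step answers "how
often within each model".  `count_embeddings()` counts **injective node
assignments** that preserve labels, edge direction and edge labels
(non-induced embeddings).  Automorphic re-assignments count separately: the
two-species/two-reaction cycle embeds twice in a single copy of itself.
This raw counting mirrors the row count of the generated database query,
whose `WHERE` clause enforces exactly pairwise node inequality.  When
distinct sub-network occurrences are wanted instead, `orbit = TRUE` divides
by the pattern's automorphism count.

`build_feature_matrix()` assembles the model-by-pattern count table: two
leading columns identify the model, pattern columns follow in descending
mining frequency (ties by pattern id), and each row is a structural feature
vector for one model.  Similarity scoring, weighting and clustering of
these vectors are deliberately out of scope.

`pattern_to_graph_query()` emits the Cypher dialect of the original graph
database: a `MATCH` anchored at the model/document pair plus one
relationship clause per edge, all pairwise `<>` inequalities, and a
`RETURN DISTINCT id, filename, count` ordered by descending count.  The
anchor relationship is `HAS_REACTION` via the pattern's first reaction
node; a species-only pattern (which has no reaction to anchor through) uses
`HAS_SPECIES` — the reference dialect only shows the reaction case, so this
is the package's own extension.

## Rendering

`render_pattern()` writes styled DOT encoding the process-description glyph
conventions: rounded rectangle for an entity, small square for a process,
plain arc for a reactant, filled arrow for a product, circle-headed arc for
a modifier.  Structural-mode images draw no text at all; SBO mode writes
the term inside/below the glyph.  Correctness is asserted at the styled-DOT
level (glyph and arc statements are a pure, byte-stable function of the
pattern), because raster output differs across rendering engines.  The
image itself comes from Graphviz when a `dot` executable is available and
otherwise from the package's own small glyph renderer on the R graphics
devices; PNG is the default format, PDF is supported.

## The synthetic corpus generator

Real curated repositories are large downloads; the generator
(`generate_corpus()`) produces corpora with the structural character of
small curated models so that every stage is testable offline:

* **Sizes.**  Per model, species and reaction counts are uniform on 3–11
  and 3–12 respectively — the typical range for most curated models — and
  each reaction draws 2–3 participating species, the commonest observed
  participation count.
* **Roles.**  Each participant is a reactant with probability 0.45, a
  product with 0.45 and a modifier with 0.10.  This favours the commonest
  encoded reaction shapes (two reactants/one product; one reactant/one
  product) while keeping modifiers present but rare, as in hand-built
  kinetic models; a chi-square check in the test suite confirms the
  generated frequencies converge to the configuration.
* **Planting.**  A planted pattern is inserted as a fresh subnetwork into a
  chosen fraction of models; with probability `fuse_prob` (default 0.25)
  one planted species is fused with an existing species, creating
  overlapping context so recovery is not trivially separable.  The ledger
  records every copy, giving ground truth for recovery and for
  lower-bounding embedding counts.
* **SBO mode.**  An optional vocabulary with sampling weights annotates
  every node, e.g. simple chemicals (`SBO:0000247`) transformed by
  biochemical reactions (`SBO:0000176`) or phosphorylation /
  de-phosphorylation pairs (`SBO:0000216` / `SBO:0000330`) acting on
  polypeptide chains (`SBO:0000252`).

What the generator does **not** emulate: kinetic laws, compartments,
heavy-tailed outlier models (hundreds of reactions, e.g. semi-automatically
assembled metabolic reconstructions), and the annotation sparsity of real
repositories.  Passing tests therefore demonstrate the correctness of the
algorithms on networks of realistic small-model scale, not performance on
repository-scale outliers.

A model enters the SBO-mode corpus only when *every* species and reaction
node of its networks carries a term.  Annotation "validity" admits weaker
readings (e.g. any annotated node); the strictest reading is the default
because partially annotated networks would mix refined and bare labels
within one graph, and it is configurable (`require_sbo = FALSE`).

## Numerical and degenerate-input choices

* Node identifiers are opaque strings; mined patterns rename them
  `Node_0..Node_k` in DFS discovery order.
* Empty inputs flow through: an empty tuple set gives an empty graph, an
  empty graph an empty network set, an empty corpus an empty pattern list.
* A single-node pattern's canonical form is its label; its DFS code has no
  edge tuples.
* Ties in pattern file naming (`<frequency>_<index>.dot`) are broken by
  file order, and pattern ids are assigned the same way.
* `min_support` must be at least 1; 0 is a configuration error, not "match
  everything".

## Problem sizes used for validation

The shipped checks run at desk scale, chosen so that exhaustive
enumeration remains feasible as an independent oracle: oracle-equivalence
mining on 20 random networks of at most 10 nodes (size cap 5 edges),
invariant suites over 200 random corpora, embedding-count cross-checks on
hosts of at most 8 nodes, planted-cycle recovery in 12 of 20 models, and a
30-model corpus at the generator's default sizes mined at minimum support
20.  Repository-scale corpora (hundreds of models, mined on large-memory
hardware) are outside what the package's validation claims cover, though
the implementation imposes no such limit beyond time and memory.

## Known limitations

* Only SBML reaction networks are ingested; CellML and rule-induced
  dependency structures are not.
* The emitted Cypher is query *text*; no live graph database connection is
  made.  Cypher's per-match relationship-uniqueness semantics coincide with
  plain injective-node semantics for these patterns once all node
  inequalities are stated, which is why raw assignment counting is the
  default.
* The styled DOT is SBGN-*style*, not a validated SBGN-ML export, and no
  layout optimisation is attempted.
* Mining cost grows quickly as `min_support` drops; the capacity guard
  fails fast rather than degrading gracefully.
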