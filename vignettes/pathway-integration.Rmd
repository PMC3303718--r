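---
title: "Integrating pathway models without merging them: species alignment, duplicate reactions and the building-block dictionary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating pathway models without merging them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathblocks)
```

## The problem and the model

A repository of computational pathway models is a set of independently
curated SBML files. Each file is internally consistent, but the
collection as a whole is redundant: the same molecular species appears
under different local ids, and the same biochemical step is modeled
repeatedly. Merging files into one monolith resolves the redundancy at
the cost of destroying the per-model curation trail. `pathblocks`
takes the opposite route: every file is abstracted into a minimal
quantitative meta-format — pathway, species, kinetic reaction,
parameter, annotation — and all cross-model reasoning happens on top of
that aggregate while each element keeps its `pathway` link. Dropping
the alignment results and recomputing them from the aggregate is
lossless: alignment is a pure function of the aggregate, which is what
makes the abstraction level tunable and every conflict traceable to its
source file.

The scientific core is a chain of three constructions:

1. **Species equivalence classes.** Let each species carry a set of
   normalized annotation resources (database cross-references such as
   `uniprot:P00533`). Two species are equivalent iff they are connected
   by the transitive closure of "shares at least one admissible
   resource". This is a union-find over species, with resources as the
   connecting elements. Species without admissible resources stay
   singletons — the package never falls back to name matching, because
   lexical similarity across independently written models is not
   evidence of identity.
2. **Species-sets and duplicate reactions.** Each reaction side maps to
   the *set* of classes of its species (stoichiometry and multiplicity
   deliberately ignored; a species-set is a set). Reactions sharing the
   ordered pair (reactant-side set, product-side set) are first-order
   duplicates. Catalysts are excluded from vertex identity — they
   appear unchanged on both sides and would fragment the vertex space —
   but a catalyst mismatch inside a duplicate group, like a differing
   rate law, raises the group's conflict flag. The flag is a warning
   surface, not a merge decision: the user keeps editorial power.
3. **The species-set digraph and N-order reachability.** Vertices are
   species-sets, and each distinct (source, target) pair is one edge
   carrying all its supporting reactions, with the lexicographically
   smallest reaction key as representative — the graph is never a
   multigraph. Reachability within N steps is the boolean union of the
   first N boolean powers of the adjacency matrix. Two species-sets
   joined by two or more distinct simple paths form an *alternative
   composition* — the generalization of the duplicate-reaction idea
   from single edges to reaction chains.

The dictionary has three sections: all edges (building blocks), all
duplicate groups (equivalent reactions), and all composition entries.
It is exported, together with the full aggregate, as deterministic
OWL2 RDF/XML.

## Tunable parameters

* `policy` (qualifier admission, default `c("is", "unqualified")`).
  Identity-qualified resources are the intended evidence of sameness;
  unqualified ones are admitted because many older models carry bare
  resource lists. `isVersionOf`/`hasPart`-style qualifiers assert
  weaker relations and are excluded by default — admitting them trades
  recall for false merges, and false merges contaminate every
  downstream species-set. The policy is an argument everywhere it
  matters.
* `reversible_edges` (default `TRUE`). SBML reactions default to
  reversible, and reachability is directional, so a reversible
  reaction contributes both directed edges (and both duplicate keys).
  Setting it `FALSE` restricts the analysis to declared directionality.
* `max_len` (default 6) and `max_paths` (default 1000) bound the
  simple-path enumeration per vertex pair. Unbounded enumeration is
  exponential; explicit caps make outputs finite and reproducible, and
  hitting `max_paths` is always flagged on the entry, never silent.
  Six steps comfortably covers the direct-versus-multi-step overlaps
  the dictionary is meant to surface; raise it for deep chains.
* `base_iri` (default `http://pathblocks.local/ontology#`) namespaces
  the exported individuals.

## Numerical and representational choices

* **Kinetics comparison is string equality of canonical forms.** The
  MathML rate law is serialized to infix with single spaces, preserving
  source operand order — reordering commutative operands could claim
  equality between formulas the modelers wrote differently, and
  symbolic equivalence of rate laws is undecidable in general. Before
  comparison, local parameter names are substituted by their values, so
  `k1 * A` with `k1 = 2` and `kf * A` with `kf = 2` compare equal while
  equal-named constants with different values do not. The flag is
  therefore conservative: a `TRUE` conflict can still be a benign
  algebraic rewriting.
* **Initial values** take `initialConcentration` over `initialAmount`
  (concentrations are what mass-action kinetics consume); the
  meta-format has a single real-valued slot.
* **Element identity** is the pair (file basename, local id):
  BioModels-style files reuse ids like `re2` freely, so the pair — not
  the local id — names exported individuals
  (`BIOMOD0000000049.xml_re2`). Underscores in the file-name component
  are percent-encoded so the mapping stays injective even for file
  names containing `_`.
* **Degenerate inputs.** A reaction with an empty side (synthesis or
  degradation) maps to a reserved empty species-set vertex `{}`,
  keeping the graph total over all reactions. Self-loop edges are kept
  but excluded from composition entries by default (they conflate with
  catalytic no-ops). An aggregate with no models exports a schema-only
  ontology.
* **Determinism everywhere.** All orderings are radix-sorted
  (locale-independent); class ids derive from the smallest resource key
  of the class; duplicate-group representatives are the smallest
  reaction key; path enumeration is iterative-deepening DFS with
  sorted neighbors, so paths come out shortest-first then
  lexicographic. Dictionary files and the OWL export are byte-identical
  across runs, which the tests assert.
* **Reachability closure.** Off-diagonal reachability is complete at
  `N = |V| - 1` (a simple path never needs more steps), but the
  diagonal convention — `TRUE` only via a cycle — can require
  `N = |V|` for a Hamiltonian cycle. Tests compare against an
  independent Floyd–Warshall closure at `N = |V|`.

## What the synthetic fixtures emulate — and what they do not

The generators produce small SBML Level 2 collections with the three
structures the pipeline must recover: cross-model annotation sharing
(`generate_models`, sharing probability per species, mixed URI
syntaxes so normalization is exercised), a single planted duplicate
pair with optionally conflicting kinetics
(`generate_duplicate_pair`), and the direct-versus-indirect overlap
motif (`generate_alternative_path_motif`; with two intermediates it
reproduces the shape of the well-known EGFR example where a
receptor-complex species-set reaches its phosphorylated form either
directly or through internalized intermediates). Every generator
writes a manifest that is computed from generation bookkeeping — not
by the pipeline — so tests compare against an independent answer key,
and the same seed regenerates byte-identical files. Kinetics are mass
action with rate constants drawn log-uniform in `[1e-3, 1e3]`:
plausible magnitudes for a mixture of binding and catalytic steps,
though the values are only stored and compared, never simulated.

What the fixtures do **not** emulate: realistic network topology
(real collections have hubs and heavy-tailed degree distributions),
curation metadata and SBO terms, annotation errors (wrong or stale
cross-references), partially annotated species mixed with rich ones,
and compartmentalization. Passing tests therefore demonstrate
correctness of the algorithms on controlled structure, not robustness
to the annotation noise of a real repository — on real data the
alignment is exactly as good as the annotations are.

Problem sizes used by the test suite and the acceptance script —
dozens of models of a handful of species each, digraph oracles up to
eight vertices with exhaustive enumeration, fifty seeded
duplicate-pair runs, twenty export round-trips — were chosen so each
check has an exact, independently computable expectation
(brute-force path enumeration and Floyd–Warshall closure are only
feasible oracles at that scale). The algorithms themselves are not
size-limited: the whole-collection test in `test-acceptance.R` runs
the identical pipeline over an archived 326-model repository release
when a local copy is present.

## Design decisions that were genuinely open

* **Per-side vertices.** Reactant-side and product-side sets are
  separate vertices; pooling both sides into one vertex would destroy
  direction and collapse the duplicate criterion.
* **Compartments are ignored** when annotations match: two models of
  the same species in different compartment naming schemes should
  align. The conservative alternative (require compartment identity)
  can be emulated by annotating per compartment.
* **Reversible duplicates are reported per direction** (an A⇌B pair in
  two models yields a forward and a reverse group). This is redundant
  but keeps every group's key a directed edge, matching the graph.
* **No `owl:sameAs` between aligned species.** Equivalence is
  expressed through shared `memberOfSet` links to species-set
  individuals; `owl:sameAs` would let a reasoner fuse individuals and
  erase model identity, which the whole design exists to preserve.
* **Global SBML parameters** are kept on the pathway record; local
  kinetic-law parameters live on the reaction and participate in
  kinetics comparison. Only local parameters are substituted — a
  global parameter shared by two models is a shared symbol, not a
  conflict.

## Known limitations

* Only SBML Level 2 is parsed (Levels 1 and 3 are reported as
  unsupported rather than half-read); rules, events, units and
  function definitions are not interpreted beyond storing the kinetics
  text. CellML/BioPAX would attach through the parser registry.
* Kinetics-conflict detection is syntactic (see above).
* Unannotated species never align, by design; collections with sparse
  annotation will fragment into singletons and under-report overlap.
* Path enumeration is exact but bounded; a truncated entry means "at
  least this many alternatives", and deeply connected vertex pairs can
  exceed any practical cap.
* The OWL reader understands the exporter's RDF/XML subset; it is a
  round-trip and verification tool, not a general RDF parser.
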