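---
title: "omicstore: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{omicstore: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the design of the package: the object model and its
validation rules, the transactional store, the population rules, the two
network queries, the synthetic-data generator that stands in for downloaded
repositories, and the places where the design was genuinely open and a
choice had to be made.

## The object model

Biological content is represented as typed records in a BioPAX-derived
class tree. The root `BioObject` contributes the attributes shared by
everything — id, names (first is primary), free-text function,
cross-references, primary source — and splits into exactly two branches:
`PhysicalEntity` for tangible molecules and `Interaction` for relationships
among them. Ten concrete classes are storable; the three ancestors are
query-only, so a search for `PhysicalEntity` matches proteins, genes, RNAs
and so on, but no stored record may carry an abstract tag.

Per-class attribute schemas are deliberately minimal — the smallest set
sufficient to encode a multi-level yeast repository (chromosome sequence
and length; gene coordinates; transcript/protein linkage; reaction
substrates and products; interaction participants; a control type). The
full table is available at runtime via `class_schema()`. Conventions worth
stating explicitly:

* Gene (`DNARegion`) coordinates are **1-based, inclusive**, GFF3
  convention, with strand `+`/`-`. `start <= end` always; the strand does
  not flip the coordinate order.
* `Control` records carry one of four control types: transcription
  regulation, phosphorylation, dephosphorylation, catalysis.
* Biochemical reactions use the `Conversion` class directly; no separate
  reaction subclass is introduced, because nothing in the data model needs
  one at this granularity.
* Names are case-sensitive (gene symbols are case-meaningful in yeast);
  queries take an explicit `case_insensitive` flag instead of silently
  folding case.

`validate()` is total and pure: it reports every violation of the schema
(missing required keys, type errors, coordinate order) without raising or
mutating, so it can be applied to anything, including deliberately
corrupted records in tests. Serialization stores the class tag under the
document property `"type"`; `from_document(to_document(r))` is the identity
on every valid record, which is what makes byte-level store comparison a
meaningful audit tool (below).

## The store

The store keeps two disjoint collections — object documents and relation
documents — plus indexes over id, name, cross-reference and class tag, and
over relation endpoints and types. Relations are typed edges with an
endpoint-tag compatibility table (`relation_compatibility()`):
`TRANSLATED_TO` is only legal from RNA to protein, `HAS_PARTICIPANT` only
from a conversion to a physical entity, and so on. The seven-type
vocabulary was chosen as the smallest set that covers chromosome placement,
the central dogma chain, physical interaction, regulation/catalysis,
reaction participation and complex membership.

Guarantees, and how each is implemented:

* **Atomicity.** `insert_atomic()` validates every object and checks every
  relation (endpoints resolved against pre-existing *plus staged* objects)
  before any mutation; the first violation aborts with the store untouched.
  The test suite asserts this by byte-comparing `store_serialize()` output
  before and after deliberately corrupted bundles — serialization is
  canonical (records sorted by id, fixed key order), so byte equality is
  content equality.
* **Referential integrity.** Relations can only be created against
  existing endpoints, and deletion either refuses (reporting the number of
  blocking relations) or cascades. A property test fuzzes 1,000 random
  CRUD operations and then scans the relation collection for danglers.
* **Isolation.** Writes are serialized at operation granularity
  (single-writer contract): an update replaces a whole validated record or
  nothing, so the store always reflects a sequence of complete updates and
  the later of two conflicting updates wins. Multi-statement concurrent
  transactions are out of scope.
* **Durability.** The on-disk format is a directory with a manifest header
  and two JSON-lines collections (`objects.jsonl`, `relations.jsonl`).
  `store_open(store_save(s))` answers every query identically to `s`.
* **Index invariance.** Every query path has an index route and an
  exhaustive-scan route (`use_index = FALSE`), and tests require the two to
  agree on randomized queries — the indexes can never change an answer,
  only its cost.

Undirected `INTERACTS_WITH` edges are canonicalized with endpoints in
lexicographic order and stored once; duplicate relations (same type,
canonical endpoints and qualifiers) are rejected rather than silently
merged, which keeps counts meaningful. All result lists are sorted by id so
repeated runs are byte-identical.

## Population rules

Parsers read the field's flat formats — FASTA (via Biostrings), a
GFF3-style gene table (via rtracklayer), GAF 2.x, a minimal OBO term graph,
and documented TSVs for proteins, interactions, controls and reactions —
and emit bundles consumed by `insert_atomic()`, one transaction per file,
in dependency order (genome → genes → proteins → compounds/reactions →
PPIs → controls). One transcript is created per gene, with a fixed id rule
(`G:X` → `R:X`) that later files use to resolve the gene → transcript →
protein chain.

The load-bearing rule is ambiguity exclusion: PPI (and gene-identified
regulator) rows name genes, and a gene mapping to anything other than
exactly one protein is incompatible with a binary edge, so **every** row
naming that gene is dropped and logged — one log entry per ambiguous
participant with its dropped-row count, and a row naming two ambiguous
participants charged to the first so each row is accounted exactly once.
Every parser satisfies the conservation identity
`rows_in == rows_emitted + rows_excluded + rows_errored`, asserted in
tests. Unknown participants in control tables are collected into a per-row
error report rather than aborting the file, because a single bad row in a
regulation table should not block an otherwise consistent load; structural
problems (bad strand, inverted coordinates, malformed equations or GO ids)
are hard parse errors.

GO annotations deliberately live *outside* the object store, as a
query-time map from protein id to term set. They are filter inputs, not
biological entities with relations, and keeping them out of the collections
keeps the count invariants clean.

## The two queries

**Signaling-path detection.** `find_signaling_paths()` enumerates simple
paths over undirected PPI edges from any source to the target with at most
`max_edges` edges (default 3 — "path length" counts edges), requiring every
*intermediate* node to pass the GO filter. Three open choices, and the
defaults taken:

* *Recursive GO constraint* is read as: expand the seed terms to all their
  descendants in the DAG (`is_a` and `part_of` collapsed), then keep
  proteins annotated with any expanded term — the standard true-path
  interpretation. Unannotated proteins fail the filter.
* *Filter scope*: the fixed source and target proteins are exempt; a
  receptor or TF should not need to carry the pathway's annotations to
  anchor the search. The filter constrains what the path may pass
  *through*.
* Sources absent from the PPI graph (for instance, excluded at population
  time by the ambiguity rule) contribute zero paths without raising — that
  silence is exactly the behavior the exclusion rule is meant to produce,
  and an end-to-end test asserts excluded participants never appear in any
  returned path.

Paths are simple (no repeated node), deduplicated, and sorted by length
then lexicographically. Correctness is established against an independent
oracle: igraph's exhaustive simple-path enumeration with post-hoc
filtering, over hundreds of random seeded graphs at `max_edges` 1–4, with
exact set equality required. Monotonicity properties (more filter terms or
more edges never remove a result) are asserted separately.

**Kinase regulon.** `kinase_regulon()` composes directed `CONTROLS` edges:
phosphorylation out-edges give the substrates; substrates with at least one
transcription-regulation out-edge are the TFs; those edges' gene endpoints
are the targets; and each target gene's reactions are reached through
transcript and protein to the conversions the protein catalyzes. Regulation
targets are stored against the *gene*, not its protein, precisely so this
step is a direct edge query. The generic `follow()` primitive expresses the
same traversal as a step program, and tests require the two routes to agree
— an internal consistency oracle.

## The synthetic fixture

`generate_fixture()` emits every input file at toy scale with a
ground-truth manifest. Default scale: 3 chromosomes, 60 genes (one
transcript each), 61 proteins, 30 compounds, 20 reactions, ~195 PPI rows,
~49 regulation rows, 10 kinase and 5 phosphatase rows — seconds to generate
and query, which is what keeps the full property suite affordable. Three
motifs are planted independently of the seed:

* a receptor→TF path `Ste3 – Ste4 – Fus3 – Ste12` whose intermediates carry
  filter GO terms (one only via a *descendant* of a seed term, so the test
  exercises DAG expansion), alongside decoy routes whose intermediates are
  unannotated or carry unrelated terms;
* a kinase cascade `Snf1 → {Cdc14, Gal83}` where only Cdc14 acts as a TF,
  regulating five metabolic genes tied to six reactions;
* the gene `STE2` mapped to two proteins, so the ambiguity rule must drop
  all of its interaction rows.

All randomized decoy wiring is confined to filler genes that are disjoint
from the planted cast, so no seed can accidentally create an additional
qualifying source→target path; different seeds rewire decoys while the
planted truth is invariant, and the same seed reproduces byte-identical
files. The manifest's counts are computed while writing the files, by the
same dedup rules the parsers document — so manifest-vs-store equality is a
genuine end-to-end check of the parsing and population code, not of the
generator against itself. A negative-control test confirms a tampered
manifest count is detected.

What the fixture does **not** emulate: realistic sequence composition,
realistic PPI degree distributions (decoy edges are uniform), expression
data, and real database identifier schemes. Passing tests therefore
demonstrate correctness of the machinery — parsing, integrity, traversal,
filtering — on data with the right *shape*, not robustness to the noise
and inconsistency of live repository snapshots.

## Numerical and degenerate-input choices

* Whole-number attribute values are normalized to integers at the setter,
  so document round trips are exact and serialized stores byte-compare.
* Self-interactions are legal and stored once; a self-edge's neighbor is
  the node itself.
* Empty inputs are answered, not raised: an empty interaction file yields
  an empty bundle; a kinase without substrates yields an empty regulon; a
  source equal to the target yields no paths.
* Relation ids are assigned from a monotone counter at commit time, in
  bundle order, so identical operation sequences produce identical stores.
* The GO DAG loader rejects cycles (by leaf-stripping) and unknown parents
  at construction, so traversal code can assume a well-formed DAG.

## Limitations

The store is single-process and in-memory with whole-store persistence —
appropriate for desk-scale integrated datasets, not for server workloads;
there is no sharding, no blob storage for expression matrices or reads, and
no multi-statement transaction protocol. The object model is a pragmatic
subset of BioPAX, not a faithful Level-3 implementation (no cellular
locations, stoichiometry objects or evidence codes), and native XML/SBML
inputs are out of scope in favor of the documented flat formats.
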