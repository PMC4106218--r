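# omicstore

An embedded, transactional document store for multi-level systems-biology
data, with parsers for standard flat formats and two network queries built
on top: GO-constrained signaling-path detection in protein–protein
interaction (PPI) networks, and kinase → transcription factor → gene →
reaction regulon traversal.

## Who this is for

Systems-biology groups that integrate heterogeneous data — genome sequence,
gene annotation, proteins, metabolic reactions, PPIs, transcriptional and
phosphorylation interactions, GO annotations — and want one consistent,
queryable store with hard integrity guarantees, without running a database
server. Everything lives in R; the store persists to a plain JSON-lines
directory.

## The model

Entities and interactions follow a BioPAX-derived class hierarchy: the root
`BioObject` splits into `PhysicalEntity` (SmallMolecule, DNA, DNARegion
(genes), RNA, Protein, Complex) and `Interaction` (Conversion
(biochemical reactions), MolecularInteraction, GeneticInteraction,
Control). Every record carries an id, names, optional function text,
cross-references and class-specific attributes validated against an
explicit schema (`class_schema()`).

Records are stored as documents in one collection; typed relations
(`LOCATED_ON`, `TRANSCRIBED_TO`, `TRANSLATED_TO`, `INTERACTS_WITH`,
`CONTROLS`, `HAS_PARTICIPANT`, `COMPONENT_OF`) live in a second, disjoint
collection, with an endpoint-tag compatibility table
(`relation_compatibility()`). The store provides ACID-style guarantees at
desk scale:

- **Atomicity** — `insert_atomic()` commits a whole bundle of objects and
  relations or nothing at all.
- **Consistency** — every object is schema-validated and every relation
  endpoint-checked before commit; no relation can ever reference a missing
  object, and `delete_object()` either refuses or cascades.
- **Isolation** — writes are serialized at operation granularity; the store
  always reflects a sequence of whole updates.
- **Durability** — `store_save()` / `store_open()` round-trip the store
  through a stable on-disk format; reopened stores answer every query
  identically.

Two application queries mirror classic yeast analyses:

1. `find_signaling_paths()` enumerates simple PPI paths (≤ *k* edges,
   default 3) from receptor proteins to a transcription factor, keeping
   only paths whose intermediate proteins are annotated with a filter GO
   term or any of its descendants (`expand_go_terms()` on a GO DAG).
2. `kinase_regulon()` walks kinase → phosphorylation substrates → those
   acting as TFs → their target genes → the biochemical reactions those
   genes' proteins catalyze.

A notable population rule: interaction files identify participants by gene;
a gene mapping to anything other than exactly one protein conflicts with
the binary representation of PPIs, so **all** of its rows are excluded and
logged (in yeast data this famously removes every Ste2 interaction). The
exclusion log makes this auditable.

## Worked example

The package ships a deterministic synthetic fixture generator that emulates
a yeast-like data repository with planted ground truth — a
pheromone-style signaling path, an Snf1-style kinase cascade, and one
deliberately ambiguous gene:

```r
library(omicstore)

dir <- tempfile()
man <- generate_fixture(dir, seed = 1)   # writes FASTA/GFF3/TSV/GAF/OBO files
res <- populate_store(dir)               # parses + inserts, transactionally
res$store
#> <bio_store> 512 objects, 519 relations

res$exclusions[, c("entity_id", "rule", "n_records_dropped")]
#> # A tibble: 2 × 3
#>   entity_id rule              n_records_dropped
#> 1 G:STE2    ambiguous_mapping                 3
#> 2 G:STE2    ambiguous_mapping                 1
```

`G:STE2` was planted to map to two proteins, so its 3 PPI rows and 1
regulation row were dropped wholesale. Now the two queries:

```r
p <- find_signaling_paths(res$store, c("P:STE2", "P:STE3"), "P:STE12",
                          max_edges = 3, filter_terms = man$go_filter_seeds,
                          dag = res$dag, annotations = res$annotations)
p
#> <signaling_paths> 1 path(s) to P:STE12 (max 3 edges, 4 filter terms)
#>    P:STE3 -- P:STE4 -- P:FUS3 -- P:STE12
```

Exactly the planted path is found: the decoy routes are filtered out
because their intermediates lack pheromone-response GO annotations, and
P:STE2 contributes nothing because its interactions never entered the
store. The regulon query, with a broom-style tidier:

```r
r <- kinase_regulon(res$store, "P:SNF1")
glance(r)
#> # A tibble: 1 × 5
#>   kinase n_substrates n_tfs n_target_genes n_reactions
#> 1 P:SNF1            2     1              5           6
tidy(r)
#> # A tibble: 7 × 5
#>   kinase substrate tf      gene   reaction
#> 1 P:SNF1 P:CDC14   P:CDC14 G:ACS1 RXN:ACS1A
#> ...
```

Snf1 phosphorylates two substrates; only Cdc14 acts as a TF, regulating
five metabolic genes whose proteins catalyze six reactions — the planted
cascade, recovered from the store alone.

The same pipeline is scriptable from a shell via the launcher in
`inst/cli/omicstore` (`generate-fixture`, `populate`, `stats`, `query`,
`path-search`, `regulon`).

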