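# End-to-end population: parse every source file of a fixture-layout
# directory in the documented order (genome -> genes -> proteins ->
# compounds/reactions -> interactions -> controls), each file inside one
# atomic transaction.

fixture_files <- function(dir) {
  list(genome = file.path(dir, "genome.fasta"),
       genes = file.path(dir, "genes.gff3"),
       proteins = file.path(dir, "proteins.tsv"),
       compounds = file.path(dir, "compounds.tsv"),
       reactions = file.path(dir, "reactions.tsv"),
       ppi = file.path(dir, "ppi.tsv"),
       tri = file.path(dir, "tri.tsv"),
       ki = file.path(dir, "ki.tsv"),
       phosphatase = file.path(dir, "phosphatase.tsv"),
       gaf = file.path(dir, "annotations.gaf"),
       dag = file.path(dir, "go.obo"))
}

#' Populate a store from a directory of source files
#'
#' Expects the fixture layout (see [generate_fixture()]): `genome.fasta`,
#' `genes.gff3`, `proteins.tsv`, `compounds.tsv`, `reactions.tsv`,
#' `ppi.tsv`, `tri.tsv`, `ki.tsv`, `phosphatase.tsv`, `annotations.gaf` and
#' `go.obo`. Files are parsed in dependency order and each parser's bundle
#' is committed in one atomic transaction; identifier-ambiguity exclusions
#' are collected into one auditable log.
#'
#' @param dir Input directory.
#' @param store Target `bio_store` (a fresh one by default).
#' @return List with `store`, `exclusions` (tibble), `summaries` (per-file
#'   row accounting), `errors` (tibble of per-row control-table errors),
#'   `idmap`, `annotations` and `dag`.
#' @export
populate_store <- function(dir, store = bio_store()) {
  f <- fixture_files(dir)
  commit <- function(b) insert_atomic(store, b$objects, b$relations)

  genome <- parse_fasta(f$genome);                commit(genome)
  genes <- parse_gene_table(f$genes);             commit(genes)
  prots <- parse_protein_table(f$proteins, genes$gene_ids); commit(prots)
  idmap <- prots$idmap
  rxns <- parse_reactions(f$compounds, f$reactions, idmap); commit(rxns)
  ppi <- parse_ppi_tab(f$ppi, idmap);             commit(ppi)
  protein_ids <- vapply(prots$objects, function(o) o$id, character(1))
  tri <- parse_control_tab(f$tri, "TRI", idmap,
                           known_genes = genes$gene_ids,
                           known_proteins = protein_ids); commit(tri)
  ki <- parse_control_tab(f$ki, "KI", idmap,
                          known_genes = genes$gene_ids,
                          known_proteins = protein_ids);  commit(ki)
  phos <- parse_control_tab(f$phosphatase, "PHOSPHATASE", idmap,
                            known_genes = genes$gene_ids,
                            known_proteins = protein_ids); commit(phos)

  bundles <- list(genome = genome, genes = genes, proteins = prots,
                  reactions = rxns, ppi = ppi, tri = tri, ki = ki,
                  phosphatase = phos)
  exclusions <- do.call(rbind, c(list(empty_exclusion_log()),
                                 lapply(bundles, `[[`, "exclusions")))
  errors <- do.call(rbind, c(list(empty_error_report()),
                             lapply(bundles, `[[`, "errors")))
  list(store = store,
       exclusions = exclusions,
       errors = errors,
       summaries = lapply(bundles, `[[`, "summary"),
       idmap = idmap,
       annotations = parse_gaf(f$gaf),
       dag = read_go_dag(f$dag))
}
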