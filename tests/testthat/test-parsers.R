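write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("FASTA chromosomes parse with ids, lengths and error cases", {
  fa <- write_lines_tmp(c(">C:I chromosome one", "ACGTACGTAC", "GGCC",
                          ">C:II", "TTTT"), ".fasta")
  b <- parse_fasta(fa)
  expect_length(b$objects, 2L)
  expect_identical(b$objects[[1]]$id, "C:I")
  expect_identical(b$objects[[1]]$attributes$length, 14L)
  expect_identical(b$objects[[2]]$attributes$length, 4L)
  expect_identical(b$summary$rows_in, 2L)

  empty_seq <- write_lines_tmp(c(">C:I", "ACGT", ">C:II"), ".fasta")
  expect_error(parse_fasta(empty_seq), class = "omics_parse_error")
  dup <- write_lines_tmp(c(">C:I x", "ACGT", ">C:I y", "GGGG"), ".fasta")
  expect_error(parse_fasta(dup), class = "omics_parse_error")
})

test_that("each gene row yields a gene, a transcript and two relations", {
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "C:I\tsrc\tgene\t100\t400\t.\t+\t.\tID=G:AAA;Name=AAA"), ".gff3")
  b <- parse_gene_table(gff)
  expect_length(b$objects, 2L)
  expect_length(b$relations, 2L)
  tags <- vapply(b$objects, `[[`, character(1), "tag")
  expect_setequal(tags, c("DNARegion", "RNA"))
  expect_identical(b$objects[[1]]$attributes$start, 100L)
  expect_identical(b$gene_ids, "G:AAA")
  rtypes <- vapply(b$relations, `[[`, character(1), "rtype")
  expect_setequal(rtypes, c("LOCATED_ON", "TRANSCRIBED_TO"))
})

test_that("gene-table dialect violations are parse errors", {
  bad_strand <- write_lines_tmp(c(
    "##gff-version 3",
    "C:I\tsrc\tgene\t100\t400\t.\t?\t.\tID=G:AAA"), ".gff3")
  expect_error(parse_gene_table(bad_strand), class = "omics_parse_error")
  coords <- write_lines_tmp(c(
    "##gff-version 3",
    "C:I\tsrc\tgene\t500\t400\t.\t+\t.\tID=G:AAA"), ".gff3")
  expect_error(parse_gene_table(coords), class = "omics_parse_error")
  no_id <- write_lines_tmp(c(
    "##gff-version 3",
    "C:I\tsrc\tgene\t100\t400\t.\t+\t.\tName=AAA"), ".gff3")
  expect_error(parse_gene_table(no_id), class = "omics_parse_error")
})

test_that("protein rows resolve through transcript ids; unknown genes fail loudly", {
  tsv <- write_lines_tmp(c("protein_id\tgene_id\tname\tsequence",
                           "P:AAA\tG:AAA\tAaa\t"))
  b <- parse_protein_table(tsv, gene_ids = "G:AAA")
  expect_length(b$objects, 1L)
  expect_identical(b$relations[[1]],
                   rel_spec("TRANSLATED_TO", "R:AAA", "P:AAA"))
  expect_identical(b$idmap$gene_to_protein[["G:AAA"]], "P:AAA")
  expect_identical(b$idmap$protein_to_gene[["P:AAA"]], "G:AAA")

  bad <- write_lines_tmp(c("protein_id\tgene_id\tname\tsequence",
                           "P:ZZZ\tG:NOPE\tZzz\t"))
  expect_error(parse_protein_table(bad, gene_ids = "G:AAA"),
               regexp = "G:NOPE", class = "omics_parse_error")
})

test_that("the ambiguity rule excludes every row of a multi-mapped participant", {
  idmap <- build_id_map(c("G:A", "G:A", "G:B", "G:C"),
                        c("P:A1", "P:A2", "P:B", "P:C"))
  ppi <- write_lines_tmp(c("gene_a\tgene_b", "G:A\tG:B", "G:B\tG:C", "G:A\tG:C"))
  b <- parse_ppi_tab(ppi, idmap)
  expect_length(b$objects, 1L)
  expect_identical(b$objects[[1]]$attributes$participants, c("P:B", "P:C"))
  expect_identical(nrow(b$exclusions), 1L)
  expect_identical(b$exclusions$entity_id, "G:A")
  expect_identical(b$exclusions$n_records_dropped, 2L)
  expect_identical(b$summary$rows_in,
                   b$summary$rows_emitted + b$summary$rows_excluded +
                     b$summary$rows_errored)
  # no surviving interaction touches an ambiguous participant's proteins
  parts <- unlist(lapply(b$objects, function(o) o$attributes$participants))
  expect_false(any(c("P:A1", "P:A2") %in% parts))
})

test_that("PPI parsing keeps self-interactions, collapses duplicates, handles empty files", {
  idmap <- build_id_map(c("G:A", "G:B"), c("P:A", "P:B"))
  ppi <- write_lines_tmp(c("gene_a\tgene_b", "G:A\tG:B", "G:B\tG:A",
                           "G:A\tG:A"))
  b <- parse_ppi_tab(ppi, idmap)
  expect_length(b$objects, 2L)  # A--B once, A--A once
  expect_identical(b$summary$rows_emitted, 3L)
  empty <- write_lines_tmp("gene_a\tgene_b")
  b0 <- parse_ppi_tab(empty, idmap)
  expect_length(b0$objects, 0L)
  expect_identical(nrow(b0$exclusions), 0L)
})

test_that("control rows produce typed Control objects and CONTROLS edges", {
  idmap <- build_id_map(c("G:SNF1", "G:CDC14", "G:X"),
                        c("P:SNF1", "P:CDC14", "P:X"))
  ki <- write_lines_tmp(c("controller\ttarget", "P:SNF1\tP:CDC14"))
  b <- parse_control_tab(ki, "KI", idmap, known_genes = c("G:SNF1", "G:CDC14", "G:X"),
                         known_proteins = c("P:SNF1", "P:CDC14", "P:X"))
  expect_identical(b$objects[[1]]$attributes$control_type, "PHOSPHORYLATION")
  expect_identical(b$relations[[1]]$source_id, "P:SNF1")
  expect_identical(b$relations[[1]]$target_id, "P:CDC14")

  tri <- write_lines_tmp(c("controller\ttarget", "G:CDC14\tG:X", "P:CDC14\tG:NOPE"))
  bt <- parse_control_tab(tri, "TRI", idmap, known_genes = c("G:SNF1", "G:CDC14", "G:X"),
                          known_proteins = c("P:SNF1", "P:CDC14", "P:X"))
  expect_identical(bt$relations[[1]],
                   rel_spec("CONTROLS", "P:CDC14", "G:X",
                            list(control_type = "TRANSCRIPTION_REGULATION")))
  expect_identical(nrow(bt$errors), 1L)  # unknown target collected, not raised
  expect_match(bt$errors$message, "G:NOPE")
  expect_identical(bt$summary$rows_in,
                   bt$summary$rows_emitted + bt$summary$rows_excluded +
                     bt$summary$rows_errored)

  none <- write_lines_tmp("controller\ttarget")
  expect_length(parse_control_tab(none, "PHOSPHATASE", idmap,
                                  known_genes = character(0),
                                  known_proteins = character(0))$objects, 0L)
})

test_that("reactions produce conversions, participant roles and catalysis links", {
  idmap <- build_id_map("G:1", "P:1")
  cmp <- write_lines_tmp(c("compound_id\tname\tformula",
                           "a\tcompound a\t", "b\tcompound b\t", "c\tcompound c\t"))
  rxn <- write_lines_tmp(c("reaction_id\tequation\tgenes",
                           "r1\ta + b => c\tG:1"))
  b <- parse_reactions(cmp, rxn, idmap)
  tags <- vapply(b$objects, `[[`, character(1), "tag")
  expect_identical(sum(tags == "Conversion"), 1L)
  expect_identical(sum(tags == "SmallMolecule"), 3L)
  expect_identical(sum(tags == "Control"), 1L)
  rtypes <- vapply(b$relations, `[[`, character(1), "rtype")
  expect_identical(sum(rtypes == "HAS_PARTICIPANT"), 3L)
  expect_identical(sum(rtypes == "CONTROLS"), 1L)
  roles <- vapply(b$relations[rtypes == "HAS_PARTICIPANT"],
                  function(r) r$qualifiers$role, character(1))
  expect_identical(sort(roles), c("PRODUCT", "SUBSTRATE", "SUBSTRATE"))

  bad_eq <- write_lines_tmp(c("reaction_id\tequation\tgenes", "r1\ta b c\t"))
  expect_error(parse_reactions(cmp, bad_eq, idmap), class = "omics_parse_error")
  undeclared <- write_lines_tmp(c("reaction_id\tequation\tgenes",
                                  "r1\ta + zz => c\t"))
  expect_error(parse_reactions(cmp, undeclared, idmap), class = "omics_parse_error")
})

test_that("GAF rows aggregate per protein with duplicates collapsed", {
  gaf_row <- function(pid, go)
    paste(c("OS", pid, sub("P:", "", pid), "", go, "REF", "IDA", "", "P",
            "x", "", "protein", "taxon:1", "20140101", "db"), collapse = "\t")
  gaf <- write_lines_tmp(c("!gaf-version: 2.2",
                           gaf_row("P:STE4", "GO:0019236"),
                           gaf_row("P:STE4", "GO:0019236"),
                           gaf_row("P:STE4", "GO:0000750")))
  ann <- parse_gaf(gaf)
  expect_identical(ann, list("P:STE4" = c("GO:0000750", "GO:0019236")))

  bad_id <- write_lines_tmp(c("!c", gaf_row("P:STE4", "0019236")))
  expect_error(parse_gaf(bad_id), class = "omics_parse_error")
  short <- write_lines_tmp("P:STE4\tGO:0019236")
  expect_error(parse_gaf(short), class = "omics_parse_error")
})

test_that("parser outputs populate a store in order without integrity errors", {
  fx <- shared_fixture()
  # populate_store() ran insert_atomic for every bundle; verify referential
  # integrity end to end by scanning the relation collection
  st <- fx$store
  for (rid in ls(st$relations)) {
    rel <- st$relations[[rid]]
    expect_false(is.null(get_by_id(st, rel$source_id)), info = rid)
    expect_false(is.null(get_by_id(st, rel$target_id)), info = rid)
  }
  # conservation for every parser
  for (nm in names(fx$summaries)) {
    s <- fx$summaries[[nm]]
    expect_identical(s$rows_in, s$rows_emitted + s$rows_excluded + s$rows_errored,
                     info = nm)
  }
})
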