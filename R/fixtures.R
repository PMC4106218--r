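# Deterministic synthetic-data generator. Emits every input file the
# population pipeline consumes — genome FASTA, gene GFF3, protein TSV,
# compound/reaction TSVs, PPI/TRI/KI/phosphatase TSVs, GAF annotations and a
# minimal OBO term graph — together with a ground-truth manifest of exact
# expected counts, the planted signaling path, the planted kinase regulon
# and the planted ambiguous participant.
#
# The planted motifs reuse the classic yeast pheromone/Snf1 cast so tests
# read like the biology they emulate; all sequences and coordinates are
# synthetic. Planted wiring is seed-independent; only decoy wiring varies
# with the seed.

# The fixed cast. Filler genes (YSNxxx) carry all randomized decoy wiring so
# random edges can never create additional source->target paths.
.cast_genes <- c("STE2", "STE3", "STE4", "STE5", "FUS3", "STE12",
                 "DIM1", "DIM2", "DIM3",
                 "SNF1", "CDC14", "GAL83",
                 "ICL1", "MLS1", "CIT2", "ACS1", "ADY2")

.seed_go_terms <- c("GO:0019236", "GO:0000750", "GO:0000185", "GO:0071508")

#' Default fixture scale
#'
#' @return Named list of scale parameters: chromosome, gene, decoy-edge,
#'   compound and reaction counts.
#' @export
fixture_scale <- function() {
  list(n_chromosomes = 3L, n_genes = 60L, n_ppi_decoys = 180L,
       n_tri_decoys = 40L, n_ki_decoys = 8L, n_phos_decoys = 4L,
       n_compounds = 30L, n_reactions = 20L)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Generate the synthetic yeast-like fixture
#'
#' Writes all input files plus `manifest.json` into `dir`. Three motifs are
#' planted independently of the seed:
#' \itemize{
#'   \item a pheromone-style PPI path `P:STE3 -- P:STE4 -- P:FUS3 -- P:STE12`
#'     whose intermediates carry GO terms under the filter seeds, alongside
#'     decoy paths whose intermediates do not;
#'   \item a kinase cascade `Snf1 -> Cdc14 -> five metabolic genes -> their
#'     reactions` (plus the non-TF substrate Gal83);
#'   \item the gene `G:STE2` mapped to two proteins, so every interaction row
#'     naming it must be excluded at population time.
#' }
#' Regenerating with the same seed reproduces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @param scale Scale parameters; see [fixture_scale()].
#' @return The manifest (invisibly); also written to `dir/manifest.json`.
#' @export
generate_fixture <- function(dir, seed = 1L, scale = fixture_scale()) {
  sc <- utils::modifyList(fixture_scale(), scale)
  n_filler <- sc$n_genes - length(.cast_genes)
  if (n_filler < 14L)
    os_argument_error(sprintf(
      "scale too small to embed the planted motifs: n_genes must be >= %d",
      length(.cast_genes) + 14L))
  if (sc$n_ppi_decoys > choose(n_filler, 2))
    os_argument_error("n_ppi_decoys exceeds the number of available filler pairs")
  if (sc$n_tri_decoys > 5L * n_filler)
    os_argument_error("n_tri_decoys exceeds the number of available TF-target pairs")
  if (sc$n_chromosomes < 1L || sc$n_compounds < 6L || sc$n_reactions < 6L)
    os_argument_error("scale too small to embed the planted motifs")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")

  fillers <- sprintf("YSN%03d", seq_len(n_filler))
  symbols <- c(.cast_genes, fillers)
  gene_ids <- paste0("G:", symbols)

  ## genome -------------------------------------------------------------
  chrom_names <- paste0("C:", utils::as.roman(seq_len(sc$n_chromosomes)))
  gene_chrom <- chrom_names[((seq_along(symbols) - 1L) %% sc$n_chromosomes) + 1L]
  per_chrom <- table(factor(gene_chrom, levels = chrom_names))
  chrom_len <- as.integer(per_chrom) * 500L + 1000L
  seqs <- Biostrings::DNAStringSet(vapply(chrom_len, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1)))
  names(seqs) <- paste(chrom_names, "synthetic chromosome")
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fasta"), width = 70L)

  ## gene table ----------------------------------------------------------
  slot <- as.integer(stats::ave(seq_along(symbols), gene_chrom, FUN = seq_along))
  starts <- (slot - 1L) * 500L + 101L
  ends <- starts + 299L
  strands <- ifelse(seq_along(symbols) %% 2L == 0L, "-", "+")
  gff <- c("##gff-version 3",
           sprintf("%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   gene_chrom, starts, ends, strands, gene_ids, symbols))
  writeLines(gff, file.path(dir, "genes.gff3"))

  ## proteins (G:STE2 maps to two -> the ambiguity plant) ----------------
  prot_rows <- data.frame(
    protein_id = paste0("P:", symbols), gene_id = gene_ids,
    name = paste0(substr(symbols, 1, 1),
                  tolower(substring(symbols, 2)), "p"),
    sequence = "", stringsAsFactors = FALSE)
  ste2_extra <- data.frame(protein_id = c("P:STE2A", "P:STE2B"),
                           gene_id = "G:STE2",
                           name = c("Ste2p-a", "Ste2p-b"), sequence = "",
                           stringsAsFactors = FALSE)
  prot_rows <- rbind(prot_rows[prot_rows$gene_id != "G:STE2", ], ste2_extra)
  write_tsv(prot_rows, file.path(dir, "proteins.tsv"))
  n_proteins <- nrow(prot_rows)

  ## compounds and reactions ---------------------------------------------
  compounds <- sprintf("M:%03d", seq_len(sc$n_compounds))
  write_tsv(data.frame(compound_id = compounds,
                       name = paste0("compound-", seq_len(sc$n_compounds)),
                       formula = sprintf("C%dH%dO%d",
                                         sample(2:20, sc$n_compounds, TRUE),
                                         sample(4:30, sc$n_compounds, TRUE),
                                         sample(1:10, sc$n_compounds, TRUE)),
                       stringsAsFactors = FALSE),
            file.path(dir, "compounds.tsv"))

  metabolic <- c("ICL1", "MLS1", "CIT2", "ACS1", "ADY2")
  planted_rxn <- data.frame(
    reaction_id = c(paste0("RXN:", metabolic, "A"), "RXN:ICL1B"),
    gene = paste0("G:", c(metabolic, "ICL1")), stringsAsFactors = FALSE)
  n_random_rxn <- sc$n_reactions - nrow(planted_rxn)
  rxn_ids <- c(planted_rxn$reaction_id, sprintf("RXN:%03d", seq_len(n_random_rxn)))
  rxn_genes <- c(planted_rxn$gene, vapply(seq_len(n_random_rxn), function(i) {
    k <- sample(0:2, 1)
    if (k == 0L) "" else paste(paste0("G:", sample(fillers, k)), collapse = ",")
  }, character(1)))
  equations <- vapply(seq_along(rxn_ids), function(i) {
    parts <- sample(compounds, 3L)
    sprintf("%s + %s => %s", parts[1], parts[2], parts[3])
  }, character(1))
  write_tsv(data.frame(reaction_id = rxn_ids, equation = equations,
                       genes = rxn_genes, stringsAsFactors = FALSE),
            file.path(dir, "reactions.tsv"))

  ## PPIs ----------------------------------------------------------------
  planted_ppi <- rbind(
    c("G:STE3", "G:STE4"), c("G:STE4", "G:FUS3"), c("G:FUS3", "G:STE12"),
    c("G:STE4", "G:STE5"), c("G:STE5", "G:FUS3"),
    c("G:STE3", "G:DIM1"), c("G:DIM1", "G:STE12"),          # decoy: unannotated
    c("G:STE3", "G:DIM2"), c("G:DIM2", "G:DIM3"), c("G:DIM3", "G:STE12"),  # decoy: wrong GO
    c("G:STE2", "G:STE4"), c("G:STE2", "G:STE5"), c("G:STE2", "G:FUS3"),   # ambiguous
    c("G:STE3", "G:STE4"),                                   # duplicate row
    c(paste0("G:", fillers[1]), paste0("G:", fillers[1])))   # self-interaction
  pairs <- utils::combn(fillers, 2)
  pick <- sample(ncol(pairs), sc$n_ppi_decoys)
  decoy_ppi <- cbind(paste0("G:", pairs[1, pick]), paste0("G:", pairs[2, pick]))
  ppi <- rbind(planted_ppi, decoy_ppi)
  write_tsv(data.frame(gene_a = ppi[, 1], gene_b = ppi[, 2],
                       stringsAsFactors = FALSE),
            file.path(dir, "ppi.tsv"))
  ste2_ppi_rows <- sum(ppi[, 1] == "G:STE2" | ppi[, 2] == "G:STE2")
  surviving <- ppi[ppi[, 1] != "G:STE2" & ppi[, 2] != "G:STE2", , drop = FALSE]
  pair_key <- apply(surviving, 1, function(r)
    paste(sort(paste0("P:", sub("^G:", "", r))), collapse = "|"))
  n_interactions <- length(unique(pair_key))

  ## TRIs, KIs, phosphatase interactions ---------------------------------
  targets_cdc14 <- paste0("G:", metabolic)
  decoy_tfs <- paste0("P:", fillers[2:6])
  tri_planted <- rbind(
    cbind("G:CDC14", targets_cdc14),                 # gene-identified controller
    cbind("P:STE12", paste0("G:", fillers[7:9])),
    cbind("G:STE2", paste0("G:", fillers[10])))      # ambiguous controller
  tri_pool <- expand.grid(controller = decoy_tfs,
                          target = paste0("G:", fillers),
                          stringsAsFactors = FALSE)
  tri_decoy <- tri_pool[sample(nrow(tri_pool), sc$n_tri_decoys), ]
  tri <- rbind(data.frame(controller = tri_planted[, 1], target = tri_planted[, 2],
                          stringsAsFactors = FALSE), tri_decoy)
  write_tsv(tri, file.path(dir, "tri.tsv"))
  ste2_tri_rows <- sum(tri$controller == "G:STE2")
  n_tri_kept <- nrow(tri) - ste2_tri_rows

  ki_pool <- setdiff(fillers, fillers[1:10])
  ki_decoy <- data.frame(
    controller = paste0("P:", sample(ki_pool, sc$n_ki_decoys, TRUE)),
    target = paste0("P:", sample(fillers, sc$n_ki_decoys, TRUE)),
    stringsAsFactors = FALSE)
  ki_decoy <- ki_decoy[!duplicated(ki_decoy), ]
  ki <- rbind(data.frame(controller = "P:SNF1",
                         target = c("P:CDC14", "P:GAL83"),
                         stringsAsFactors = FALSE), ki_decoy)
  write_tsv(ki, file.path(dir, "ki.tsv"))

  phos_decoy <- data.frame(
    controller = paste0("P:", sample(ki_pool, sc$n_phos_decoys, TRUE)),
    target = paste0("P:", sample(fillers, sc$n_phos_decoys, TRUE)),
    stringsAsFactors = FALSE)
  phos_decoy <- phos_decoy[!duplicated(phos_decoy), ]
  phos <- rbind(data.frame(controller = "P:CDC14", target = "P:FUS3",
                           stringsAsFactors = FALSE), phos_decoy)
  write_tsv(phos, file.path(dir, "phosphatase.tsv"))

  ## GO DAG and annotations ----------------------------------------------
  root <- "GO:0008150"; meta <- "GO:0008152"
  meta_kids <- c("GO:0006097", "GO:0006099", "GO:0006006", "GO:0006119")
  seed_kids <- c("GO:1900001", "GO:1900002")  # descendants of two filter seeds
  obo <- c("format-version: 1.2", "",
           "[Term]", paste0("id: ", root), "name: biological_process", "",
           unlist(lapply(.seed_go_terms, function(t)
             c("[Term]", paste0("id: ", t), paste0("is_a: ", root, " ! root"), ""))),
           "[Term]", paste0("id: ", seed_kids[1]),
           "name: synthetic MAPKKK-activation child",
           paste0("is_a: ", .seed_go_terms[3], " ! activation of MAPKKK activity"), "",
           "[Term]", paste0("id: ", seed_kids[2]),
           "name: synthetic pheromone-response part",
           paste0("relationship: part_of ", .seed_go_terms[1], " ! response to pheromone"), "",
           "[Term]", paste0("id: ", meta), "name: metabolic process",
           paste0("is_a: ", root, " ! root"), "",
           unlist(lapply(meta_kids, function(t)
             c("[Term]", paste0("id: ", t), paste0("is_a: ", meta, " ! metabolic"), ""))))
  writeLines(obo, file.path(dir, "go.obo"))

  gaf_line <- function(pid, go) {
    sym <- sub("^P:", "", pid)
    paste(c("OS", pid, sym, "", go, "FIX:0001", "IDA", "", "P",
            paste0(sym, " protein"), "", "protein", "taxon:559292",
            "20140710", "omicstore"), collapse = "\t")
  }
  planted_ann <- list(
    c("P:STE3", .seed_go_terms[1]),
    c("P:STE4", .seed_go_terms[2]),
    c("P:STE4", .seed_go_terms[2]),          # duplicate (protein, term) row
    c("P:STE5", .seed_go_terms[4]),
    c("P:FUS3", seed_kids[1]),               # passes only via descendant expansion
    c("P:STE12", .seed_go_terms[1]),
    c("P:DIM2", meta),
    c("P:DIM3", meta_kids[2]),
    c("P:SNF1", meta), c("P:CDC14", meta))
  ann_fillers <- sample(fillers, round(0.7 * n_filler))
  random_ann <- lapply(ann_fillers, function(f)
    c(paste0("P:", f), sample(meta_kids, 1L)))
  all_ann <- c(planted_ann, random_ann)
  writeLines(c("!gaf-version: 2.2",
               vapply(all_ann, function(a) gaf_line(a[1], a[2]), character(1))),
             file.path(dir, "annotations.gaf"))
  annotated <- unique(vapply(all_ann, `[[`, character(1), 1L))

  ## manifest ------------------------------------------------------------
  n_catalysis <- sum(vapply(strsplit(rxn_genes, ","), function(g)
    length(unique(trimws(g[nzchar(trimws(g))]))), integer(1)))
  per_tag <- list(
    SmallMolecule = sc$n_compounds, DNA = sc$n_chromosomes,
    DNARegion = sc$n_genes, RNA = sc$n_genes, Protein = n_proteins,
    Complex = 0L, Conversion = sc$n_reactions,
    MolecularInteraction = n_interactions, GeneticInteraction = 0L,
    Control = n_tri_kept + nrow(ki) + nrow(phos) + n_catalysis)
  per_rtype <- list(
    LOCATED_ON = sc$n_genes, TRANSCRIBED_TO = sc$n_genes,
    TRANSLATED_TO = n_proteins, INTERACTS_WITH = n_interactions,
    CONTROLS = n_tri_kept + nrow(ki) + nrow(phos) + n_catalysis,
    HAS_PARTICIPANT = 3L * sc$n_reactions, COMPONENT_OF = 0L)
  reactions_by_gene <- split(planted_rxn$reaction_id, planted_rxn$gene)
  manifest <- list(
    format = "omicstore-fixture", version = 1L, seed = as.integer(seed),
    scale = sc,
    counts = list(
      objects = sum(unlist(per_tag)), relations = sum(unlist(per_rtype)),
      per_tag = per_tag, per_rtype = per_rtype,
      annotated_proteins = length(annotated)),
    planted_paths = list(c("P:STE3", "P:STE4", "P:FUS3", "P:STE12")),
    planted_regulon = list(
      kinase = "P:SNF1",
      substrates = c("P:CDC14", "P:GAL83"),
      tfs = "P:CDC14",
      targets = list("P:CDC14" = sort(targets_cdc14)),
      reactions = lapply(reactions_by_gene[sort(names(reactions_by_gene))], sort)),
    go_filter_seeds = .seed_go_terms,
    path_search = list(sources = c("P:STE2", "P:STE3"), target = "P:STE12",
                       max_edges = 3L),
    ambiguous_participants = list(
      list(entity_id = "G:STE2", n_proteins = 2L,
           ppi_rows = ste2_ppi_rows, tri_rows = ste2_tri_rows)))
  write_manifest(manifest, file.path(dir, "manifest.json"))
  invisible(manifest)
}

.manifest_required <- c("format", "version", "seed", "scale", "counts",
                        "planted_paths", "planted_regulon", "go_filter_seeds",
                        "path_search", "ambiguous_participants")

#' Write / read the fixture manifest
#'
#' JSON round trip with a schema check: a manifest missing any required
#' section is rejected.
#'
#' @param manifest Manifest list.
#' @param path JSON file path.
#' @return `read_manifest()` returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(.manifest_required, names(manifest))
  if (length(missing))
    os_schema_error(sprintf("manifest lacks section(s): %s",
                            paste(missing, collapse = ", ")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) os_storage_error(sprintf("manifest '%s' not found", path))
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  missing <- setdiff(.manifest_required, names(m))
  if (length(missing))
    os_schema_error(sprintf("manifest lacks section(s): %s",
                            paste(missing, collapse = ", ")))
  m
}
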