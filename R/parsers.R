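# Parsers for the flat source formats that populate the store:
# FASTA chromosomes, a GFF3-style gene table, a protein TSV, BioGRID-like
# PPI pairs, control-interaction TSVs, compound/reaction TSVs and GAF
# annotations. Every parser emits a bundle — objects, relation specs, an
# exclusion log and a row-accounting summary — ready for insert_atomic().
#
# Identifier conventions used throughout the bundled formats:
#   chromosomes "C:<name>", genes "G:<symbol>", transcripts "R:<symbol>",
#   proteins "P:<accession>", compounds "M:<id>", reactions "RXN:<id>".
# The transcript id of gene "G:X" is always "R:X", which is how the protein
# table's TRANSLATED_TO edges are resolved through the gene table.

new_bundle <- function(objects = list(), relations = list(),
                       exclusions = empty_exclusion_log(),
                       errors = empty_error_report(),
                       rows_in = 0L, rows_emitted = 0L, extra = list()) {
  c(list(objects = objects, relations = relations, exclusions = exclusions,
         errors = errors,
         summary = list(rows_in = rows_in, rows_emitted = rows_emitted,
                        rows_excluded = sum(exclusions$n_records_dropped),
                        rows_errored = nrow(errors))),
    extra)
}

empty_exclusion_log <- function() {
  tibble::tibble(entity_id = character(0), rule = character(0),
                 reason = character(0), n_records_dropped = integer(0))
}
empty_error_report <- function() {
  tibble::tibble(line = integer(0), message = character(0))
}

read_tsv_file <- function(path, col_names) {
  if (!file.exists(path)) os_parse_error(sprintf("input file '%s' not found", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE, quote = "")
  missing <- setdiff(col_names, names(df))
  if (length(missing))
    os_parse_error(sprintf("'%s' lacks required column(s): %s",
                           path, paste(missing, collapse = ", ")))
  df
}

#' Parse a genome FASTA into chromosome (DNA) records
#'
#' One `DNA` record per sequence; the id is the first whitespace-delimited
#' header token, the rest of the header (if any) becomes the primary name.
#' The `length` attribute is set from the sequence length and the sequence
#' itself is stored.
#'
#' @param path FASTA file.
#' @return A bundle whose `objects` are the chromosome records.
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) os_parse_error(sprintf("input file '%s' not found", path))
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) os_parse_error(
                     sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e))))
  if (!length(seqs)) os_parse_error(sprintf("FASTA '%s' holds no sequences", path))
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    os_parse_error(sprintf("duplicate FASTA header id '%s'", ids[duplicated(ids)][1]))
  if (any(Biostrings::width(seqs) == 0L))
    os_parse_error(sprintf("FASTA record '%s' has an empty sequence",
                           ids[Biostrings::width(seqs) == 0L][1]))
  objects <- lapply(seq_along(seqs), function(i) {
    desc <- sub("^\\S+\\s*", "", headers[i])
    rec <- make_object("DNA", ids[i],
                       if (nzchar(desc)) desc else ids[i],
                       list(length = Biostrings::width(seqs)[i],
                            sequence = as.character(seqs[[i]])),
                       source = "genome_fasta")
    add_name(rec, ids[i])
  })
  new_bundle(objects = objects, rows_in = length(seqs), rows_emitted = length(seqs))
}

#' Parse a GFF3-style gene table into genes, transcripts and their relations
#'
#' Per gene row, emits one `DNARegion` (1-based inclusive coordinates) and
#' one `RNA` transcript (one transcript per gene), plus
#' `LOCATED_ON`(gene -> chromosome) and `TRANSCRIBED_TO`(gene -> transcript)
#' relations. Rows need `ID=` (and optionally `Name=`) attributes, a strand
#' of `+` or `-`, and `start <= end`.
#'
#' @param path GFF3 file.
#' @return A bundle; `extra` field `gene_ids` lists the gene ids in file
#'   order.
#' @export
parse_gene_table <- function(path) {
  if (!file.exists(path)) os_parse_error(sprintf("input file '%s' not found", path))
  g <- tryCatch(rtracklayer::readGFF(path),
                error = function(e) os_parse_error(
                  sprintf("cannot read GFF3 '%s': %s", path, conditionMessage(e))))
  g <- as.data.frame(g)
  if (!nrow(g)) os_parse_error(sprintf("gene table '%s' is empty", path))
  objects <- list(); relations <- list(); gene_ids <- character(0)
  for (i in seq_len(nrow(g))) {
    row <- g[i, ]
    id <- if ("ID" %in% names(g)) as.character(row$ID) else NA_character_
    if (!length(id) || is.na(id) || !nzchar(id))
      os_parse_error(sprintf("gene table row %d lacks an ID attribute", i))
    strand <- as.character(row$strand)
    if (is.na(strand) || !strand %in% c("+", "-"))
      os_parse_error(sprintf("gene '%s': unknown strand '%s'", id, strand))
    if (is.na(row$start) || is.na(row$end) || row$start > row$end)
      os_parse_error(sprintf("gene '%s': start must be <= end", id))
    nm <- if ("Name" %in% names(g)) as.character(row$Name) else NA_character_
    if (!length(nm) || is.na(nm) || !nzchar(nm)) nm <- id
    gene <- make_object("DNARegion", id, nm,
                        list(chromosome = as.character(row$seqid),
                             start = row$start, end = row$end, strand = strand),
                        source = "gene_table")
    rna_id <- paste0("R:", sub("^G:", "", id))
    rna <- make_object("RNA", rna_id, paste0(nm, " transcript"),
                       list(encoded_by = id), source = "gene_table")
    objects <- c(objects, list(gene, rna))
    relations <- c(relations,
                   list(rel_spec("LOCATED_ON", id, as.character(row$seqid)),
                        rel_spec("TRANSCRIBED_TO", id, rna_id)))
    gene_ids <- c(gene_ids, id)
  }
  new_bundle(objects = objects, relations = relations,
             rows_in = nrow(g), rows_emitted = nrow(g),
             extra = list(gene_ids = gene_ids))
}

#' Parse the protein table
#'
#' TSV with columns `protein_id`, `gene_id`, `name` and optional `sequence`.
#' Emits one `Protein` per row plus a `TRANSLATED_TO` relation from the
#' gene's transcript (resolved through the gene table's transcript ids) to
#' the protein. Rows referencing a gene absent from `gene_ids` are an error.
#'
#' @param path Protein TSV.
#' @param gene_ids Character vector of known gene ids (from
#'   [parse_gene_table()]).
#' @return A bundle; `extra` field `idmap` is the gene/protein identifier
#'   map (see [build_id_map()]).
#' @export
parse_protein_table <- function(path, gene_ids) {
  df <- read_tsv_file(path, c("protein_id", "gene_id", "name"))
  unknown <- setdiff(unique(df$gene_id), gene_ids)
  if (length(unknown))
    os_parse_error(sprintf("protein table references unknown gene id(s): %s",
                           paste(unknown, collapse = ", ")))
  if (anyDuplicated(df$protein_id))
    os_parse_error(sprintf("duplicate protein id '%s'",
                           df$protein_id[duplicated(df$protein_id)][1]))
  objects <- list(); relations <- list()
  for (i in seq_len(nrow(df))) {
    attrs <- list()
    if ("sequence" %in% names(df) && nzchar(df$sequence[i]))
      attrs$sequence <- df$sequence[i]
    p <- make_object("Protein", df$protein_id[i], df$name[i], attrs,
                     source = "protein_table")
    rna_id <- paste0("R:", sub("^G:", "", df$gene_id[i]))
    objects <- c(objects, list(p))
    relations <- c(relations, list(rel_spec("TRANSLATED_TO", rna_id, df$protein_id[i])))
  }
  new_bundle(objects = objects, relations = relations,
             rows_in = nrow(df), rows_emitted = nrow(df),
             extra = list(idmap = build_id_map(df$gene_id, df$protein_id)))
}

#' Build the gene/protein identifier map
#'
#' @param gene_ids,protein_ids Parallel character vectors (one protein row
#'   each).
#' @return List with mutually consistent `gene_to_protein` and
#'   `protein_to_gene` maps (named lists of character vectors).
#' @export
build_id_map <- function(gene_ids, protein_ids) {
  stopifnot(length(gene_ids) == length(protein_ids))
  list(gene_to_protein = lapply(split(protein_ids, gene_ids), sort),
       protein_to_gene = lapply(split(gene_ids, protein_ids), sort))
}

# Gene symbols with a mapping to anything other than exactly one protein are
# ambiguous; their rows are excluded wholesale (auditable in the log).
ambiguous_genes <- function(genes, idmap) {
  unique(genes[vapply(genes, function(g)
    length(idmap$gene_to_protein[[g]] %||% character(0)) != 1L, logical(1))])
}

#' Parse a BioGRID-style PPI table under the binary-relation rule
#'
#' TSV with two systematic gene-name columns `gene_a` and `gene_b`. Each
#' participant is mapped to its protein through `idmap`; a participant
#' mapping to anything other than exactly one protein conflicts with the
#' binary representation of PPIs, so every row involving it is excluded and
#' logged (one log entry per ambiguous participant; a row involving two
#' ambiguous participants is charged to the first). Surviving rows emit one
#' `MolecularInteraction` object and one undirected `INTERACTS_WITH`
#' relation per distinct protein pair; self-interactions are kept and
#' duplicate rows collapse onto one interaction.
#'
#' @param path PPI TSV.
#' @param idmap From [build_id_map()].
#' @return A bundle (with a populated exclusion log when ambiguous
#'   participants occur).
#' @export
parse_ppi_tab <- function(path, idmap) {
  df <- read_tsv_file(path, c("gene_a", "gene_b"))
  if (!nrow(df)) return(new_bundle())
  bad <- vapply(seq_len(nrow(df)), function(i)
    !nzchar(df$gene_a[i]) || !nzchar(df$gene_b[i]), logical(1))
  if (any(bad))
    os_parse_error(sprintf("malformed PPI row at line %d", which(bad)[1] + 1L))
  amb <- ambiguous_genes(unique(c(df$gene_a, df$gene_b)), idmap)
  exclusions <- empty_exclusion_log()
  keep <- rep(TRUE, nrow(df))
  charged <- rep(FALSE, nrow(df))
  for (g in sort(amb)) {
    hit <- (df$gene_a == g | df$gene_b == g) & !charged
    charged <- charged | hit
    keep <- keep & !(df$gene_a == g | df$gene_b == g)
    exclusions <- rbind(exclusions, tibble::tibble(
      entity_id = g, rule = "ambiguous_mapping",
      reason = sprintf("'%s' maps to %d protein(s); binary PPI rule requires exactly 1",
                       g, length(idmap$gene_to_protein[[g]] %||% character(0))),
      n_records_dropped = sum(hit)))
  }
  objects <- list(); relations <- list(); seen <- character(0)
  for (i in which(keep)) {
    pa <- idmap$gene_to_protein[[df$gene_a[i]]]
    pb <- idmap$gene_to_protein[[df$gene_b[i]]]
    pair <- sort(c(pa, pb))
    key <- paste(pair, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    mi <- make_object("MolecularInteraction", paste0("MI:", key),
                      paste(pair, collapse = "--"),
                      list(participants = pair), source = "ppi_table")
    objects <- c(objects, list(mi))
    relations <- c(relations, list(rel_spec("INTERACTS_WITH", pair[1], pair[2])))
  }
  new_bundle(objects = objects, relations = relations, exclusions = exclusions,
             rows_in = nrow(df), rows_emitted = sum(keep))
}

#' Parse a control-interaction table (TRI, kinase or phosphatase rows)
#'
#' TSV with columns `controller` and `target`. Per row, emits a `Control`
#' object and a `CONTROLS` relation from the controller protein to the
#' controlled entity, with the control type echoed as an edge qualifier:
#' transcriptional-regulation rows (`kind = "TRI"`) target genes and carry
#' `TRANSCRIPTION_REGULATION`; kinase rows carry `PHOSPHORYLATION` and
#' phosphatase rows `DEPHOSPHORYLATION`, both targeting proteins.
#'
#' TRI controllers given as gene symbols are mapped to proteins through
#' `idmap` under the same ambiguity-exclusion rule as PPIs; kinase and
#' phosphatase rows already name proteins and need no mapping. Rows naming
#' unknown participants are collected into the per-row error report rather
#' than raised.
#'
#' @param path Control TSV.
#' @param kind `"TRI"`, `"KI"` or `"PHOSPHATASE"`.
#' @param idmap From [build_id_map()].
#' @param known_genes,known_proteins Valid id universes for the endpoints.
#' @return A bundle.
#' @export
parse_control_tab <- function(path, kind = c("TRI", "KI", "PHOSPHATASE"),
                              idmap, known_genes, known_proteins) {
  kind <- match.arg(kind)
  df <- read_tsv_file(path, c("controller", "target"))
  ctype <- switch(kind, TRI = "TRANSCRIPTION_REGULATION",
                  KI = "PHOSPHORYLATION", PHOSPHATASE = "DEPHOSPHORYLATION")
  if (!nrow(df)) return(new_bundle())
  exclusions <- empty_exclusion_log()
  errors <- empty_error_report()
  keep <- rep(TRUE, nrow(df))
  if (kind == "TRI") {
    as_gene <- df$controller %in% names(idmap$gene_to_protein) |
      !df$controller %in% known_proteins
    amb <- ambiguous_genes(unique(df$controller[as_gene]), idmap)
    amb <- setdiff(amb, known_proteins)  # resolvable as proteins directly
    for (g in sort(amb)) {
      if (!g %in% names(idmap$gene_to_protein)) next  # handled as unknown below
      hit <- df$controller == g & keep
      keep <- keep & df$controller != g
      exclusions <- rbind(exclusions, tibble::tibble(
        entity_id = g, rule = "ambiguous_mapping",
        reason = sprintf("'%s' maps to %d proteins; controller mapping requires exactly 1",
                         g, length(idmap$gene_to_protein[[g]])),
        n_records_dropped = sum(hit)))
    }
  }
  objects <- list(); relations <- list(); n_emitted <- 0L
  for (i in which(keep)) {
    ctrl <- df$controller[i]; tgt <- df$target[i]
    ctrl_prot <- if (ctrl %in% known_proteins) ctrl
    else if (ctrl %in% names(idmap$gene_to_protein)) idmap$gene_to_protein[[ctrl]]
    else NA_character_
    if (length(ctrl_prot) != 1L || is.na(ctrl_prot)) {
      errors <- rbind(errors, tibble::tibble(
        line = i + 1L, message = sprintf("unknown controller id '%s'", ctrl)))
      next
    }
    tgt_ok <- if (kind == "TRI") tgt %in% known_genes else tgt %in% known_proteins
    if (!tgt_ok) {
      errors <- rbind(errors, tibble::tibble(
        line = i + 1L, message = sprintf("unknown target id '%s'", tgt)))
      next
    }
    ctl <- make_object("Control", sprintf("CTRL:%s:%s>%s", kind, ctrl_prot, tgt),
                       sprintf("%s %s of %s", ctrl_prot, tolower(ctype), tgt),
                       list(control_type = ctype), source = paste0(tolower(kind), "_table"))
    objects <- c(objects, list(ctl))
    relations <- c(relations, list(
      rel_spec("CONTROLS", ctrl_prot, tgt, list(control_type = ctype))))
    n_emitted <- n_emitted + 1L
  }
  new_bundle(objects = objects, relations = relations, exclusions = exclusions,
             errors = errors, rows_in = nrow(df), rows_emitted = n_emitted)
}

#' Parse compound and reaction tables
#'
#' Compounds come from a TSV with columns `compound_id`, `name`, `formula`;
#' reactions from a TSV with columns `reaction_id`, `equation` (of the form
#' `"a + b => c"`) and `genes` (comma-separated gene ids, possibly empty).
#' Each reaction becomes a `Conversion` with `HAS_PARTICIPANT` edges (role
#' `SUBSTRATE`/`PRODUCT`) to its declared compounds, and a
#' `CONTROLS` catalysis edge from each associated gene's protein (resolved
#' gene -> transcript -> protein through `idmap`) to the conversion.
#'
#' @param compounds_path,reactions_path The two TSVs.
#' @param idmap From [build_id_map()].
#' @return A bundle covering both files (`rows_in` counts reaction rows
#'   plus compound rows).
#' @export
parse_reactions <- function(compounds_path, reactions_path, idmap) {
  cmp <- read_tsv_file(compounds_path, c("compound_id", "name"))
  rxn <- read_tsv_file(reactions_path, c("reaction_id", "equation", "genes"))
  objects <- lapply(seq_len(nrow(cmp)), function(i) {
    attrs <- list()
    if ("formula" %in% names(cmp) && nzchar(cmp$formula[i]))
      attrs$formula <- cmp$formula[i]
    make_object("SmallMolecule", cmp$compound_id[i], cmp$name[i], attrs,
                source = "compound_table")
  })
  relations <- list()
  for (i in seq_len(nrow(rxn))) {
    eq <- rxn$equation[i]
    if (!grepl("=>", eq, fixed = TRUE))
      os_parse_error(sprintf("reaction '%s': equation lacks '=>'", rxn$reaction_id[i]))
    sides <- strsplit(eq, "=>", fixed = TRUE)[[1]]
    split_side <- function(s) {
      parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
      parts[nzchar(parts)]
    }
    subs <- split_side(sides[1]); prods <- split_side(if (length(sides) > 1) sides[2] else "")
    if (!length(subs) || !length(prods))
      os_parse_error(sprintf("reaction '%s': both equation sides need participants",
                             rxn$reaction_id[i]))
    undeclared <- setdiff(c(subs, prods), cmp$compound_id)
    if (length(undeclared))
      os_parse_error(sprintf("reaction '%s': undeclared compound(s) %s",
                             rxn$reaction_id[i], paste(undeclared, collapse = ", ")))
    conv <- make_object("Conversion", rxn$reaction_id[i],
                        if ("name" %in% names(rxn) && nzchar(rxn$name[i]))
                          rxn$name[i] else rxn$reaction_id[i],
                        list(substrates = subs, products = prods),
                        source = "reaction_table")
    objects <- c(objects, list(conv))
    for (s in unique(subs))
      relations <- c(relations, list(rel_spec("HAS_PARTICIPANT", rxn$reaction_id[i], s,
                                              list(role = "SUBSTRATE"))))
    for (p in unique(prods))
      relations <- c(relations, list(rel_spec("HAS_PARTICIPANT", rxn$reaction_id[i], p,
                                              list(role = "PRODUCT"))))
    genes <- trimws(strsplit(rxn$genes[i], ",", fixed = TRUE)[[1]])
    for (g in unique(genes[nzchar(genes)])) {
      prot <- idmap$gene_to_protein[[g]]
      if (length(prot) != 1L)
        os_parse_error(sprintf("reaction '%s': gene '%s' has no unique protein",
                               rxn$reaction_id[i], g))
      relations <- c(relations, list(
        rel_spec("CONTROLS", prot, rxn$reaction_id[i],
                 list(control_type = "CATALYSIS"))))
      objects <- c(objects, list(
        make_object("Control", sprintf("CTRL:CAT:%s>%s", prot, rxn$reaction_id[i]),
                    sprintf("%s catalysis of %s", prot, rxn$reaction_id[i]),
                    list(control_type = "CATALYSIS"), source = "reaction_table")))
    }
  }
  new_bundle(objects = objects, relations = relations,
             rows_in = nrow(cmp) + nrow(rxn), rows_emitted = nrow(cmp) + nrow(rxn))
}

#' Parse a GAF 2.x annotation file into a protein -> GO-term map
#'
#' Lines starting with `!` are comments; data lines need at least 15
#' tab-separated columns with the annotated object id in column 2 and the GO
#' id (`GO:` plus seven digits) in column 5. Duplicate (protein, term) pairs
#' collapse.
#'
#' @param path GAF file.
#' @return Named list mapping protein id to a sorted character vector of GO
#'   term ids.
#' @export
parse_gaf <- function(path) {
  if (!file.exists(path)) os_parse_error(sprintf("input file '%s' not found", path))
  lines <- readLines(path)
  ann <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line) || startsWith(line, "!")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 15L)
      os_parse_error(sprintf("GAF line %d has %d columns (15 required)", i, length(f)))
    go <- f[5]
    if (!grepl("^GO:[0-9]{7}$", go))
      os_parse_error(sprintf("GAF line %d: malformed GO id '%s'", i, go))
    ann[[f[2]]] <- union(ann[[f[2]]] %||% character(0), go)
  }
  lapply(ann, sort)
}
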