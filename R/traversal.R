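# Graph views over the store: GO-term expansion, GO-constrained signaling
# path detection over the PPI network, the kinase -> TF -> gene -> reaction
# regulon traversal, and a generic multi-hop follow() primitive.

#' Construct a GO DAG object
#'
#' @param terms Character vector of term ids.
#' @param parents Named list mapping a term to its parent terms (`is_a` and
#'   `part_of` collapsed). Terms without parents may be omitted.
#' @return A `go_dag`.
#' @export
go_dag <- function(terms, parents = list()) {
  terms <- unique(as.character(terms))
  parents <- parents[intersect(names(parents), terms)]
  for (ch in names(parents)) {
    ps <- unique(as.character(parents[[ch]]))
    bad <- setdiff(ps, terms)
    if (length(bad))
      os_schema_error(sprintf("parent term(s) %s of %s are not in the term set",
                              paste(bad, collapse = ", "), ch))
    parents[[ch]] <- ps
  }
  dag <- structure(list(terms = terms, parents = parents), class = "go_dag")
  # cycle check: repeated leaf-stripping must consume every term
  remaining <- terms
  repeat {
    leaves <- remaining[vapply(remaining, function(t)
      !length(intersect(dag$parents[[t]] %||% character(0), remaining)), logical(1))]
    if (!length(leaves)) break
    remaining <- setdiff(remaining, leaves)
  }
  if (length(remaining))
    os_schema_error(sprintf("term graph contains a cycle involving %s",
                            paste(utils::head(remaining, 3), collapse = ", ")))
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d child->parent links\n",
              length(x$terms), sum(lengths(x$parents))))
  invisible(x)
}

#' Read a GO term graph from minimal OBO or a child-parent TSV
#'
#' OBO input uses `[Term]` stanzas with `id:`, `is_a:` and
#' `relationship: part_of` lines (both relationship kinds are collapsed into
#' the parent map). TSV input has two columns, child and parent, with an
#' optional header.
#'
#' @param path `.obo` file or two-column TSV.
#' @return A `go_dag`.
#' @export
read_go_dag <- function(path) {
  if (!file.exists(path)) os_parse_error(sprintf("input file '%s' not found", path))
  lines <- readLines(path)
  if (any(grepl("^\\[Term\\]", lines))) {
    terms <- character(0); parents <- list(); cur <- NULL
    for (line in lines) {
      line <- trimws(line)
      if (line == "[Term]") { cur <- NULL; next }
      if (startsWith(line, "id:")) {
        cur <- trimws(sub("^id:", "", line))
        terms <- c(terms, cur)
      } else if (startsWith(line, "is_a:") && !is.null(cur)) {
        p <- trimws(sub("!.*$", "", sub("^is_a:", "", line)))
        parents[[cur]] <- c(parents[[cur]] %||% character(0), p)
      } else if (grepl("^relationship:\\s*part_of", line) && !is.null(cur)) {
        p <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", line)))
        parents[[cur]] <- c(parents[[cur]] %||% character(0), p)
      }
    }
    go_dag(terms, parents)
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            colClasses = "character", comment.char = "#")
    if (identical(tolower(df[1, 1]), "child")) df <- df[-1, , drop = FALSE]
    if (ncol(df) < 2L) os_parse_error("term TSV needs child and parent columns")
    go_dag(unique(c(df[[1]], df[[2]])),
           lapply(split(df[[2]], df[[1]]), unique))
  }
}

#' Expand seed GO terms to all their descendants
#'
#' The recursive filter interpretation of a seed term set: a term qualifies
#' if it is a seed or any of its ancestors is, so the expansion returns the
#' seeds plus every descendant term.
#'
#' @param dag A `go_dag`.
#' @param seed_terms Character vector of term ids present in `dag`.
#' @return Sorted character vector of expanded terms.
#' @export
expand_go_terms <- function(dag, seed_terms) {
  stopifnot(inherits(dag, "go_dag"))
  seed_terms <- unique(as.character(seed_terms))
  missing <- setdiff(seed_terms, dag$terms)
  if (length(missing))
    os_argument_error(sprintf("seed term(s) not in the DAG: %s",
                              paste(missing, collapse = ", ")))
  children <- list()
  for (ch in names(dag$parents))
    for (p in dag$parents[[ch]])
      children[[p]] <- c(children[[p]] %||% character(0), ch)
  out <- seed_terms; frontier <- seed_terms
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(lapply(frontier, function(t)
      children[[t]] %||% character(0)), use.names = FALSE)), out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

#' Does a protein pass the GO-term filter?
#'
#' True iff the protein's annotation set intersects the expanded term set;
#' unannotated proteins fail.
#'
#' @param protein_id Protein id.
#' @param annotations Named list protein id -> GO term ids (see
#'   [parse_gaf()]).
#' @param expanded_terms Terms from [expand_go_terms()].
#' @return Logical scalar.
#' @export
protein_passes_filter <- function(protein_id, annotations, expanded_terms) {
  length(intersect(annotations[[protein_id]] %||% character(0), expanded_terms)) > 0L
}

# Undirected PPI adjacency (named list id -> sorted neighbor ids) from the
# store's INTERACTS_WITH relations.
ppi_adjacency <- function(store) {
  adj <- list()
  for (rid in ls(store$relations)) {
    rel <- store$relations[[rid]]
    if (rel$rtype != "INTERACTS_WITH") next
    adj[[rel$source_id]] <- c(adj[[rel$source_id]] %||% character(0), rel$target_id)
    adj[[rel$target_id]] <- c(adj[[rel$target_id]] %||% character(0), rel$source_id)
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' GO-constrained signaling-path search over the PPI network
#'
#' Enumerates every simple path along undirected `INTERACTS_WITH` edges from
#' any source protein to the target with at most `max_edges` edges, keeping
#' only paths whose intermediate nodes pass the GO filter (the fixed source
#' and target proteins are exempt). Sources absent from the PPI graph — for
#' example a receptor whose interactions were excluded at population time by
#' the identifier-ambiguity rule — simply contribute no paths.
#'
#' @param store A populated `bio_store`.
#' @param sources Character vector of source protein ids.
#' @param target Target protein id (must exist in the store).
#' @param max_edges Maximum path length in edges (default 3).
#' @param filter_terms Seed GO term ids.
#' @param dag A `go_dag` used to expand `filter_terms` to descendants.
#' @param annotations Named list protein id -> GO term ids.
#' @return A `signaling_paths` object: list of paths (each a character
#'   vector of node ids), sorted by length then lexicographically, plus the
#'   search parameters. Use [tidy()][generics::tidy] for a tabular view.
#' @export
find_signaling_paths <- function(store, sources, target, max_edges = 3L,
                                 filter_terms, dag, annotations) {
  stopifnot(inherits(store, "bio_store"))
  if (is.null(store$objects[[target]]))
    os_not_found_error(sprintf("unknown target id '%s'", target))
  if (!is_count(max_edges)) os_argument_error("max_edges must be a positive integer")
  expanded <- expand_go_terms(dag, filter_terms)
  adj <- ppi_adjacency(store)
  passes <- function(id) protein_passes_filter(id, annotations, expanded)

  paths <- list()
  walk <- function(node, visited) {
    if (node == target) {
      paths[[length(paths) + 1L]] <<- visited
      return(invisible())  # target reached; simple paths cannot extend past it
    }
    if (length(visited) > max_edges) return(invisible())
    for (nb in adj[[node]] %||% character(0)) {
      if (nb %in% visited) next
      if (nb != target && !passes(nb)) next  # intermediates must pass the filter
      walk(nb, c(visited, nb))
    }
  }
  for (src in sort(unique(sources))) {
    if (src == target) next
    if (is.null(adj[[src]])) next  # not in the PPI graph: zero paths, no error
    walk(src, src)
  }
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths <- paths[!duplicated(keys)]
  ord <- order(lengths(paths),
               vapply(paths, paste, character(1), collapse = "\r"))
  structure(list(paths = paths[ord], sources = sort(unique(sources)),
                 target = target, max_edges = as.integer(max_edges),
                 filter_terms = sort(unique(filter_terms)),
                 expanded_terms = expanded),
            class = "signaling_paths")
}

#' @export
print.signaling_paths <- function(x, ...) {
  cat(sprintf("<signaling_paths> %d path(s) to %s (max %d edges, %d filter terms)\n",
              length(x$paths), x$target, x$max_edges, length(x$filter_terms)))
  for (p in x$paths) cat("  ", paste(p, collapse = " -- "), "\n")
  invisible(x)
}

#' Kinase regulon traversal: substrates, TFs, target genes, reactions
#'
#' Starting from a kinase protein: its substrates are the out-neighbors via
#' phosphorylation control edges; those substrates with at least one
#' outgoing transcription-regulation edge act as transcription factors; each
#' TF's target genes are read off those edges; and each target gene's
#' biochemical reactions are reached through its transcript and protein to
#' the conversions the protein catalyzes
#' (gene -> transcript -> protein -> catalysis -> conversion). All result
#' sets are sorted and deterministic.
#'
#' @param store A populated `bio_store`.
#' @param kinase_protein_id Protein id of the kinase.
#' @return A `regulon` object: list with `kinase`, `substrates`, `tfs`,
#'   `targets` (named list tf -> gene ids) and `reactions` (named list
#'   gene -> conversion ids).
#' @export
kinase_regulon <- function(store, kinase_protein_id) {
  stopifnot(inherits(store, "bio_store"))
  rec <- store$objects[[kinase_protein_id]]
  if (is.null(rec)) os_not_found_error(sprintf("unknown id '%s'", kinase_protein_id))
  if (rec$tag != "Protein")
    os_argument_error(sprintf("'%s' is a %s, not a Protein", kinase_protein_id, rec$tag))
  out_ids <- function(id, qual) {
    vapply(neighbors(store, id, rtype = "CONTROLS", direction = "OUT",
                     qualifier_filter = list(control_type = qual)),
           function(x) x$object$id, character(1))
  }
  substrates <- sort(unique(out_ids(kinase_protein_id, "PHOSPHORYLATION")))
  tfs <- character(0); targets <- list()
  for (s in substrates) {
    genes <- sort(unique(out_ids(s, "TRANSCRIPTION_REGULATION")))
    if (length(genes)) { tfs <- c(tfs, s); targets[[s]] <- genes }
  }
  reactions <- list()
  for (gene in sort(unique(unlist(targets, use.names = FALSE)))) {
    rxns <- follow(store, gene, list(
      list(rtype = "TRANSCRIBED_TO", direction = "OUT"),
      list(rtype = "TRANSLATED_TO", direction = "OUT"),
      list(rtype = "CONTROLS", direction = "OUT",
           qualifier_filter = list(control_type = "CATALYSIS"))))
    if (length(rxns)) reactions[[gene]] <- rxns
  }
  structure(list(kinase = kinase_protein_id, substrates = substrates,
                 tfs = sort(tfs), targets = targets, reactions = reactions),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> kinase %s: %d substrate(s), %d TF(s), %d target gene(s), %d reaction(s)\n",
              x$kinase, length(x$substrates), length(x$tfs),
              length(unique(unlist(x$targets))), length(unique(unlist(x$reactions)))))
  invisible(x)
}

#' Multi-hop relation traversal
#'
#' Composes [neighbors()] step by step: starting from `start_ids`, each step
#' follows relations of one type in one direction (optionally restricted by
#' qualifiers) and feeds the reached objects into the next step.
#'
#' @param store A `bio_store`.
#' @param start_ids Character vector of starting object ids.
#' @param steps List of steps; each a list with `rtype`, `direction`
#'   (default `"OUT"`) and optional `qualifier_filter`.
#' @return Sorted character vector of end ids (empty if `start_ids` is).
#' @export
follow <- function(store, start_ids, steps) {
  stopifnot(inherits(store, "bio_store"))
  if (!length(steps)) os_argument_error("steps must be non-empty")
  ids <- unique(as.character(start_ids))
  for (step in steps) {
    if (!is_string(step$rtype) || !step$rtype %in% relation_types())
      os_schema_error(sprintf("unknown relation type '%s'",
                              as.character(step$rtype)[1]))
    nxt <- character(0)
    for (id in ids) {
      if (is.null(store$objects[[id]])) next
      nb <- neighbors(store, id, rtype = step$rtype,
                      direction = step$direction %||% "OUT",
                      qualifier_filter = step$qualifier_filter %||% NULL)
      nxt <- c(nxt, vapply(nb, function(x) x$object$id, character(1)))
    }
    ids <- unique(nxt)
    if (!length(ids)) break
  }
  sort(ids)
}
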