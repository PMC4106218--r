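# Shared fixtures and oracles for the suite.
#
# The default fixture is generated and populated once per test run and must
# be treated as read-only; tests that mutate a store build their own.

.fixture_cache <- new.env(parent = emptyenv())

shared_fixture <- function(seed = 1L) {
  key <- paste0("seed", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("omicstore-fixture-", seed))
    unlink(dir, recursive = TRUE)
    manifest <- generate_fixture(dir, seed = seed)
    res <- populate_store(dir)
    .fixture_cache[[key]] <- c(list(dir = dir, manifest = manifest), res)
  }
  .fixture_cache[[key]]
}

# A small hand-built store: one chromosome, two genes/transcripts/proteins,
# for store-level tests that mutate state.
tiny_store <- function() {
  st <- bio_store()
  objs <- list(
    make_object("DNA", "C:I", "chrI", list(length = 10000L)),
    make_object("DNARegion", "G:AAA", "AAA",
                list(chromosome = "C:I", start = 100L, end = 400L, strand = "+")),
    make_object("DNARegion", "G:BBB", "BBB",
                list(chromosome = "C:I", start = 600L, end = 900L, strand = "-")),
    make_object("RNA", "R:AAA", "AAA transcript", list(encoded_by = "G:AAA")),
    make_object("RNA", "R:BBB", "BBB transcript", list(encoded_by = "G:BBB")),
    make_object("Protein", "P:AAA", "Aaa"),
    make_object("Protein", "P:BBB", "Bbb"))
  rels <- list(
    rel_spec("LOCATED_ON", "G:AAA", "C:I"),
    rel_spec("LOCATED_ON", "G:BBB", "C:I"),
    rel_spec("TRANSCRIBED_TO", "G:AAA", "R:AAA"),
    rel_spec("TRANSCRIBED_TO", "G:BBB", "R:BBB"),
    rel_spec("TRANSLATED_TO", "R:AAA", "P:AAA"),
    rel_spec("TRANSLATED_TO", "R:BBB", "P:BBB"))
  insert_atomic(st, objs, rels)
  st
}

# --- random PPI graph + independent path oracle ------------------------------

# Random undirected graph over <= n nodes with edge probability p, plus
# random GO annotations over a 3-term toy DAG (seed S, child C under S,
# unrelated U).
random_ppi_case <- function(n = 30L, p = 0.15) {
  nodes <- sprintf("P:N%02d", seq_len(n))
  upper <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sel <- upper[stats::runif(nrow(upper)) < p, , drop = FALSE]
  edges <- cbind(nodes[sel[, 1]], nodes[sel[, 2]])
  dag <- go_dag(c("GO:0000001", "GO:0000002", "GO:0000009"),
                list("GO:0000002" = "GO:0000001"))
  ann <- lapply(stats::setNames(nodes, nodes), function(x) {
    terms <- c("GO:0000001", "GO:0000002", "GO:0000009")
    picked <- terms[stats::runif(3) < 0.35]
    if (length(picked)) picked else NULL
  })
  ann <- Filter(Negate(is.null), ann)
  ends <- sample(nodes, 3L)
  list(nodes = nodes, edges = edges, dag = dag, annotations = ann,
       sources = ends[1:2], target = ends[3], filter_terms = "GO:0000001")
}

ppi_case_store <- function(case) {
  st <- bio_store()
  insert_atomic(st, lapply(case$nodes, function(id)
    make_object("Protein", id, sub("^P:", "", id))))
  for (i in seq_len(nrow(case$edges)))
    link(st, "INTERACTS_WITH", case$edges[i, 1], case$edges[i, 2])
  st
}

# Independent oracle: igraph simple-path enumeration with post-hoc filtering
# of intermediate nodes (sources and target exempt).
brute_force_paths <- function(case, max_edges) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(case$edges), directed = FALSE,
    vertices = data.frame(name = case$nodes))
  expanded <- expand_go_terms(case$dag, case$filter_terms)
  passes <- vapply(case$nodes, function(id)
    length(intersect(case$annotations[[id]] %||% character(0), expanded)) > 0,
    logical(1))
  names(passes) <- case$nodes
  out <- character(0)
  for (src in setdiff(unique(case$sources), case$target)) {
    if (igraph::degree(g, src) == 0) next
    sp <- igraph::all_simple_paths(g, from = src, to = case$target,
                                   cutoff = max_edges)
    for (p in sp) {
      ids <- igraph::V(g)$name[as.integer(p)]
      mids <- ids[-c(1L, length(ids))]
      if (all(passes[mids])) out <- c(out, paste(ids, collapse = " "))
    }
  }
  sort(unique(out))
}

path_strings <- function(sp) {
  sort(vapply(sp$paths, paste, character(1), collapse = " "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
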