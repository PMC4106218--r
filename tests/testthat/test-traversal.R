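# Independent closure oracle: a term qualifies if any of its ancestors
# (computed recursively, nothing shared with expand_go_terms) is a seed.
closure_oracle <- function(dag, seeds) {
  ancestors <- function(t) {
    ps <- dag$parents[[t]] %||% character(0)
    unique(c(ps, unlist(lapply(ps, ancestors), use.names = FALSE)))
  }
  sort(unique(c(seeds, Filter(function(t)
    length(intersect(c(t, ancestors(t)), seeds)) > 0, dag$terms))))
}

test_that("GO expansion returns seeds plus all descendants", {
  dag <- go_dag(c("s", "c", "g", "u"),
                list(c = "s", g = "c"))
  expect_identical(expand_go_terms(dag, "s"), c("c", "g", "s"))
  expect_identical(expand_go_terms(dag, "u"), "u")
  expect_error(expand_go_terms(dag, "nope"), class = "omics_argument_error")
})

test_that("GO expansion equals brute-force transitive closure on random DAGs", {
  set.seed(11)
  for (i in 1:20) {
    n <- 50L
    terms <- sprintf("GO:%07d", seq_len(n))
    # random DAG: parents only among earlier terms, so acyclicity holds
    parents <- list()
    for (j in 2:n) {
      k <- sample(0:min(2L, j - 1L), 1)
      if (k > 0) parents[[terms[j]]] <- sample(terms[seq_len(j - 1L)], k)
    }
    dag <- go_dag(terms, parents)
    seeds <- sample(terms, 3L)
    expect_identical(expand_go_terms(dag, seeds), closure_oracle(dag, seeds))
  }
})

test_that("cyclic term graphs are rejected", {
  expect_error(go_dag(c("a", "b"), list(a = "b", b = "a")),
               class = "omics_schema_error")
  expect_error(go_dag("a", list(a = "zz")), class = "omics_schema_error")
})

test_that("OBO and TSV term-graph dialects load identically", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "",
               "[Term]", "id: GO:0000002", "is_a: GO:0000001 ! parent", "",
               "[Term]", "id: GO:0000003",
               "relationship: part_of GO:0000002 ! part"), obo)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("child\tparent", "GO:0000002\tGO:0000001",
               "GO:0000003\tGO:0000002"), tsv)
  d1 <- read_go_dag(obo)
  d2 <- read_go_dag(tsv)
  expect_setequal(d1$terms, d2$terms)
  expect_identical(expand_go_terms(d1, "GO:0000001"),
                   expand_go_terms(d2, "GO:0000001"))
})

test_that("the GO filter admits seed and descendant annotations only", {
  dag <- go_dag(c("GO:0019236", "GO:1111111", "GO:2222222"),
                list("GO:1111111" = "GO:0019236"))
  expanded <- expand_go_terms(dag, "GO:0019236")
  ann <- list("P:A" = "GO:0019236", "P:B" = "GO:1111111", "P:C" = "GO:2222222")
  expect_true(protein_passes_filter("P:A", ann, expanded))
  expect_true(protein_passes_filter("P:B", ann, expanded))   # via descendant
  expect_false(protein_passes_filter("P:C", ann, expanded))
  expect_false(protein_passes_filter("P:UNANNOTATED", ann, expanded))
})

test_that("a forced chain is found iff its intermediates pass the filter", {
  st <- bio_store()
  insert_atomic(st, lapply(c("P:S", "P:a", "P:b", "P:T"), function(id)
    make_object("Protein", id, id)))
  for (e in list(c("P:S", "P:a"), c("P:a", "P:b"), c("P:b", "P:T")))
    link(st, "INTERACTS_WITH", e[1], e[2])
  dag <- go_dag("GO:0000001")
  ann_ok <- list("P:a" = "GO:0000001", "P:b" = "GO:0000001")
  res <- find_signaling_paths(st, "P:S", "P:T", 3, "GO:0000001", dag, ann_ok)
  expect_identical(res$paths, list(c("P:S", "P:a", "P:b", "P:T")))

  ann_blocked <- list("P:a" = "GO:0000001")  # b unannotated
  res2 <- find_signaling_paths(st, "P:S", "P:T", 3, "GO:0000001", dag, ann_blocked)
  expect_length(res2$paths, 0L)

  # a source outside the PPI graph contributes nothing without raising
  insert_atomic(st, list(make_object("Protein", "P:GHOST", "ghost")))
  res3 <- find_signaling_paths(st, c("P:GHOST", "P:S"), "P:T", 3,
                               "GO:0000001", dag, ann_ok)
  expect_identical(res3$paths, res$paths)
  expect_error(find_signaling_paths(st, "P:S", "P:NOPE", 3, "GO:0000001",
                                    dag, ann_ok),
               class = "omics_not_found_error")
})

test_that("path search equals brute-force enumeration on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(101)
  for (i in 1:25) {
    case <- random_ppi_case(n = sample(10:30, 1))
    st <- ppi_case_store(case)
    for (me in c(1L, 3L)) {
      got <- find_signaling_paths(st, case$sources, case$target, me,
                                  case$filter_terms, case$dag, case$annotations)
      expect_identical(path_strings(got), brute_force_paths(case, me),
                       info = sprintf("graph %d, max_edges %d", i, me))
    }
  }
})

test_that("more filter terms or longer paths never remove results", {
  set.seed(202)
  for (i in 1:10) {
    case <- random_ppi_case(n = 20L)
    st <- ppi_case_store(case)
    narrow <- find_signaling_paths(st, case$sources, case$target, 3L,
                                   "GO:0000002", case$dag, case$annotations)
    wide <- find_signaling_paths(st, case$sources, case$target, 3L,
                                 c("GO:0000002", "GO:0000009"),
                                 case$dag, case$annotations)
    expect_true(all(path_strings(narrow) %in% path_strings(wide)))
    short <- find_signaling_paths(st, case$sources, case$target, 2L,
                                  case$filter_terms, case$dag, case$annotations)
    long <- find_signaling_paths(st, case$sources, case$target, 4L,
                                 case$filter_terms, case$dag, case$annotations)
    expect_true(all(path_strings(short) %in% path_strings(long)))
  }
})

test_that("kinase_regulon reproduces the planted cascade and its edge cases", {
  fx <- shared_fixture()
  reg <- kinase_regulon(fx$store, "P:SNF1")
  man <- fx$manifest$planted_regulon
  expect_identical(reg$kinase, man$kinase)
  expect_identical(reg$substrates, man$substrates)
  expect_identical(reg$tfs, man$tfs)
  expect_identical(reg$targets, man$targets)
  expect_identical(reg$reactions, man$reactions)
  # a substrate that is not a TF appears in substrates only
  expect_true("P:GAL83" %in% reg$substrates)
  expect_false("P:GAL83" %in% reg$tfs)
  # repeated calls are identical (sorted, deterministic)
  expect_identical(kinase_regulon(fx$store, "P:SNF1"), reg)

  no_sub <- kinase_regulon(fx$store, "P:STE4")
  expect_length(no_sub$substrates, 0L)
  expect_length(no_sub$tfs, 0L)
  expect_error(kinase_regulon(fx$store, "G:SNF1"), class = "omics_argument_error")
  expect_error(kinase_regulon(fx$store, "P:NOPE"), class = "omics_not_found_error")
})

test_that("follow composes neighbor steps and matches the regulon chain", {
  fx <- shared_fixture()
  st <- fx$store
  expect_identical(follow(st, "G:SNF1", list(
    list(rtype = "TRANSCRIBED_TO"), list(rtype = "TRANSLATED_TO"))),
    "P:SNF1")
  expect_identical(follow(st, character(0), list(list(rtype = "CONTROLS"))),
                   character(0))
  expect_error(follow(st, "G:SNF1", list()), class = "omics_argument_error")
  expect_error(follow(st, "G:SNF1", list(list(rtype = "BOGUS"))),
               class = "omics_schema_error")

  reg <- kinase_regulon(st, "P:SNF1")
  genes_via_follow <- follow(st, "P:SNF1", list(
    list(rtype = "CONTROLS", qualifier_filter = list(control_type = "PHOSPHORYLATION")),
    list(rtype = "CONTROLS", qualifier_filter = list(control_type = "TRANSCRIPTION_REGULATION"))))
  expect_identical(genes_via_follow,
                   sort(unique(unlist(reg$targets, use.names = FALSE))))
})

test_that("excluded participants never appear in returned paths", {
  fx <- shared_fixture()
  res <- find_signaling_paths(fx$store, c("P:STE2", "P:STE2A", "P:STE2B", "P:STE3"),
                              "P:STE12", 3,
                              fx$manifest$go_filter_seeds, fx$dag, fx$annotations)
  nodes <- unique(unlist(res$paths))
  expect_false(any(c("P:STE2", "P:STE2A", "P:STE2B") %in% nodes))
  expect_true(length(res$paths) >= 1L)
})
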