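# broom-style tabular views of result objects, for piping into dplyr/ggplot2
# or flat-file export.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signaling-path result
#'
#' @param x A `signaling_paths` object from [find_signaling_paths()].
#' @param ... Unused.
#' @return One row per path: `source`, `target`, `n_edges`, `path` (nodes
#'   joined with `" -- "`).
#' @method tidy signaling_paths
#' @export
tidy.signaling_paths <- function(x, ...) {
  tibble::tibble(
    source = vapply(x$paths, `[[`, character(1), 1L),
    target = rep(x$target, length(x$paths)),
    n_edges = lengths(x$paths) - 1L,
    path = vapply(x$paths, paste, character(1), collapse = " -- "))
}

#' @rdname tidy.signaling_paths
#' @method glance signaling_paths
#' @export
glance.signaling_paths <- function(x, ...) {
  tibble::tibble(n_paths = length(x$paths), n_sources = length(x$sources),
                 target = x$target, max_edges = x$max_edges,
                 n_filter_terms = length(x$filter_terms),
                 n_expanded_terms = length(x$expanded_terms))
}

#' Tidy a kinase-regulon result
#'
#' @param x A `regulon` object from [kinase_regulon()].
#' @param ... Unused.
#' @return One row per kinase-TF-gene-reaction tuple (genes without
#'   reactions and substrates that are not TFs yield rows with `NA` in the
#'   unreached columns).
#' @method tidy regulon
#' @export
tidy.regulon <- function(x, ...) {
  rows <- list()
  for (s in x$substrates) {
    if (!s %in% x$tfs) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kinase = x$kinase, substrate = s, tf = NA_character_,
        gene = NA_character_, reaction = NA_character_)
      next
    }
    for (g in x$targets[[s]]) {
      rxns <- x$reactions[[g]] %||% NA_character_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kinase = x$kinase, substrate = s, tf = s, gene = g, reaction = rxns)
    }
  }
  if (!length(rows))
    return(tibble::tibble(kinase = character(0), substrate = character(0),
                          tf = character(0), gene = character(0),
                          reaction = character(0)))
  do.call(rbind, rows)
}

#' @rdname tidy.regulon
#' @method glance regulon
#' @export
glance.regulon <- function(x, ...) {
  tibble::tibble(kinase = x$kinase, n_substrates = length(x$substrates),
                 n_tfs = length(x$tfs),
                 n_target_genes = length(unique(unlist(x$targets))),
                 n_reactions = length(unique(unlist(x$reactions))))
}

#' Tidy store statistics
#'
#' @param x A `bio_store`.
#' @param ... Unused.
#' @return One row per concrete class tag and relation type with its count.
#' @method tidy bio_store
#' @export
tidy.bio_store <- function(x, ...) {
  s <- store_stats(x)
  rbind(tibble::tibble(collection = "objects", type = names(s$per_tag),
                       n = unname(s$per_tag)),
        tibble::tibble(collection = "relations", type = names(s$per_rtype),
                       n = unname(s$per_rtype)))
}
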