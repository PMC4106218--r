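# Two-collection document store: biological objects in one collection,
# relations in the other, with indexes, atomic bundle inserts, referential
# integrity and a durable JSON-lines on-disk format.
#
# A store is an environment mutated by reference (storr-style); all reads are
# answered either from indexes or by full scan, and the two must always agree.

#' Relation types of the relation collection
#'
#' @return Character vector of the seven relation types.
#' @export
relation_types <- function() {
  c("LOCATED_ON", "TRANSCRIBED_TO", "TRANSLATED_TO", "INTERACTS_WITH",
    "CONTROLS", "HAS_PARTICIPANT", "COMPONENT_OF")
}

# Endpoint-tag compatibility per relation type. Targets may name abstract
# classes; compatibility is checked through the subclass relation.
.rel_compat <- list(
  LOCATED_ON      = list(src = "DNARegion", tgt = "DNA",            directed = TRUE),
  TRANSCRIBED_TO  = list(src = "DNARegion", tgt = "RNA",            directed = TRUE),
  TRANSLATED_TO   = list(src = "RNA",       tgt = "Protein",        directed = TRUE),
  INTERACTS_WITH  = list(src = "Protein",   tgt = "Protein",        directed = FALSE),
  CONTROLS        = list(src = "Protein",
                         tgt = c("Protein", "DNARegion", "Conversion"), directed = TRUE),
  HAS_PARTICIPANT = list(src = "Conversion", tgt = "PhysicalEntity", directed = TRUE),
  COMPONENT_OF    = list(src = "PhysicalEntity", tgt = "Complex",    directed = TRUE)
)

#' Endpoint compatibility table for relation types
#'
#' @return A tibble with columns `rtype`, `source_tag`, `target_tags`,
#'   `directed`. Abstract tags admit all their concrete descendants.
#' @export
relation_compatibility <- function() {
  tibble::tibble(
    rtype = names(.rel_compat),
    source_tag = vapply(.rel_compat, function(x) x$src, character(1)),
    target_tags = vapply(.rel_compat, function(x) paste(x$tgt, collapse = "|"), character(1)),
    directed = vapply(.rel_compat, function(x) x$directed, logical(1))
  )
}

#' Create an empty document store
#'
#' The store keeps two disjoint collections — biological objects and relation
#' records — plus indexes over id, name, cross-reference and class tag
#' (objects) and over endpoints and type (relations). It is an environment:
#' all store operations mutate it in place.
#'
#' @return A `bio_store`.
#' @export
bio_store <- function() {
  st <- new.env(parent = emptyenv())
  st$objects   <- new.env(parent = emptyenv())
  st$relations <- new.env(parent = emptyenv())
  st$idx <- list(
    name  = new.env(parent = emptyenv()),  # name -> ids
    xref  = new.env(parent = emptyenv()),  # "db:acc" -> ids
    tag   = new.env(parent = emptyenv()),  # concrete tag -> ids
    rsrc  = new.env(parent = emptyenv()),  # source_id -> rids
    rtgt  = new.env(parent = emptyenv()),  # target_id -> rids
    rtype = new.env(parent = emptyenv()),  # rtype -> rids
    rkey  = new.env(parent = emptyenv())   # canonical relation key -> rid
  )
  st$rid_counter <- 0L
  class(st) <- "bio_store"
  st
}

#' @export
print.bio_store <- function(x, ...) {
  s <- store_stats(x)
  cat(sprintf("<bio_store> %d objects, %d relations\n", s$objects, s$relations))
  invisible(x)
}

idx_add <- function(env, key, value) {
  env[[key]] <- unique(c(env[[key]], value))
}
idx_drop <- function(env, key, value) {
  v <- setdiff(env[[key]], value)
  if (length(v)) env[[key]] <- v else if (!is.null(env[[key]])) rm(list = key, envir = env)
}

index_object <- function(store, rec) {
  for (nm in rec$names) idx_add(store$idx$name, nm, rec$id)
  for (xr in rec$xrefs) idx_add(store$idx$xref, xr, rec$id)
  idx_add(store$idx$tag, rec$tag, rec$id)
}
unindex_object <- function(store, rec) {
  for (nm in rec$names) idx_drop(store$idx$name, nm, rec$id)
  for (xr in rec$xrefs) idx_drop(store$idx$xref, xr, rec$id)
  idx_drop(store$idx$tag, rec$tag, rec$id)
}
index_relation <- function(store, rel) {
  idx_add(store$idx$rsrc, rel$source_id, rel$rid)
  idx_add(store$idx$rtgt, rel$target_id, rel$rid)
  idx_add(store$idx$rtype, rel$rtype, rel$rid)
  store$idx$rkey[[relation_key(rel)]] <- rel$rid
}
unindex_relation <- function(store, rel) {
  idx_drop(store$idx$rsrc, rel$source_id, rel$rid)
  idx_drop(store$idx$rtgt, rel$target_id, rel$rid)
  idx_drop(store$idx$rtype, rel$rtype, rel$rid)
  rm(list = relation_key(rel), envir = store$idx$rkey)
}

canonical_qualifiers <- function(qualifiers) {
  if (is.null(qualifiers) || !length(qualifiers)) return(list())
  if (!is.list(qualifiers) || is.null(names(qualifiers)))
    os_argument_error("qualifiers must be a named list")
  qualifiers[order(names(qualifiers))]
}

relation_key <- function(rel) {
  q <- if (length(rel$qualifiers))
    jsonlite::toJSON(rel$qualifiers, auto_unbox = TRUE) else "{}"
  paste(rel$rtype, rel$source_id, rel$target_id, q, sep = "\r")
}

# Build and check a relation against a lookup function for endpoint records;
# returns the canonicalized relation (without rid) or raises.
check_relation <- function(rtype, source_id, target_id, qualifiers, lookup) {
  if (!is_string(rtype) || !rtype %in% relation_types())
    os_schema_error(sprintf("unknown relation type '%s'", as.character(rtype)[1]))
  if (!is_nonempty_string(source_id) || !is_nonempty_string(target_id))
    os_argument_error("relation endpoints must be non-empty id strings")
  compat <- .rel_compat[[rtype]]
  if (!compat$directed && source_id > target_id) {
    tmp <- source_id; source_id <- target_id; target_id <- tmp
  }
  src <- lookup(source_id)
  if (is.null(src))
    os_integrity_error(sprintf("relation %s references missing object '%s'", rtype, source_id))
  tgt <- lookup(target_id)
  if (is.null(tgt))
    os_integrity_error(sprintf("relation %s references missing object '%s'", rtype, target_id))
  if (!is_subclass(src$tag, compat$src) ||
      !any(vapply(compat$tgt, function(t) is_subclass(tgt$tag, t), logical(1)))) {
    # undirected: accept either orientation of the tag pair
    swapped <- !compat$directed && is_subclass(tgt$tag, compat$src) &&
      any(vapply(compat$tgt, function(t) is_subclass(src$tag, t), logical(1)))
    if (!swapped)
      os_schema_error(sprintf(
        "relation %s not permitted between %s and %s (requires %s -> %s)",
        rtype, src$tag, tgt$tag, compat$src, paste(compat$tgt, collapse = "|")))
  }
  structure(list(rid = NA_character_, rtype = rtype, source_id = source_id,
                 target_id = target_id, directed = compat$directed,
                 qualifiers = canonical_qualifiers(qualifiers)),
            class = "bio_relation")
}

next_rid <- function(store) {
  store$rid_counter <- store$rid_counter + 1L
  sprintf("REL:%06d", store$rid_counter)
}

commit_relation <- function(store, rel) {
  rel$rid <- next_rid(store)
  store$relations[[rel$rid]] <- rel
  index_relation(store, rel)
  rel
}

#' Relation specification helper
#'
#' Builds the plain description of a relation for [insert_atomic()].
#'
#' @param rtype One of [relation_types()].
#' @param source_id,target_id Object ids.
#' @param qualifiers Named list of edge qualifiers (e.g. `role`,
#'   `control_type`).
#' @return A list understood by [insert_atomic()].
#' @export
rel_spec <- function(rtype, source_id, target_id, qualifiers = list()) {
  list(rtype = rtype, source_id = source_id, target_id = target_id,
       qualifiers = qualifiers)
}

#' Insert a bundle of objects and relations atomically
#'
#' Either every object and relation in the bundle is inserted — each object
#' validated, each relation endpoint checked against pre-existing plus staged
#' objects — or none is: the first violation aborts the whole bundle and the
#' store is left exactly as it was.
#'
#' @param store A `bio_store`.
#' @param objects List of `bio_object` records.
#' @param relations List of relation specs (see [rel_spec()]).
#' @return Commit report: list with per-collection insert counts `objects`
#'   and `relations`.
#' @export
insert_atomic <- function(store, objects = list(), relations = list()) {
  stopifnot(inherits(store, "bio_store"))
  staged <- new.env(parent = emptyenv())
  for (rec in objects) {
    if (!inherits(rec, "bio_object"))
      os_argument_error("bundle objects must be bio_object records")
    rep <- validate(rec)
    if (!rep$ok)
      os_validation_error(sprintf("invalid object '%s': %s",
                                  as.character(rec$id)[1], rep$violations$message[1]))
    if (!is.null(store$objects[[rec$id]]) || !is.null(staged[[rec$id]]))
      os_duplicate_error(sprintf("duplicate object id '%s'", rec$id))
    staged[[rec$id]] <- rec
  }
  lookup <- function(id) staged[[id]] %||% store$objects[[id]]
  checked <- vector("list", length(relations))
  seen_keys <- character(0)
  for (i in seq_along(relations)) {
    sp <- relations[[i]]
    rel <- check_relation(sp$rtype, sp$source_id, sp$target_id,
                          sp$qualifiers %||% list(), lookup)
    key <- relation_key(rel)
    if (!is.null(store$idx$rkey[[key]]) || key %in% seen_keys)
      os_duplicate_error(sprintf("duplicate relation %s(%s -> %s)",
                                 rel$rtype, rel$source_id, rel$target_id))
    seen_keys <- c(seen_keys, key)
    checked[[i]] <- rel
  }
  # all checks passed: commit
  for (id in ls(staged)) {
    store$objects[[id]] <- staged[[id]]
    index_object(store, staged[[id]])
  }
  for (rel in checked) commit_relation(store, rel)
  list(objects = length(objects), relations = length(relations))
}

#' Fetch an object by id
#'
#' @param store A `bio_store`.
#' @param id Object id.
#' @return The `bio_object`, or `NULL` if no object has that id (not-found is
#'   a distinct signal, not an error).
#' @export
get_by_id <- function(store, id) {
  stopifnot(inherits(store, "bio_store"))
  if (!is_nonempty_string(id)) return(NULL)
  store$objects[[id]]
}

#' Query objects by class, name and/or cross-reference
#'
#' Criteria combine conjunctively. Abstract tags match all their concrete
#' descendants (querying `PhysicalEntity` returns proteins, genes, ...).
#' Name and xref matching is exact and case-sensitive unless
#' `case_insensitive = TRUE`. Results are ordered by id.
#'
#' @param store A `bio_store`.
#' @param tag Optional class tag, concrete or abstract.
#' @param name Optional name (matched against all names of a record).
#' @param xref Optional cross-reference `"database:accession"`.
#' @param case_insensitive Match `name`/`xref` ignoring case.
#' @param use_index Answer from indexes (default) or by exhaustive scan; the
#'   two are guaranteed to agree.
#' @return List of `bio_object` records sorted by id.
#' @export
find_objects <- function(store, tag = NULL, name = NULL, xref = NULL,
                         case_insensitive = FALSE, use_index = TRUE) {
  stopifnot(inherits(store, "bio_store"))
  if (is.null(tag) && is.null(name) && is.null(xref))
    os_argument_error("find_objects needs at least one criterion")
  if (!is.null(tag) && (!is_string(tag) || !tag %in% all_tags()))
    os_argument_error(sprintf("unknown class tag '%s'", as.character(tag)[1]))

  if (use_index) {
    sets <- list()
    if (!is.null(tag)) {
      ids <- unlist(lapply(tag_descendants(tag), function(t) store$idx$tag[[t]]),
                    use.names = FALSE)
      sets <- c(sets, list(ids %||% character(0)))
    }
    if (!is.null(name)) {
      ids <- if (case_insensitive) {
        keys <- ls(store$idx$name)
        unlist(lapply(keys[tolower(keys) == tolower(name)],
                      function(k) store$idx$name[[k]]), use.names = FALSE)
      } else store$idx$name[[name]]
      sets <- c(sets, list(ids %||% character(0)))
    }
    if (!is.null(xref)) {
      ids <- if (case_insensitive) {
        keys <- ls(store$idx$xref)
        unlist(lapply(keys[tolower(keys) == tolower(xref)],
                      function(k) store$idx$xref[[k]]), use.names = FALSE)
      } else store$idx$xref[[xref]]
      sets <- c(sets, list(ids %||% character(0)))
    }
    ids <- Reduce(intersect, sets)
  } else {
    match_str <- function(haystack, needle) {
      if (case_insensitive) tolower(needle) %in% tolower(haystack)
      else needle %in% haystack
    }
    want_tags <- if (!is.null(tag)) tag_descendants(tag) else NULL
    ids <- Filter(function(id) {
      rec <- store$objects[[id]]
      if (!is.null(want_tags) && !rec$tag %in% want_tags) return(FALSE)
      if (!is.null(name) && !match_str(rec$names, name)) return(FALSE)
      if (!is.null(xref) && !match_str(rec$xrefs, xref)) return(FALSE)
      TRUE
    }, ls(store$objects))
  }
  lapply(sort(unique(ids)), function(id) store$objects[[id]])
}

#' Create a single relation between two stored objects
#'
#' Both endpoints must already exist and the relation type must be compatible
#' with their class tags. `INTERACTS_WITH` is undirected and canonicalized
#' with its endpoints in lexicographic order. An identical relation (same
#' type, canonical endpoints and qualifiers) is rejected as a duplicate.
#'
#' @inheritParams rel_spec
#' @param store A `bio_store`.
#' @return The stored `bio_relation` (with its assigned `rid`).
#' @export
link <- function(store, rtype, source_id, target_id, qualifiers = list()) {
  stopifnot(inherits(store, "bio_store"))
  rel <- check_relation(rtype, source_id, target_id, qualifiers,
                        function(id) store$objects[[id]])
  if (!is.null(store$idx$rkey[[relation_key(rel)]]))
    os_duplicate_error(sprintf("duplicate relation %s(%s -> %s)",
                               rel$rtype, rel$source_id, rel$target_id))
  commit_relation(store, rel)
}

#' Update a stored object atomically
#'
#' Applies the given changes to a copy of the record, validates the result,
#' and only then replaces the stored record (and its index entries) in one
#' step. Writes are serialized: the store always reflects a sequence of whole
#' updates, so of two conflicting updates the later one wins. Relations are
#' untouched.
#'
#' @param store A `bio_store`.
#' @param id Id of an existing object.
#' @param changes Named list; keys may be `names`, `function`, `xrefs`,
#'   `source`, or any attribute permitted for the record's class.
#' @return The updated `bio_object`.
#' @export
update_object <- function(store, id, changes) {
  stopifnot(inherits(store, "bio_store"))
  old <- store$objects[[id]]
  if (is.null(old)) os_not_found_error(sprintf("no object with id '%s'", id))
  if (!is.list(changes) || (length(changes) && is.null(names(changes))))
    os_argument_error("changes must be a named list")
  rec <- old
  for (key in names(changes)) {
    val <- changes[[key]]
    if (key == "names") rec$names <- as.character(val)
    else if (key == "function") rec$func <- val
    else if (key == "xrefs") rec$xrefs <- as.character(val)
    else if (key == "source") rec$source <- val
    else if (key %in% permitted_keys(rec$tag)) rec$attributes[[key]] <- val
    else os_schema_error(sprintf("'%s' is not an updatable field of %s", key, rec$tag))
  }
  rep <- validate(rec)
  if (!rep$ok)
    os_validation_error(sprintf("update would invalidate '%s': %s",
                                id, rep$violations$message[1]))
  unindex_object(store, old)
  store$objects[[id]] <- rec
  index_object(store, rec)
  rec
}

#' Delete an object under a relation policy
#'
#' `REFUSE_IF_LINKED` refuses (with the number of blocking relations) if any
#' relation touches the object; `CASCADE` removes the object together with
#' every relation touching it, so no dangling relation can remain.
#'
#' @param store A `bio_store`.
#' @param id Id of an existing object.
#' @param policy `"REFUSE_IF_LINKED"` (default) or `"CASCADE"`.
#' @return Deletion report: list with `id` and `relations_removed`.
#' @export
delete_object <- function(store, id, policy = c("REFUSE_IF_LINKED", "CASCADE")) {
  stopifnot(inherits(store, "bio_store"))
  policy <- match.arg(policy)
  rec <- store$objects[[id]]
  if (is.null(rec)) os_not_found_error(sprintf("no object with id '%s'", id))
  touching <- unique(c(store$idx$rsrc[[id]], store$idx$rtgt[[id]]))
  if (policy == "REFUSE_IF_LINKED" && length(touching))
    os_integrity_error(sprintf(
      "cannot delete '%s': %d relation(s) reference it", id, length(touching)),
      blocking = length(touching))
  for (rid in touching) {
    rel <- store$relations[[rid]]
    unindex_relation(store, rel)
    rm(list = rid, envir = store$relations)
  }
  unindex_object(store, rec)
  rm(list = id, envir = store$objects)
  list(id = id, relations_removed = length(touching))
}

#' Relations and neighbor objects of one object
#'
#' Directed relation types respect `direction` (`OUT`: the object is the
#' source; `IN`: the target; `ANY`: either). Undirected `INTERACTS_WITH`
#' edges match from either endpoint regardless of `direction`. An optional
#' qualifier filter keeps only relations whose qualifiers contain every
#' given key/value pair.
#'
#' @param store A `bio_store`.
#' @param id Id of an existing object.
#' @param rtype Optional relation type to restrict to.
#' @param direction `"OUT"`, `"IN"` or `"ANY"`.
#' @param qualifier_filter Optional named list.
#' @return List of `list(relation = , object = )` pairs ordered by the
#'   neighbor object's id.
#' @export
neighbors <- function(store, id, rtype = NULL, direction = c("ANY", "OUT", "IN"),
                      qualifier_filter = NULL) {
  stopifnot(inherits(store, "bio_store"))
  direction <- match.arg(direction)
  if (is.null(store$objects[[id]]))
    os_not_found_error(sprintf("no object with id '%s'", id))
  if (!is.null(rtype) && !rtype %in% relation_types())
    os_schema_error(sprintf("unknown relation type '%s'", as.character(rtype)[1]))
  rids <- unique(c(store$idx$rsrc[[id]], store$idx$rtgt[[id]]))
  out <- list()
  for (rid in rids) {
    rel <- store$relations[[rid]]
    if (!is.null(rtype) && rel$rtype != rtype) next
    if (rel$directed) {
      if (direction == "OUT" && rel$source_id != id) next
      if (direction == "IN" && rel$target_id != id) next
    }
    if (!is.null(qualifier_filter)) {
      hit <- all(vapply(names(qualifier_filter), function(k)
        identical(rel$qualifiers[[k]], qualifier_filter[[k]]), logical(1)))
      if (!hit) next
    }
    other <- if (rel$source_id == id) rel$target_id else rel$source_id
    out[[length(out) + 1L]] <- list(relation = rel, object = store$objects[[other]])
  }
  ord <- order(vapply(out, function(x) x$object$id, character(1)),
               vapply(out, function(x) x$relation$rid, character(1)))
  out[ord]
}

#' Collection and per-class counts of a store
#'
#' @param store A `bio_store`.
#' @return List with `objects`, `relations`, `per_tag` (named integer vector
#'   over the ten concrete tags) and `per_rtype` (over the relation types).
#' @export
store_stats <- function(store) {
  stopifnot(inherits(store, "bio_store"))
  per_tag <- vapply(concrete_tags(), function(t)
    length(store$idx$tag[[t]] %||% character(0)), integer(1))
  per_rtype <- vapply(relation_types(), function(t)
    length(store$idx$rtype[[t]] %||% character(0)), integer(1))
  list(objects = length(ls(store$objects)),
       relations = length(ls(store$relations)),
       per_tag = per_tag, per_rtype = per_rtype)
}

# --- serialization and durability -------------------------------------------

relation_document <- function(rel) {
  list(rid = rel$rid, rtype = rel$rtype, source_id = rel$source_id,
       target_id = rel$target_id, directed = rel$directed,
       qualifiers = rel$qualifiers)
}

relation_from_document <- function(doc) {
  structure(list(rid = doc$rid, rtype = doc$rtype, source_id = doc$source_id,
                 target_id = doc$target_id, directed = isTRUE(doc$directed),
                 qualifiers = canonical_qualifiers(
                   lapply(doc$qualifiers %||% list(), function(v) v))),
            class = "bio_relation")
}

doc_json <- function(doc) {
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Serialize a store to a canonical text form
#'
#' Deterministic: records sorted by id, relations by rid, fixed key order.
#' Two stores with identical content serialize to identical bytes, which is
#' how transaction atomicity is audited.
#'
#' @param store A `bio_store`.
#' @return A single character string (header line plus one JSON line per
#'   document).
#' @export
store_serialize <- function(store) {
  stopifnot(inherits(store, "bio_store"))
  s <- store_stats(store)
  header <- doc_json(list(format = "omicstore-jsonl", version = 1L,
                          objects = s$objects, relations = s$relations))
  obj_lines <- vapply(sort(ls(store$objects)), function(id)
    doc_json(to_document(store$objects[[id]])), character(1))
  rel_lines <- vapply(sort(ls(store$relations)), function(rid)
    doc_json(relation_document(store$relations[[rid]])), character(1))
  paste(c(header, "## objects", obj_lines, "## relations", rel_lines),
        collapse = "\n")
}

#' Save a store to disk
#'
#' Writes a directory holding `manifest.json` (format header and counts) and
#' two JSON-lines collections, `objects.jsonl` and `relations.jsonl`. A
#' reopened store answers every query identically to the saved one.
#'
#' @param store A `bio_store`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
store_save <- function(store, path) {
  stopifnot(inherits(store, "bio_store"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  s <- store_stats(store)
  writeLines(doc_json(list(format = "omicstore-jsonl", version = 1L,
                           objects = s$objects, relations = s$relations)),
             file.path(path, "manifest.json"))
  writeLines(vapply(sort(ls(store$objects)), function(id)
    doc_json(to_document(store$objects[[id]])), character(1)),
    file.path(path, "objects.jsonl"))
  writeLines(vapply(sort(ls(store$relations)), function(rid)
    doc_json(relation_document(store$relations[[rid]])), character(1)),
    file.path(path, "relations.jsonl"))
  invisible(path)
}

#' Open a store saved with [store_save()]
#'
#' @param path Directory written by [store_save()].
#' @return A `bio_store`.
#' @export
store_open <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!dir.exists(path) || !file.exists(man_path))
    os_storage_error(sprintf("'%s' is not a saved store (missing manifest.json)", path))
  man <- tryCatch(jsonlite::fromJSON(man_path, simplifyVector = TRUE),
                  error = function(e)
                    os_storage_error(sprintf("corrupt manifest in '%s': %s",
                                             path, conditionMessage(e))))
  if (!identical(man$format, "omicstore-jsonl"))
    os_storage_error(sprintf("'%s': unrecognized store format", path))
  for (f in c("objects.jsonl", "relations.jsonl"))
    if (!file.exists(file.path(path, f)))
      os_storage_error(sprintf("'%s' is missing collection file %s", path, f))
  st <- bio_store()
  for (line in readLines(file.path(path, "objects.jsonl"))) {
    if (!nzchar(line)) next
    rec <- from_document(jsonlite::fromJSON(line, simplifyVector = FALSE))
    st$objects[[rec$id]] <- rec
    index_object(st, rec)
  }
  max_rid <- 0L
  for (line in readLines(file.path(path, "relations.jsonl"))) {
    if (!nzchar(line)) next
    rel <- relation_from_document(jsonlite::fromJSON(line, simplifyVector = FALSE))
    if (is.null(st$objects[[rel$source_id]]) || is.null(st$objects[[rel$target_id]]))
      os_storage_error(sprintf("relation %s references a missing object", rel$rid))
    st$relations[[rel$rid]] <- rel
    index_relation(st, rel)
    n <- suppressWarnings(as.integer(sub("^REL:", "", rel$rid)))
    if (!is.na(n)) max_rid <- max(max_rid, n)
  }
  st$rid_counter <- max_rid
  if (length(ls(st$objects)) != man$objects || length(ls(st$relations)) != man$relations)
    os_storage_error(sprintf(
      "'%s': collection counts disagree with manifest (corrupt save?)", path))
  st
}
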