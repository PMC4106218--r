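# BioPAX-derived object model: class hierarchy, per-class attribute schemas,
# validation, and (de)serialization to plain documents.

# Class tree: BioObject at the root, PhysicalEntity and Interaction the only
# depth-1 nodes, ten concrete leaf classes. Abstract tags are legal in queries
# only, never as a stored record's tag.
.tag_parent <- c(
  PhysicalEntity       = "BioObject",
  Interaction          = "BioObject",
  SmallMolecule        = "PhysicalEntity",
  DNA                  = "PhysicalEntity",
  DNARegion            = "PhysicalEntity",
  RNA                  = "PhysicalEntity",
  Protein              = "PhysicalEntity",
  Complex              = "PhysicalEntity",
  Conversion           = "Interaction",
  MolecularInteraction = "Interaction",
  GeneticInteraction   = "Interaction",
  Control              = "Interaction"
)

#' Concrete class tags of the object model
#'
#' The ten storable classes: six physical-entity classes (small molecules, DNA
#' molecules, genes as DNA regions, RNA, proteins, complexes) and four
#' interaction classes (conversions, molecular and genetic interactions,
#' control events).
#'
#' @return Character vector of the ten concrete tags.
#' @export
concrete_tags <- function() {
  c("SmallMolecule", "DNA", "DNARegion", "RNA", "Protein", "Complex",
    "Conversion", "MolecularInteraction", "GeneticInteraction", "Control")
}

#' Abstract class tags (query-only)
#'
#' @return Character vector: `BioObject`, `PhysicalEntity`, `Interaction`.
#' @export
abstract_tags <- function() c("BioObject", "PhysicalEntity", "Interaction")

all_tags <- function() c(abstract_tags(), concrete_tags())

#' Test the subclass relation between two class tags
#'
#' Reflexive and transitive over the class tree: every tag is a subclass of
#' itself and of `BioObject`.
#'
#' @param tag,ancestor Class tags (concrete or abstract).
#' @return `TRUE` if `tag` is `ancestor` or a descendant of it.
#' @export
is_subclass <- function(tag, ancestor) {
  if (!tag %in% all_tags()) os_argument_error(sprintf("unknown class tag '%s'", tag))
  if (!ancestor %in% all_tags()) os_argument_error(sprintf("unknown class tag '%s'", ancestor))
  cur <- tag
  repeat {
    if (cur == ancestor) return(TRUE)
    if (cur == "BioObject") return(FALSE)
    cur <- unname(.tag_parent[[cur]])
  }
}

#' Concrete descendants of a class tag
#'
#' Used by queries: searching for `PhysicalEntity` matches proteins, genes,
#' RNAs and the other physical classes.
#'
#' @param tag A concrete or abstract class tag.
#' @return Character vector of concrete tags at or below `tag`.
#' @export
tag_descendants <- function(tag) {
  ct <- concrete_tags()
  ct[vapply(ct, is_subclass, logical(1), ancestor = tag)]
}

# Allowed control_type values for Control records.
control_types <- function() {
  c("TRANSCRIPTION_REGULATION", "PHOSPHORYLATION", "DEPHOSPHORYLATION", "CATALYSIS")
}

# --- per-class attribute schema ---------------------------------------------
# Each entry: required / optional key sets plus a per-key checker returning
# NULL (ok) or a message. Cross-field rules (start <= end) live in validate().

.chk_string  <- function(v) if (!is_nonempty_string(v)) "must be a non-empty string"
.chk_posint  <- function(v) if (!is_count(v)) "must be a positive integer"
.chk_strand  <- function(v) if (!is_string(v) || !v %in% c("+", "-")) "must be '+' or '-'"
.chk_ids     <- function(v) {
  if (!is.character(v) || length(v) < 1L || anyNA(v) || any(!nzchar(v)))
    "must be a character vector of one or more non-empty ids"
}
.chk_pair    <- function(v) {
  if (!is.character(v) || length(v) != 2L || anyNA(v) || any(!nzchar(v)))
    "must be exactly two participant ids"
}
.chk_control <- function(v) {
  if (!is_string(v) || !v %in% control_types())
    paste("must be one of", paste(control_types(), collapse = ", "))
}

.class_schema <- list(
  SmallMolecule = list(required = character(0), optional = "formula",
                       check = list(formula = .chk_string)),
  DNA           = list(required = "length", optional = "sequence",
                       check = list(length = .chk_posint, sequence = .chk_string)),
  DNARegion     = list(required = c("chromosome", "start", "end", "strand"),
                       optional = character(0),
                       check = list(chromosome = .chk_string, start = .chk_posint,
                                    end = .chk_posint, strand = .chk_strand)),
  RNA           = list(required = character(0), optional = "encoded_by",
                       check = list(encoded_by = .chk_string)),
  Protein       = list(required = character(0), optional = "sequence",
                       check = list(sequence = .chk_string)),
  Complex       = list(required = "components", optional = character(0),
                       check = list(components = .chk_ids)),
  Conversion    = list(required = c("substrates", "products"), optional = character(0),
                       check = list(substrates = .chk_ids, products = .chk_ids)),
  MolecularInteraction = list(required = "participants", optional = character(0),
                              check = list(participants = .chk_pair)),
  GeneticInteraction   = list(required = "participants", optional = character(0),
                              check = list(participants = .chk_pair)),
  Control       = list(required = "control_type", optional = character(0),
                       check = list(control_type = .chk_control))
)

#' Attribute schema of the ten concrete classes
#'
#' One row per (class, attribute) pair. Genes (`DNARegion`) use 1-based
#' inclusive coordinates, GFF3 convention, with strand `+`/`-`; `Control`
#' records carry a `control_type` out of transcription regulation,
#' phosphorylation, dephosphorylation and catalysis.
#'
#' @return A tibble with columns `tag`, `attribute`, `required`.
#' @export
class_schema <- function() {
  rows <- lapply(names(.class_schema), function(tag) {
    s <- .class_schema[[tag]]
    keys <- c(s$required, s$optional)
    if (!length(keys)) return(NULL)
    tibble::tibble(tag = tag, attribute = keys,
                   required = keys %in% s$required)
  })
  do.call(rbind, rows)
}

permitted_keys <- function(tag) {
  s <- .class_schema[[tag]]
  c(s$required, s$optional)
}

# --- record construction -----------------------------------------------------

new_bio_object <- function(id, tag, names, func = NULL, xrefs = character(0),
                           source = NULL, attributes = list()) {
  structure(
    list(id = id, tag = tag, names = names, func = func,
         xrefs = xrefs, source = source, attributes = attributes),
    class = "bio_object"
  )
}

#' Create a biological object record
#'
#' Builds an in-memory record of one of the ten concrete classes. The record
#' is populated but not yet validated or stored; required attributes may still
#' be missing (see [validate()]). Attribute values supplied here go through
#' the same per-key checks as [set_attribute()].
#'
#' @param tag Concrete class tag (see [concrete_tags()]). Abstract tags are
#'   rejected.
#' @param id Store-unique identifier string.
#' @param primary_name The record's primary name (first element of `names`).
#' @param attributes Named list of class-specific attributes.
#' @param source Optional primary data-source name.
#' @return A `bio_object` record.
#' @examples
#' make_object("Protein", "P:STE12", "Ste12")
#' make_object("DNARegion", "G:SNF1", "SNF1",
#'             list(chromosome = "C:IV", start = 1, end = 1902, strand = "+"))
#' @export
make_object <- function(tag, id, primary_name, attributes = list(), source = NULL) {
  if (!is_string(tag) || !tag %in% all_tags())
    os_argument_error(sprintf("unknown class tag '%s'", as.character(tag)[1]))
  if (tag %in% abstract_tags())
    os_abstract_error(sprintf(
      "'%s' is an abstract class; records must use a concrete tag", tag))
  if (!is_nonempty_string(id)) os_argument_error("object id must be a non-empty string")
  if (!is_nonempty_string(primary_name))
    os_argument_error("primary name must be a non-empty string")
  if (!is.list(attributes) || (length(attributes) && is.null(names(attributes))))
    os_argument_error("attributes must be a named list")
  rec <- new_bio_object(id = id, tag = tag, names = primary_name, source = source)
  for (key in names(attributes)) rec <- set_attribute(rec, key, attributes[[key]])
  rec
}

#' Append a name to a record
#'
#' Names are case-sensitive; appending a name already present is a no-op and
#' the primary (first) name never changes.
#'
#' @param record A `bio_object`.
#' @param name Non-empty string.
#' @return The updated record.
#' @export
add_name <- function(record, name) {
  stopifnot(inherits(record, "bio_object"))
  if (!is_nonempty_string(name)) os_argument_error("name must be a non-empty string")
  if (!name %in% record$names) record$names <- c(record$names, name)
  record
}

#' Add a cross-reference to a record
#'
#' @param record A `bio_object`.
#' @param database Short database name, e.g. `"UniProt"`.
#' @param accession Identifier within that database.
#' @return The updated record; the xref is rendered `"database:accession"`.
#' @export
add_xref <- function(record, database, accession) {
  stopifnot(inherits(record, "bio_object"))
  if (!is_nonempty_string(database) || !is_nonempty_string(accession))
    os_argument_error("xref database and accession must be non-empty strings")
  xr <- paste0(database, ":", accession)
  if (!xr %in% record$xrefs) record$xrefs <- c(record$xrefs, xr)
  record
}

#' Set a class-specific attribute on a record
#'
#' The key must be permitted for the record's class (schema error otherwise)
#' and the value must satisfy the per-key type rule (validation error
#' otherwise), e.g. a DNA `length` must be a positive integer.
#'
#' @param record A `bio_object`.
#' @param key Attribute name.
#' @param value Attribute value.
#' @return The updated record.
#' @export
set_attribute <- function(record, key, value) {
  stopifnot(inherits(record, "bio_object"))
  if (!is_nonempty_string(key)) os_argument_error("attribute key must be a non-empty string")
  ok_keys <- permitted_keys(record$tag)
  if (!key %in% ok_keys)
    os_schema_error(sprintf("'%s' is not a permitted attribute for class %s (allowed: %s)",
                            key, record$tag,
                            if (length(ok_keys)) paste(ok_keys, collapse = ", ") else "none"))
  msg <- .class_schema[[record$tag]]$check[[key]](value)
  if (!is.null(msg))
    os_validation_error(sprintf("attribute '%s' of %s %s", key, record$tag, msg))
  if (is.numeric(value) && length(value) == 1L && !is.na(value) && value == trunc(value))
    value <- as.integer(value)
  record$attributes[[key]] <- value
  record
}

#' Set the free-text function description of a record
#' @param record A `bio_object`.
#' @param text Non-empty string.
#' @return The updated record.
#' @export
set_function <- function(record, text) {
  stopifnot(inherits(record, "bio_object"))
  if (!is_nonempty_string(text)) os_argument_error("function text must be a non-empty string")
  record$func <- text
  record
}

# --- validation --------------------------------------------------------------

violation <- function(field, rule, message) {
  tibble::tibble(field = field, rule = rule, message = message)
}

#' Validate a record against its class schema
#'
#' Total and pure: reports every problem (missing required attributes, type
#' violations, coordinate order, unknown tag) without raising or mutating.
#'
#' @param record A `bio_object`.
#' @return A list with `ok` (logical) and `violations` (tibble with columns
#'   `field`, `rule`, `message`); `ok` is `TRUE` iff `violations` has no rows.
#' @export
validate <- function(record) {
  v <- violation(character(0), character(0), character(0))
  if (!inherits(record, "bio_object")) {
    v <- rbind(v, violation("record", "class", "not a bio_object"))
    return(list(ok = FALSE, violations = v))
  }
  if (!is_nonempty_string(record$id))
    v <- rbind(v, violation("id", "non_empty", "id must be a non-empty string"))
  if (!is_string(record$tag) || !record$tag %in% concrete_tags())
    v <- rbind(v, violation("tag", "concrete_tag",
                            "tag must be one of the ten concrete classes"))
  if (!is.character(record$names) || length(record$names) < 1L ||
      anyNA(record$names) || any(!nzchar(record$names)))
    v <- rbind(v, violation("names", "non_empty",
                            "names must hold at least one non-empty string"))
  if (is_string(record$tag) && record$tag %in% concrete_tags()) {
    schema <- .class_schema[[record$tag]]
    got <- names(record$attributes)
    for (key in setdiff(schema$required, got))
      v <- rbind(v, violation(key, "required_key",
                              sprintf("required attribute '%s' missing for %s",
                                      key, record$tag)))
    for (key in got) {
      if (!key %in% c(schema$required, schema$optional)) {
        v <- rbind(v, violation(key, "permitted_key",
                                sprintf("'%s' not permitted for %s", key, record$tag)))
        next
      }
      msg <- schema$check[[key]](record$attributes[[key]])
      if (!is.null(msg))
        v <- rbind(v, violation(key, "type", sprintf("'%s' %s", key, msg)))
    }
    if (record$tag == "DNARegion" &&
        is_count(record$attributes$start) && is_count(record$attributes$end) &&
        record$attributes$start > record$attributes$end)
      v <- rbind(v, violation("start", "coordinate_order",
                              "start must be <= end (1-based inclusive)"))
  }
  list(ok = nrow(v) == 0L, violations = v)
}

# --- document (de)serialization ---------------------------------------------
# The class tag lives under the JSON property "type"; documents carry keys in
# a fixed order so serialized stores are byte-stable.

#' Serialize a record to a plain document
#'
#' The record must validate; the class tag is stored under the `"type"`
#' property and cross-references as `"database:accession"` strings.
#'
#' @param record A validated `bio_object`.
#' @return A named list ready for JSON serialization.
#' @export
to_document <- function(record) {
  rep <- validate(record)
  if (!rep$ok)
    os_validation_error(paste0("cannot serialize an invalid record: ",
                               rep$violations$message[1]))
  doc <- list(id = record$id, type = record$tag, names = as.list(record$names))
  if (!is.null(record$func)) doc$`function` <- record$func
  doc$xrefs <- as.list(record$xrefs)
  if (!is.null(record$source)) doc$source <- record$source
  for (key in permitted_keys(record$tag))
    if (key %in% names(record$attributes)) {
      val <- record$attributes[[key]]
      doc[[key]] <- if (is.character(val) && length(val) > 1L) as.list(val) else val
    }
  doc
}

#' Rebuild a record from a plain document
#'
#' Inverse of [to_document()]: `from_document(to_document(r))` equals `r`
#' field for field. The `"type"` value must be one of the ten concrete tags.
#'
#' @param doc A named list as produced by [to_document()] or parsed from JSON.
#' @return A `bio_object`.
#' @export
from_document <- function(doc) {
  if (!is.list(doc)) os_schema_error("document must be a named list")
  if (!is_nonempty_string(doc$id %||% NULL)) os_schema_error("document lacks an id")
  type <- doc$type %||% NULL
  if (is.null(type)) os_schema_error("document lacks a 'type' property")
  if (!is_string(type) || !type %in% concrete_tags())
    os_schema_error(sprintf("unknown document type '%s'", as.character(type)[1]))
  nms <- unlist(doc$names, use.names = FALSE)
  if (is.null(nms) || !length(nms)) os_schema_error("document lacks names")
  rec <- new_bio_object(
    id = doc$id, tag = type, names = as.character(nms),
    func = doc$`function` %||% NULL,
    xrefs = as.character(unlist(doc$xrefs %||% character(0), use.names = FALSE)),
    source = doc$source %||% NULL
  )
  known <- c("id", "type", "names", "function", "xrefs", "source")
  for (key in setdiff(names(doc), known)) {
    val <- doc[[key]]
    if (is.list(val)) val <- as.character(unlist(val, use.names = FALSE))
    rec <- set_attribute(rec, key, val)
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bio_object <- function(x, ...) {
  cat(sprintf("<%s> %s (%s)\n", x$tag, x$id, paste(x$names, collapse = ", ")))
  if (length(x$attributes))
    cat("  attributes:", paste(names(x$attributes), collapse = ", "), "\n")
  invisible(x)
}
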