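#' The GGO annotation ontology
#'
#' The annotation schema for ground-glass opacity (GGO) findings in radiology
#' notes: 15 entity semantic types (GGO mentions, their attributes, potential
#' etiologies, status changes and dates) and 7 relation semantic types, each
#' anchored on a GGO mention (pure or part-solid) and pointing at one family
#' of attribute entities.
#'
#' @return `ggo_entity_types()` returns the 15 entity type names in canonical
#'   order. `ggo_relation_types()` returns the 7 relation type names.
#'   `ggo_schema()` returns the full schema as a `ggo_schema` object: a list
#'   with elements `entity_types` (character) and `relations` (named list;
#'   each element has `head_types` and `tail_types`).
#' @examples
#' length(ggo_entity_types())           # 15
#' ggo_schema()$relations$has_size_info
#' @export
ggo_entity_types <- function() {
  c("pure_ggo_term", "part_solid_ggo_term",
    "ggo_size", "ggo_quantity", "ggo_location", "ggo_shape_margin",
    "ggo_solidity", "temporal",
    "cause_neoplasm", "cause_infectious_inflammatory", "cause_hemorrhage",
    "cause_other_pulmonary",
    "status_better", "status_stable", "status_worsen")
}

#' @rdname ggo_entity_types
#' @export
ggo_relation_types <- function() {
  c("has_size_info", "has_number_info", "has_location_info",
    "has_shape_margin_info", "has_solidity_info", "has_status",
    "has_potential_cause")
}

.ggo_anchor_types <- function() c("pure_ggo_term", "part_solid_ggo_term")

#' @rdname ggo_entity_types
#' @export
ggo_schema <- function() {
  anchors <- .ggo_anchor_types()
  rel <- function(tails) list(head_types = anchors, tail_types = tails)
  schema <- list(
    version = "1.0",
    entity_types = ggo_entity_types(),
    relations = list(
      has_size_info        = rel("ggo_size"),
      has_number_info      = rel("ggo_quantity"),
      has_location_info    = rel("ggo_location"),
      has_shape_margin_info = rel("ggo_shape_margin"),
      has_solidity_info    = rel("ggo_solidity"),
      has_status           = rel(c("status_better", "status_stable",
                                   "status_worsen")),
      has_potential_cause  = rel(c("cause_neoplasm",
                                   "cause_infectious_inflammatory",
                                   "cause_hemorrhage",
                                   "cause_other_pulmonary"))
    )
  )
  class(schema) <- "ggo_schema"
  schema
}

#' Check a (head, tail, relation) triple against the GGO schema
#'
#' A relation is valid iff the head entity type is a GGO mention
#' (`pure_ggo_term` or `part_solid_ggo_term`) and the tail entity type belongs
#' to the relation's attribute family (e.g. `has_size_info` tails only
#' `ggo_size`; `has_potential_cause` tails only the four `cause_*` types).
#'
#' @param head_type,tail_type entity type names (members of
#'   [ggo_entity_types()]).
#' @param relation_type a relation type name (member of
#'   [ggo_relation_types()]).
#' @param schema a `ggo_schema` object; defaults to the built-in schema.
#' @return `TRUE` or `FALSE`. Unknown type names are an error.
#' @examples
#' validate_relation("pure_ggo_term", "ggo_size", "has_size_info")  # TRUE
#' validate_relation("ggo_size", "ggo_size", "has_size_info")       # FALSE
#' @export
validate_relation <- function(head_type, tail_type, relation_type,
                              schema = ggo_schema()) {
  ents <- schema$entity_types
  if (!head_type %in% ents)
    stop("unknown entity type: ", head_type)
  if (!tail_type %in% ents)
    stop("unknown entity type: ", tail_type)
  r <- schema$relations[[relation_type]]
  if (is.null(r))
    stop("unknown relation type: ", relation_type)
  head_type %in% r$head_types && tail_type %in% r$tail_types
}

#' The BIO label space over the GGO entity types
#'
#' Standard BIO encoding: the outside label `"O"` first, then `B-<type>` and
#' `I-<type>` for each entity type in canonical ontology order, giving
#' 2 x 15 + 1 = 31 labels. The order is deterministic and is the label
#' indexing used throughout the tagger.
#'
#' @param entity_types entity type names; defaults to the full ontology.
#' @return character vector of labels, `"O"` at position 1.
#' @export
bio_label_space <- function(entity_types = ggo_entity_types()) {
  c("O", as.vector(rbind(paste0("B-", entity_types),
                         paste0("I-", entity_types))))
}

#' Read or write the GGO schema as a JSON document
#'
#' The schema serializes to plain JSON (entity types, relation types and the
#' allowed head/tail pairs per relation) and re-parses to an identical
#' `ggo_schema` object. A copy of the built-in schema ships with the package
#' at `system.file("extdata", "ggo_schema.json", package = "ggonlp")`.
#'
#' @param schema a `ggo_schema` object.
#' @param path file path.
#' @return `read_schema()` returns a `ggo_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "ggo_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$entity_types) || is.null(x$relations))
    stop("not a GGO schema file: ", path)
  x$relations <- lapply(x$relations, function(r)
    list(head_types = as.character(r$head_types),
         tail_types = as.character(r$tail_types)))
  x$entity_types <- as.character(x$entity_types)
  class(x) <- "ggo_schema"
  x
}

#' @export
print.ggo_schema <- function(x, ...) {
  cat("GGO annotation schema (version ", x$version, ")\n", sep = "")
  cat("  ", length(x$entity_types), " entity types: ",
      paste(x$entity_types, collapse = ", "), "\n", sep = "")
  cat("  ", length(x$relations), " relation types:\n", sep = "")
  for (nm in names(x$relations))
    cat("    ", nm, " -> ",
        paste(x$relations[[nm]]$tail_types, collapse = ", "), "\n", sep = "")
  invisible(x)
}
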