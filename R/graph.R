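## ProvenanceGraph construction and basic manipulation (copy-on-write).

triple_key <- function(df) paste(df$s, df$p, df$o, df$o_type, sep = "\r")

#' Construct a provenance graph
#'
#' Duplicate triples are removed (set semantics); a ground-truth label
#' vector, if supplied, is deduplicated consistently.
#'
#' @param triples a triple data.frame (see [tripleTable()]).
#' @param schema optional [OntologySchema-class] backing the graph.
#' @param graphId optional named-graph IRI.
#' @param metadata list of graph-level annotations.
#' @param labels optional "data"/"provenance" label per triple.
#' @return a [ProvenanceGraph-class].
#' @export
provenanceGraph <- function(triples = tripleTable(), schema = NULL,
                            graphId = NA_character_, metadata = list(),
                            labels = character()) {
  ok <- check_triple_table(triples)
  if (!isTRUE(ok)) stop(ok)
  triples <- triples[, TRIPLE_COLS]
  keep <- !duplicated(triple_key(triples))
  if (length(labels)) {
    stopifnot(length(labels) == nrow(triples))
    labels <- labels[keep]
  }
  triples <- triples[keep, , drop = FALSE]
  rownames(triples) <- NULL
  new("ProvenanceGraph", triples = triples, schema = schema,
      graphId = graphId, metadata = metadata, labels = labels)
}

#' Graph accessors
#'
#' `triples()` returns the triple data.frame, `graphSchema()` the backing
#' schema (or NULL), `tripleCount()` the number of triples and
#' `tripleLabels()` the ground-truth labels (empty for unlabeled graphs).
#'
#' @param graph a [ProvenanceGraph-class].
#' @rdname graphAccessors
#' @export
triples <- function(graph) graph@triples

#' @rdname graphAccessors
#' @export
graphSchema <- function(graph) graph@schema

#' @rdname graphAccessors
#' @export
tripleCount <- function(graph) nrow(graph@triples)

#' @rdname graphAccessors
#' @export
tripleLabels <- function(graph) graph@labels

#' Add triples to a graph (copy-on-write)
#'
#' @param graph a [ProvenanceGraph-class].
#' @param new a triple data.frame.
#' @param labels optional labels for the added rows.
#' @return a new [ProvenanceGraph-class]; the input is unchanged.
#' @export
addTriples <- function(graph, new, labels = character()) {
  has_lab <- length(graph@labels) > 0L || length(labels) > 0L
  lab <- character()
  if (has_lab) {
    old_lab <- if (length(graph@labels)) graph@labels
               else rep("data", nrow(graph@triples))
    new_lab <- if (length(labels)) labels else rep("data", nrow(new))
    lab <- c(old_lab, new_lab)
  }
  provenanceGraph(rbind(graph@triples, new[, TRIPLE_COLS]),
                  schema = graph@schema, graphId = graph@graphId,
                  metadata = graph@metadata, labels = lab)
}

#' Remove triples from a graph (copy-on-write)
#'
#' @param graph a [ProvenanceGraph-class].
#' @param drop a triple data.frame of rows to remove.
#' @return a new [ProvenanceGraph-class].
#' @export
removeTriples <- function(graph, drop) {
  keep <- !(triple_key(graph@triples) %in% triple_key(drop))
  provenanceGraph(graph@triples[keep, , drop = FALSE], schema = graph@schema,
                  graphId = graph@graphId, metadata = graph@metadata,
                  labels = if (length(graph@labels)) graph@labels[keep]
                           else character())
}

#' Union of two graphs' triple sets
#' @keywords internal
union_graphs <- function(g1, g2) {
  provenanceGraph(rbind(g1@triples, g2@triples),
                  schema = g1@schema %||% g2@schema,
                  metadata = c(g1@metadata, g2@metadata))
}

#' All node IRIs appearing in a graph
#'
#' @param graph a [ProvenanceGraph-class].
#' @return character vector of distinct subject/object IRIs (literals and
#'   vocabulary terms excluded).
#' @export
graphNodes <- function(graph) {
  df <- graph@triples
  obj <- df$o[df$o_type == "iri"]
  setdiff(unique(c(df$s, obj)), reserved_vocabulary())
}

#' Fingerprint of a graph's triple set
#'
#' Order-independent hash used by the materialized-view cache to detect
#' base-graph mutation.
#'
#' @param graph a [ProvenanceGraph-class].
#' @return a character hash.
#' @export
graphFingerprint <- function(graph) {
  df <- graph@triples
  rlang::hash(sort(triple_key(df)))
}

#' Types of an instance node in a graph, resolved to schema class names
#'
#' @keywords internal
instance_classes <- function(graph, nodes) {
  df <- graph@triples
  ty <- df[df$p == RDF_TYPE & df$s %in% nodes & df$o_type == "iri", c("s", "o")]
  if (!is.null(graph@schema))
    ty$class <- class_name_from_uri(graph@schema, ty$o)
  else ty$class <- NA_character_
  ty
}

# TRUE for each node that is (transitively) an instance of `cls`
is_instance_of <- function(graph, nodes, cls) {
  if (is.null(graph@schema)) stop("graph has no schema")
  accepted <- class_uri(graph@schema, subclassesOf(graph@schema, cls))
  df <- graph@triples
  ty <- df[df$p == RDF_TYPE & df$o_type == "iri" & df$o %in% accepted, "s"]
  nodes %in% ty
}

# all instances of cls (or subclasses) in the graph
instances_of <- function(graph, cls) {
  if (is.null(graph@schema)) stop("graph has no schema")
  accepted <- class_uri(graph@schema, subclassesOf(graph@schema, cls))
  df <- graph@triples
  sort(unique(df$s[df$p == RDF_TYPE & df$o_type == "iri" & df$o %in% accepted]))
}

setMethod("show", "ProvenanceGraph", function(object) {
  cat("ProvenanceGraph:", nrow(object@triples), "triples")
  if (!is.null(object@schema)) cat(" (schema-backed)")
  if (length(object@labels)) {
    cat(";", sum(object@labels == "provenance"), "labeled provenance")
  }
  cat("\n")
  if (!is.na(object@graphId)) cat("  graph id:", object@graphId, "\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})
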