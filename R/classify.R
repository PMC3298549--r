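## Data-vs-provenance triple classification and propagation export.
## Data and provenance co-reside in one graph; what counts as provenance
## is application-defined, so the classifier works from the schema: a
## triple is provenance-specific iff its predicate is one of the schema's
## provenance properties, or its subject/object is (transitively) an
## instance of process, agent, or parameter.

#' StorageStats: triple-classification summary
#'
#' @slot totalTriples instance-level triple count (schema/TBox triples are
#'   excluded from the statistics).
#' @slot provenanceTriples provenance-specific triple count.
#' @slot provenanceFraction percentage of total.
#' @export
setClass("StorageStats",
         representation(totalTriples = "numeric",
                        provenanceTriples = "numeric",
                        provenanceFraction = "numeric"))

setValidity("StorageStats", function(object) {
  if (object@provenanceTriples < 0 ||
      object@provenanceTriples > object@totalTriples)
    return("0 <= provenanceTriples <= totalTriples violated")
  TRUE
})

setMethod("show", "StorageStats", function(object) {
  cat(sprintf("StorageStats: %d triples, %d provenance-specific (%.1f%%)\n",
              object@totalTriples, object@provenanceTriples,
              object@provenanceFraction))
})

tbox_rows <- function(df) {
  df$p %in% c(RDFS_SUBCLASSOF, RDFS_SUBPROPERTYOF, RDFS_DOMAIN, RDFS_RANGE,
              RDFS_LABEL) |
    (df$p == RDF_TYPE & df$o %in% c(OWL_CLASS, OWL_OBJECTPROPERTY))
}

# per-row logical: is this triple provenance-specific under the schema rule?
provenance_rows <- function(graph) {
  schema <- graph@schema
  if (is.null(schema)) stop("classification error: graph has no schema")
  df <- graph@triples
  prov_props <- schema@properties$uri
  prov_classes <- unique(unlist(lapply(
    intersect(c("process", "agent", "parameter"), schema@classes$name),
    function(cl) subclassesOf(schema, cl))))
  prov_class_uris <- class_uri(schema, prov_classes)
  prov_instances <- unique(df$s[df$p == RDF_TYPE & df$o_type == "iri" &
                                  df$o %in% prov_class_uris])
  df$p %in% prov_props |
    df$s %in% prov_instances |
    (df$o_type == "iri" & df$o %in% prov_instances)
}

#' Classify a graph's triples as data vs provenance-specific
#'
#' Statistics are instance-level: schema (TBox) triples — subclass,
#' subproperty, domain, range, label assertions and `owl:Class`/
#' `owl:ObjectProperty` typing — are excluded before counting.
#'
#' @param graph a schema-backed [ProvenanceGraph-class].
#' @return a [StorageStats-class].
#' @export
classifyTriples <- function(graph) {
  df <- graph@triples
  keep <- !tbox_rows(df)
  inst <- provenanceGraph(df[keep, , drop = FALSE], schema = graph@schema)
  prov <- provenance_rows(inst)
  total <- nrow(inst@triples)
  new("StorageStats", totalTriples = total,
      provenanceTriples = sum(prov),
      provenanceFraction = if (total) 100 * sum(prov) / total else 0)
}

#' Per-triple provenance classification
#'
#' @param graph a schema-backed [ProvenanceGraph-class].
#' @return character vector, "data"/"provenance" per triple (TBox triples
#'   are reported as "data").
#' @export
classifyTripleLabels <- function(graph) {
  lab <- ifelse(provenance_rows(graph), "provenance", "data")
  lab[tbox_rows(graph@triples)] <- "data"
  lab
}

#' Propagation export: an entity set with its full provenance closure
#'
#' Returns the self-contained induced subgraph holding the requested
#' entities, every triple mentioning them, the provenance closure
#' reachable from them along the schema's provenance properties in either
#' direction (including `preceded_by` chains), and the type and literal
#' triples of every node pulled in — so the export travels with all the
#' provenance needed to interpret it. Agent instances are included but
#' not traversed through: agents are shared resources (one researcher
#' operates many runs) and expanding through them would connect otherwise
#' unrelated lineages.
#'
#' @param graph a schema-backed [ProvenanceGraph-class].
#' @param entities character vector of IRIs present in the graph.
#' @return a [ProvenanceGraph-class] (labels preserved when present).
#' @export
propagate <- function(graph, entities) {
  schema <- graph@schema
  if (is.null(schema)) stop("propagation error: graph has no schema")
  df <- graph@triples
  known <- unique(c(df$s, df$o[df$o_type == "iri"]))
  missing <- setdiff(entities, known)
  if (length(missing))
    stop("propagation error: entity(ies) not in graph: ",
         paste(missing, collapse = ", "))

  prov <- df[df$p %in% schema@properties$uri & df$o_type == "iri",
             c("s", "o")]
  terminal <- setdiff(instances_of(graph, "agent"), entities)
  nodes <- unique(entities)
  repeat {
    expandable <- setdiff(nodes, terminal)
    fwd <- prov$o[prov$s %in% expandable]
    bwd <- prov$s[prov$o %in% expandable]
    more <- setdiff(unique(c(fwd, bwd)), nodes)
    if (!length(more)) break
    nodes <- c(nodes, more)
  }
  keep <- (df$s %in% entities) |
    (df$o_type == "iri" & df$o %in% entities) |
    (df$p %in% schema@properties$uri & df$s %in% nodes) |
    (df$p == RDF_TYPE & df$s %in% nodes) |
    (df$o_type == "literal" & df$s %in% nodes)
  provenanceGraph(df[keep, , drop = FALSE], schema = schema,
                  metadata = graph@metadata,
                  labels = if (length(graph@labels)) graph@labels[keep]
                           else character())
}
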