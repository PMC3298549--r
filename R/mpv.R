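## Materialized provenance views: schema-driven caching of provenance
## subgraphs. Views are keyed per entity (default) or per schema region
## (a class name: the view materializes the propagation closure of all
## its instances). The base graph is immutable (copy-on-write), so
## mutation shows up as a changed fingerprint; a view whose fingerprint
## no longer matches the presented graph is marked stale and is never
## served — cached answers are always identical to uncached evaluation.

#' Create an empty materialized-view cache
#'
#' @return an [MpvCache-class].
#' @export
mpvCache <- function() new("MpvCache", views = new.env(parent = emptyenv()))

#' Materialize a provenance view
#'
#' For an entity key (an IRI in the graph) the view holds
#' `provenance(graph, key)`; for a schema-region key (a class name) it
#' holds the propagation closure of all instances of that class.
#'
#' @param graph a schema-backed [ProvenanceGraph-class].
#' @param key entity IRI or schema class name.
#' @return a [MaterializedProvenanceView-class].
#' @export
buildMpv <- function(graph, key) {
  sub <- if (!grepl("://", key) && !is.null(graph@schema) &&
             key %in% graph@schema@classes$name) {
    propagate(graph, instances_of(graph, key))
  } else {
    provenance(graph, key)
  }
  new("MaterializedProvenanceView", key = key, subgraph = sub,
      stale = FALSE, fingerprint = graphFingerprint(graph))
}

#' @describeIn queryWithMpv store a view in a cache.
#' @param view a [MaterializedProvenanceView-class].
#' @export
storeMpv <- function(cache, view) {
  assign(view@key, view, envir = cache@views)
  invisible(cache)
}

#' @describeIn queryWithMpv keys currently cached.
#' @export
mpvKeys <- function(cache) ls(cache@views)

#' @describeIn queryWithMpv is the cached view for `key` stale relative
#'   to `graph`? (TRUE as well when no view exists)
#' @param key a view key.
#' @export
mpvIsStale <- function(cache, graph, key) {
  if (!exists(key, envir = cache@views, inherits = FALSE)) return(TRUE)
  v <- get(key, envir = cache@views, inherits = FALSE)
  v@stale || !identical(v@fingerprint, graphFingerprint(graph))
}

#' Answer a provenance query through the view cache
#'
#' Serves `provenance(graph, entity)` from a fresh materialized view when
#' one exists; otherwise (cold cache, or the base graph mutated since the
#' view was built) the stale view is marked, evaluation falls through to
#' the base graph, and the fresh result is re-materialized. Answers are
#' always identical to uncached evaluation.
#'
#' @param cache an [MpvCache-class].
#' @param graph the current base [ProvenanceGraph-class].
#' @param entity the query input (entity IRI).
#' @param materialize store the freshly computed view on a miss.
#' @return the provenance subgraph ([ProvenanceGraph-class]).
#' @export
queryWithMpv <- function(cache, graph, entity, materialize = TRUE) {
  fp <- graphFingerprint(graph)
  if (exists(entity, envir = cache@views, inherits = FALSE)) {
    v <- get(entity, envir = cache@views, inherits = FALSE)
    if (!v@stale && identical(v@fingerprint, fp))
      return(v@subgraph)
    v@stale <- TRUE                      # never serve a stale view
    assign(entity, v, envir = cache@views)
  }
  # region views: a fresh view of the entity's class region can answer
  # the query by evaluation over its (self-contained) subgraph
  if (!is.null(graph@schema)) {
    for (k in mpvKeys(cache)) {
      v <- get(k, envir = cache@views, inherits = FALSE)
      if (!v@stale && identical(v@fingerprint, fp) &&
          k %in% graph@schema@classes$name &&
          entity %in% graphNodes(v@subgraph) &&
          is_instance_of(graph, entity, k)) {
        return(provenance(v@subgraph, entity))
      }
    }
  }
  res <- provenance(graph, entity)
  if (materialize)
    storeMpv(cache, new("MaterializedProvenanceView", key = entity,
                        subgraph = res, stale = FALSE, fingerprint = fp))
  res
}

setMethod("show", "MaterializedProvenanceView", function(object) {
  cat("MaterializedProvenanceView for", object@key,
      if (object@stale) "(stale)" else "(fresh)", "-",
      tripleCount(object@subgraph), "triples\n")
})

setMethod("show", "MpvCache", function(object) {
  cat("MpvCache with", length(ls(object@views)), "view(s)\n")
})
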