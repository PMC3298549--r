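#' @import methods
NULL

## ---- triple table ----------------------------------------------------------

TRIPLE_COLS <- c("s", "p", "o", "o_type", "o_datatype")

#' Construct a triple table
#'
#' Triples are kept as a plain data.frame with columns `s`, `p`, `o`
#' (character), `o_type` (`"iri"` or `"literal"`) and `o_datatype`
#' (datatype IRI or `NA` for plain literals / IRI objects).
#'
#' @param s,p,o character vectors (recycled to common length).
#' @param o_type `"iri"` or `"literal"`, recycled.
#' @param o_datatype datatype IRI or `NA`, recycled.
#' @return a triple data.frame.
#' @export
tripleTable <- function(s = character(), p = character(), o = character(),
                        o_type = "iri", o_datatype = NA_character_) {
  n <- if (length(s) == 0L || length(p) == 0L || length(o) == 0L) 0L
       else max(length(s), length(p), length(o))
  if (n == 0L) {
    return(data.frame(s = character(), p = character(), o = character(),
                      o_type = character(), o_datatype = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(s = rep_len(as.character(s), n),
             p = rep_len(as.character(p), n),
             o = rep_len(as.character(o), n),
             o_type = rep_len(as.character(o_type), n),
             o_datatype = rep_len(as.character(o_datatype), n),
             stringsAsFactors = FALSE)
}

check_triple_table <- function(df) {
  if (!is.data.frame(df)) return("triples must be a data.frame")
  if (!all(TRIPLE_COLS %in% names(df)))
    return(sprintf("triples must have columns %s",
                   paste(TRIPLE_COLS, collapse = ", ")))
  if (nrow(df) && !all(df$o_type %in% c("iri", "literal")))
    return("o_type must be 'iri' or 'literal'")
  TRUE
}

## ---- schema ----------------------------------------------------------------

#' ClassDef: a named ontology class
#'
#' @slot name class identifier, unique within a schema.
#' @slot uri absolute IRI of the class.
#' @slot parent name of the parent class, or `NA` for a top-level class.
#' @export
setClass("ClassDef",
         representation(name = "character", uri = "character",
                        parent = "character"),
         prototype(parent = NA_character_))

#' PropertyDef: a named ontology property with domain and range
#'
#' @slot name property identifier.
#' @slot uri absolute IRI.
#' @slot parent name of parent property or `NA`.
#' @slot domain name of the domain class.
#' @slot range name of the range class, or a datatype IRI
#'   (anything containing "://" is treated as a literal datatype marker).
#' @export
setClass("PropertyDef",
         representation(name = "character", uri = "character",
                        parent = "character", domain = "character",
                        range = "character"),
         prototype(parent = NA_character_))

#' OntologySchema: an upper-level provenance schema plus extensions
#'
#' Holds the class and property registries as data.frames. The default
#' schema ([defaultProvenirSchema()]) has the three top-level classes
#' `data`, `process`, `agent`, five subclasses, and eleven named
#' relationships.
#'
#' @slot baseNamespace IRI prefix used to mint class/property IRIs.
#' @slot classes data.frame with columns name, uri, parent.
#' @slot properties data.frame with columns name, uri, parent, domain, range.
#' @export
setClass("OntologySchema",
         representation(baseNamespace = "character",
                        classes = "data.frame",
                        properties = "data.frame"))

setClassUnion("OntologySchemaOrNULL", c("OntologySchema", "NULL"))

# Returns TRUE, or a character vector naming a parent-chain cycle.
schema_parent_acyclic <- function(df) {
  parent <- stats::setNames(as.character(df$parent), df$name)
  for (start in df$name) {
    seen <- character()
    cur <- start
    repeat {
      nxt <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
      if (is.na(nxt)) break
      if (nxt %in% c(seen, cur)) return(unique(c(seen, cur, nxt)))
      seen <- c(seen, cur)
      cur <- nxt
    }
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setValidity("OntologySchema", function(object) {
  cl <- object@classes
  pr <- object@properties
  msgs <- character()
  if (anyDuplicated(cl$name)) msgs <- c(msgs, "duplicate class names")
  if (anyDuplicated(pr$name)) msgs <- c(msgs, "duplicate property names")
  bad_parent <- !is.na(cl$parent) & !(cl$parent %in% cl$name)
  if (any(bad_parent))
    msgs <- c(msgs, sprintf("unknown class parent(s): %s",
                            paste(cl$parent[bad_parent], collapse = ", ")))
  cyc <- schema_parent_acyclic(cl)
  if (!isTRUE(cyc))
    msgs <- c(msgs, sprintf("subclass cycle: %s", paste(cyc, collapse = " -> ")))
  bad_pp <- !is.na(pr$parent) & !(pr$parent %in% pr$name)
  if (any(bad_pp))
    msgs <- c(msgs, sprintf("unknown property parent(s): %s",
                            paste(pr$parent[bad_pp], collapse = ", ")))
  pcyc <- schema_parent_acyclic(pr)
  if (!isTRUE(pcyc))
    msgs <- c(msgs, sprintf("subproperty cycle: %s", paste(pcyc, collapse = " -> ")))
  if (nrow(pr)) {
    bad_dom <- !(pr$domain %in% cl$name)
    if (any(bad_dom))
      msgs <- c(msgs, sprintf("property domain not in schema: %s",
                              paste(pr$name[bad_dom], collapse = ", ")))
    is_dt <- grepl("://", pr$range)
    bad_rng <- !is_dt & !(pr$range %in% cl$name)
    if (any(bad_rng))
      msgs <- c(msgs, sprintf("property range not in schema: %s",
                              paste(pr$name[bad_rng], collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

## ---- pattern ---------------------------------------------------------------

#' ProvenancePattern: an ordered chain of classes joined by properties
#'
#' Element i (i > 1) is connected to element i-1 by the property in row i;
#' the first row's property is `NA`. Patterns are composed from schema
#' class/property names and validated against the schema before use.
#'
#' @slot elements data.frame with columns `class` and `property`.
#' @export
setClass("ProvenancePattern",
         representation(elements = "data.frame"))

setValidity("ProvenancePattern", function(object) {
  el <- object@elements
  if (!all(c("class", "property") %in% names(el)))
    return("elements needs columns class, property")
  if (nrow(el) && !is.na(el$property[1]))
    return("first element cannot have a connecting property")
  TRUE
})

## ---- provenance context / assertions --------------------------------------

#' SourceDescriptor: identity of a data source behind an assertion
#'
#' @slot sourceType one of "literature", "structured_db", "terminology".
#' @slot sourceId identifier string, e.g. "PUBMED_17209178".
#' @slot publicationDate optional date string (ISO), or `NA`.
#' @slot version optional source version string, or `NA`.
#' @export
setClass("SourceDescriptor",
         representation(sourceType = "character", sourceId = "character",
                        publicationDate = "character", version = "character"),
         prototype(publicationDate = NA_character_, version = NA_character_))

setValidity("SourceDescriptor", function(object) {
  if (!object@sourceType %in% c("literature", "structured_db", "terminology"))
    return("sourceType must be literature, structured_db or terminology")
  if (!nzchar(object@sourceId)) return("sourceId must be non-empty")
  if (grepl("[/\\\\]", object@sourceId))
    return("sourceId must not contain path separators")
  TRUE
})

#' SourcedAssertion: an extracted S-P-O statement plus its source
#'
#' @slot subjectName,predicateName,objectName entity/relation labels.
#' @slot source a [SourceDescriptor-class].
#' @slot confidence optional unitless extraction-tool score (`NA` if absent).
#' @slot subjectClass,predicateClass,objectClass optional schema class names
#'   used to emit `rdf:type` triples.
#' @export
setClass("SourcedAssertion",
         representation(subjectName = "character", predicateName = "character",
                        objectName = "character", source = "SourceDescriptor",
                        confidence = "numeric",
                        subjectClass = "character", predicateClass = "character",
                        objectClass = "character"),
         prototype(confidence = NA_real_, subjectClass = NA_character_,
                   predicateClass = NA_character_, objectClass = NA_character_))

setValidity("SourcedAssertion", function(object) {
  if (!all(nzchar(c(object@subjectName, object@predicateName, object@objectName))))
    return("subject, predicate and object names must be non-empty")
  TRUE
})

#' ProvenanceContext: the PaCE provenance-context definition
#'
#' @slot baseUri absolute HTTP IRI prefix under which contextualized IRIs
#'   are minted.
#' @slot contextTerms schema class names making up the context; each must be
#'   a declared subclass of the schema's `data` class.
#' @slot linkingProperty schema property name used to attach entities to
#'   source nodes (default `derives_from`).
#' @slot schema the [OntologySchema-class] the context is defined against.
#' @export
setClass("ProvenanceContext",
         representation(baseUri = "character", contextTerms = "character",
                        linkingProperty = "character",
                        schema = "OntologySchema"))

## ---- graph -----------------------------------------------------------------

#' ProvenanceGraph: data and provenance in a single RDF graph
#'
#' Data triples and provenance triples co-reside in one graph (set
#' semantics, no duplicates). An optional ground-truth label vector
#' (parallel to the triple rows, values "data"/"provenance") is carried
#' by graphs built by the synthetic generators.
#'
#' @slot triples triple data.frame (see [tripleTable()]).
#' @slot schema the schema used for classification/query, or NULL.
#' @slot graphId optional named-graph IRI (`NA` if none).
#' @slot metadata free-form list of graph-level annotations.
#' @slot labels character(0) or one "data"/"provenance" label per triple.
#' @export
setClass("ProvenanceGraph",
         representation(triples = "data.frame", schema = "OntologySchemaOrNULL",
                        graphId = "character", metadata = "list",
                        labels = "character"),
         prototype(graphId = NA_character_, metadata = list(),
                   labels = character()))

setValidity("ProvenanceGraph", function(object) {
  ok <- check_triple_table(object@triples)
  if (!isTRUE(ok)) return(ok)
  if (length(object@labels) &&
      length(object@labels) != nrow(object@triples))
    return("labels must be empty or one per triple")
  if (length(object@labels) &&
      !all(object@labels %in% c("data", "provenance")))
    return("labels must be 'data' or 'provenance'")
  key <- paste(object@triples$s, object@triples$p, object@triples$o,
               object@triples$o_type)
  if (anyDuplicated(key)) return("duplicate triples (set semantics required)")
  TRUE
})

## ---- materialized views ----------------------------------------------------

#' MaterializedProvenanceView: a cached provenance subgraph
#'
#' @slot key the entity IRI (or schema-region key) the view answers.
#' @slot subgraph the cached [ProvenanceGraph-class].
#' @slot stale logical staleness flag.
#' @slot fingerprint hash of the base graph the view was computed from.
#' @export
setClass("MaterializedProvenanceView",
         representation(key = "character", subgraph = "ProvenanceGraph",
                        stale = "logical", fingerprint = "character"),
         prototype(stale = FALSE))

#' MpvCache: a mutable store of materialized provenance views
#'
#' @slot views environment keyed by view key.
#' @export
setClass("MpvCache", representation(views = "environment"))

## ---- generator specs -------------------------------------------------------

#' ProtocolSpec: recipe for synthetic experiment-protocol provenance
#'
#' @slot steps list of steps; each step is a list with `process` (class
#'   name), `parameters` (named list: parameter class name -> value
#'   distribution, itself a list like `list(kind="uniform",min=,max=)` or
#'   `list(kind="choice", values=)`), and `agents` (agent pool size).
#' @slot branching number of output samples produced by the final step of
#'   each run.
#' @slot seed integer seed for the spec's private random stream.
#' @export
setClass("ProtocolSpec",
         representation(steps = "list", branching = "integer",
                        seed = "integer"),
         prototype(branching = 1L, seed = 1L))

setValidity("ProtocolSpec", function(object) {
  if (!length(object@steps)) return("spec needs at least one step")
  for (st in object@steps) {
    if (is.null(st$process) || !nzchar(st$process))
      return("each step needs a process class name")
    if (is.null(st$agents) || st$agents < 1)
      return("each step needs an agent pool size >= 1")
    for (pm in st$parameters) {
      if (is.null(pm$kind) ||
          !pm$kind %in% c("uniform", "choice", "integer"))
        return("parameter distributions must be uniform, integer or choice")
      if (pm$kind %in% c("uniform", "integer") &&
          (is.null(pm$min) || is.null(pm$max)))
        return("uniform/integer distributions need min and max")
      if (pm$kind == "choice" && !length(pm$values))
        return("choice distributions need values")
    }
  }
  if (object@branching < 1L) return("branching must be >= 1")
  TRUE
})

#' CorpusSpec: recipe for a synthetic extraction corpus
#'
#' @slot nAssertions number of assertions to draw.
#' @slot nSources number of distinct literature sources.
#' @slot confidenceRange numeric length-2, uniform confidence range.
#' @slot yearRange integer length-2, publication-year interval.
#' @slot impactFactorRange numeric length-2, per-source impact factors are
#'   drawn uniformly from this interval.
#' @slot seed integer seed.
#' @export
setClass("CorpusSpec",
         representation(nAssertions = "integer", nSources = "integer",
                        confidenceRange = "numeric", yearRange = "integer",
                        impactFactorRange = "numeric", seed = "integer"),
         prototype(seed = 1L))

setValidity("CorpusSpec", function(object) {
  if (object@nAssertions < 1L || object@nSources < 1L)
    return("counts must be positive")
  if (length(object@confidenceRange) != 2L ||
      diff(object@confidenceRange) < 0)
    return("confidenceRange must be a non-empty interval")
  if (length(object@yearRange) != 2L || diff(object@yearRange) < 0)
    return("yearRange must be a non-empty interval")
  if (length(object@impactFactorRange) != 2L ||
      diff(object@impactFactorRange) < 0)
    return("impactFactorRange must be a non-empty interval")
  TRUE
})
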