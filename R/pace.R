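## Provenance Context Entity (PaCE) triple generation: contextualized IRI
## minting, three encoding granularities, the RDF-reification baseline,
## and context-based grouping.

#' ContextualizedIRI: a source-contextualized entity IRI
#'
#' An IRI of the form `<base>/<provenance context string>/<entity name>`
#' identifying a source-specific occurrence of an entity.
#'
#' @slot base absolute HTTP IRI prefix.
#' @slot contextString the source-identifying path segment.
#' @slot localName the raw (decoded) entity name.
#' @export
setClass("ContextualizedIRI",
         representation(base = "character", contextString = "character",
                        localName = "character"))

#' Create a source descriptor
#'
#' @param sourceType "literature", "structured_db" or "terminology".
#' @param sourceId identifier string (e.g. "PUBMED_17209178"); must not
#'   contain path separators.
#' @param publicationDate optional ISO date string.
#' @param version optional version string.
#' @return a [SourceDescriptor-class].
#' @export
sourceDescriptor <- function(sourceType, sourceId,
                             publicationDate = NA_character_,
                             version = NA_character_) {
  new("SourceDescriptor", sourceType = sourceType,
      sourceId = trimws(as.character(sourceId)),
      publicationDate = as.character(publicationDate),
      version = as.character(version))
}

#' Create a sourced assertion
#'
#' An extracted subject-predicate-object statement together with its
#' source descriptor, an optional extraction confidence, and optional
#' schema classes for typing the three components.
#'
#' @param subject,predicate,object entity/relation labels (non-empty).
#' @param source a [SourceDescriptor-class].
#' @param confidence optional unitless score.
#' @param subjectClass,predicateClass,objectClass optional schema class
#'   names.
#' @return a [SourcedAssertion-class].
#' @export
sourcedAssertion <- function(subject, predicate, object, source,
                             confidence = NA_real_,
                             subjectClass = NA_character_,
                             predicateClass = NA_character_,
                             objectClass = NA_character_) {
  new("SourcedAssertion", subjectName = subject, predicateName = predicate,
      objectName = object, source = source,
      confidence = as.numeric(confidence),
      subjectClass = subjectClass, predicateClass = predicateClass,
      objectClass = objectClass)
}

#' Create a PaCE provenance-context definition
#'
#' @param schema the [OntologySchema-class] the context is defined
#'   against.
#' @param baseUri absolute HTTP IRI prefix for contextualized IRIs.
#' @param contextTerms schema class names forming the context; each must
#'   be a declared subclass of the schema's `data` class.
#' @param linkingProperty schema property used to attach entities to their
#'   source node (default `derives_from`).
#' @return a [ProvenanceContext-class].
#' @export
paceContext <- function(schema, baseUri, contextTerms = character(),
                        linkingProperty = "derives_from") {
  if (!is_absolute_http_iri(baseUri))
    stop("baseUri must be an absolute HTTP IRI prefix")
  baseUri <- sub("/+$", "", baseUri)
  for (term in contextTerms) {
    if (!term %in% schema@classes$name)
      stop("context term '", term, "' is not declared in the schema")
    if (!isSubclassOf(schema, term, "data") || identical(term, "data"))
      stop("context term '", term,
           "' must be a declared subclass of the data class")
  }
  property_uri(schema, linkingProperty)  # errors on unknown property
  new("ProvenanceContext", baseUri = baseUri, contextTerms = contextTerms,
      linkingProperty = linkingProperty, schema = schema)
}

#' Mint a contextualized IRI
#'
#' Rendered form is `base + "/" + contextString + "/" +
#' percent-encoded entity name` — e.g.
#' `http://mor.nlm.nih.gov/bkr/PUBMED_17209178/lipoprotein`.
#'
#' @param base absolute HTTP IRI prefix.
#' @param contextString provenance context string identifying the source.
#' @param entityName raw entity name (percent-encoded on rendering).
#' @return a [ContextualizedIRI-class].
#' @export
mintUri <- function(base, contextString, entityName) {
  if (!is_absolute_http_iri(base))
    stop("minting error: base must be an absolute HTTP IRI prefix")
  if (!nzchar(entityName) || is.na(entityName))
    stop("minting error: empty entity name")
  if (!nzchar(contextString))
    stop("minting error: empty context string")
  new("ContextualizedIRI", base = sub("/+$", "", base),
      contextString = contextString, localName = entityName)
}

#' Render a contextualized IRI to its string form
#' @param x a [ContextualizedIRI-class].
#' @return character IRI.
#' @export
renderUri <- function(x) {
  paste0(x@base, "/", percent_encode(x@contextString), "/",
         percent_encode(x@localName))
}

#' Parse a contextualized IRI string minted under a base prefix
#'
#' Inverse of [renderUri()]: `parseContextUri(renderUri(x), x@base)` is
#' identical to `x`.
#'
#' @param iri the rendered IRI.
#' @param base the base prefix it was minted under.
#' @return a [ContextualizedIRI-class].
#' @export
parseContextUri <- function(iri, base) {
  base <- sub("/+$", "", base)
  prefix <- paste0(base, "/")
  if (!startsWith(iri, prefix))
    stop("IRI was not minted under base ", base)
  rest <- substring(iri, nchar(prefix) + 1L)
  parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("not a contextualized IRI (expected context/name): ", iri)
  new("ContextualizedIRI", base = base,
      contextString = percent_decode(parts[1]),
      localName = percent_decode(parts[2]))
}

setMethod("show", "ContextualizedIRI", function(object) {
  cat("<", renderUri(object), ">\n", sep = "")
})

# Extraction labels may contain whitespace; normalize before minting.
normalize_entity_name <- function(x) {
  gsub("[[:space:]]+", "_", trimws(x))
}

## Canonical batch representation: one row per assertion.
as_assertion_table <- function(assertions) {
  if (is(assertions, "SourcedAssertion")) assertions <- list(assertions)
  if (is.data.frame(assertions)) {
    need <- c("subject", "predicate", "object", "source_id")
    if (!all(need %in% names(assertions)))
      stop("assertion table needs columns ", paste(need, collapse = ", "))
    df <- assertions
    for (col in c("source_type", "publication_date", "version",
                  "subject_class", "predicate_class", "object_class"))
      if (is.null(df[[col]])) df[[col]] <- rep(NA_character_, nrow(df))
    df$source_type[is.na(df$source_type)] <- "literature"
    if (is.null(df$confidence)) df$confidence <- rep(NA_real_, nrow(df))
    return(df)
  }
  rows <- lapply(assertions, function(a) {
    stopifnot(is(a, "SourcedAssertion"))
    data.frame(subject = a@subjectName, predicate = a@predicateName,
               object = a@objectName, source_type = a@source@sourceType,
               source_id = a@source@sourceId,
               publication_date = a@source@publicationDate,
               version = a@source@version, confidence = a@confidence,
               subject_class = a@subjectClass,
               predicate_class = a@predicateClass,
               object_class = a@objectClass, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(list(data.frame()), rows))
}

source_node_iri <- function(baseUri, source_id) {
  if (!length(source_id)) return(character())
  paste0(baseUri, "/source/", percent_encode(source_id))
}

annotation_triples <- function(node, date, confidence) {
  tt <- tripleTable()
  if (!is.na(confidence))
    tt <- rbind(tt, tripleTable(node, ANNO_CONFIDENCE,
                                format(confidence, scientific = FALSE, trim = TRUE),
                                o_type = "literal", o_datatype = XSD_DOUBLE))
  if (!is.na(date) && nzchar(date)) {
    tt <- rbind(tt, tripleTable(node, ANNO_PUB_DATE, date,
                                o_type = "literal", o_datatype = XSD_DATE))
    yr <- suppressWarnings(as.integer(substr(date, 1, 4)))
    if (!is.na(yr))
      tt <- rbind(tt, tripleTable(node, ANNO_YEAR, as.character(yr),
                                  o_type = "literal", o_datatype = XSD_INTEGER))
  }
  tt
}

source_typing_triples <- function(ctx, src_nodes, sourceClass) {
  if (is.na(sourceClass)) return(tripleTable())
  tripleTable(unique(src_nodes), RDF_TYPE, class_uri(ctx@schema, sourceClass))
}

#' Contextualize sourced assertions (PaCE encoding)
#'
#' Emits, per assertion, one contextualized assertion triple whose
#' subject, predicate and object are IRIs minted from the assertion's
#' source context, plus provenance-attachment triples linking the subject
#' only (`minimal`), subject and predicate (`intermediate`), or subject,
#' predicate and object (`exhaustive`) to the source node via the
#' context's linking property. Optional `rdf:type` triples are emitted
#' when component classes are supplied, and confidence/publication-date
#' annotations are attached to the subject. The output contains no blank
#' nodes and no reification vocabulary. In `intermediate` mode the
#' assumption that the object shares the subject's source is recorded in
#' the graph metadata (`assumes_shared_object_source`).
#'
#' @param assertions a [SourcedAssertion-class], a list of them, or an
#'   assertion data.frame (columns subject, predicate, object, source_id,
#'   optionally source_type, publication_date, version, confidence,
#'   subject_class, predicate_class, object_class).
#' @param mode `"minimal"`, `"intermediate"` or `"exhaustive"`.
#' @param ctx a [ProvenanceContext-class].
#' @param sourceClass optional schema class name used to type source
#'   nodes.
#' @return a labeled [ProvenanceGraph-class] ("data" for assertion/type
#'   triples, "provenance" for attachment, source and annotation triples).
#' @export
contextualize <- function(assertions, mode = c("minimal", "intermediate",
                                               "exhaustive"),
                          ctx, sourceClass = NA_character_) {
  if (length(mode) == 1L && !mode %in% c("minimal", "intermediate", "exhaustive"))
    stop("mode error: unknown PaCE mode '", mode, "'")
  mode <- match.arg(mode)
  at <- as_assertion_table(assertions)
  link <- property_uri(ctx@schema, ctx@linkingProperty)
  tt <- tripleTable(); lab <- character()
  emit <- function(df, label) {
    tt <<- rbind(tt, df)
    lab <<- c(lab, rep(label, nrow(df)))
  }
  for (i in seq_len(nrow(at))) {
    a <- at[i, ]
    if (!all(nzchar(c(a$subject, a$predicate, a$object))))
      stop("assertion ", i, " has empty component name(s)")
    cstr <- a$source_id
    s <- renderUri(mintUri(ctx@baseUri, cstr, normalize_entity_name(a$subject)))
    p <- renderUri(mintUri(ctx@baseUri, cstr, normalize_entity_name(a$predicate)))
    o <- renderUri(mintUri(ctx@baseUri, cstr, normalize_entity_name(a$object)))
    src <- source_node_iri(ctx@baseUri, a$source_id)
    emit(tripleTable(s, p, o), "data")
    attach_to <- switch(mode, minimal = s, intermediate = c(s, p),
                        exhaustive = c(s, p, o))
    emit(tripleTable(attach_to, link, src), "provenance")
    for (comp in list(c(a$subject_class, s), c(a$predicate_class, p),
                      c(a$object_class, o))) {
      if (!is.na(comp[1]))
        emit(tripleTable(comp[2], RDF_TYPE, class_uri(ctx@schema, comp[1])),
             "data")
    }
    emit(annotation_triples(s, a$publication_date, a$confidence), "provenance")
  }
  src_nodes <- source_node_iri(ctx@baseUri, at$source_id)
  emit(source_typing_triples(ctx, src_nodes, sourceClass), "provenance")
  meta <- list(pace_mode = mode)
  if (mode == "intermediate") meta$assumes_shared_object_source <- TRUE
  provenanceGraph(tt, schema = ctx@schema, metadata = meta, labels = lab)
}

#' Encode sourced assertions with the RDF reification vocabulary
#'
#' The baseline PaCE replaces: each assertion becomes a statement node
#' with exactly four reification-artifact triples (`rdf:type
#' rdf:Statement`, `rdf:subject`, `rdf:predicate`, `rdf:object`) plus one
#' provenance-attachment triple from the statement node to the source.
#' The artifact triples model no provenance — they are syntax overhead,
#' which is the motivation for the PaCE encodings.
#'
#' @inheritParams contextualize
#' @return a labeled [ProvenanceGraph-class]; artifact triples are
#'   labeled "provenance" (they exist only to carry provenance), as are
#'   attachment and annotation triples.
#' @export
reify <- function(assertions, ctx, sourceClass = NA_character_) {
  at <- as_assertion_table(assertions)
  link <- property_uri(ctx@schema, ctx@linkingProperty)
  tt <- tripleTable(); lab <- character()
  emit <- function(df, label) {
    tt <<- rbind(tt, df)
    lab <<- c(lab, rep(label, nrow(df)))
  }
  for (i in seq_len(nrow(at))) {
    a <- at[i, ]
    s <- paste0(ctx@baseUri, "/", percent_encode(normalize_entity_name(a$subject)))
    p <- paste0(ctx@baseUri, "/", percent_encode(normalize_entity_name(a$predicate)))
    o <- paste0(ctx@baseUri, "/", percent_encode(normalize_entity_name(a$object)))
    st <- paste0(ctx@baseUri, "/statement/", percent_encode(a$source_id), "/", i)
    src <- source_node_iri(ctx@baseUri, a$source_id)
    emit(tripleTable(s, p, o), "data")
    emit(tripleTable(rep(st, 4),
                     c(RDF_TYPE, RDF_SUBJECT, RDF_PREDICATE, RDF_OBJECT),
                     c(RDF_STATEMENT, s, p, o)), "provenance")
    emit(tripleTable(st, link, src), "provenance")
    for (comp in list(c(a$subject_class, s), c(a$predicate_class, p),
                      c(a$object_class, o))) {
      if (!is.na(comp[1]))
        emit(tripleTable(comp[2], RDF_TYPE, class_uri(ctx@schema, comp[1])),
             "data")
    }
    emit(annotation_triples(st, a$publication_date, a$confidence), "provenance")
  }
  src_nodes <- source_node_iri(ctx@baseUri, at$source_id)
  emit(source_typing_triples(ctx, src_nodes, sourceClass), "provenance")
  provenanceGraph(tt, schema = ctx@schema,
                  metadata = list(pace_mode = "reification"), labels = lab)
}

#' Group contextualized IRIs by their provenance context
#'
#' Every contextualized IRI minted under the context's base prefix is
#' placed under exactly one key, its provenance context string; IRIs
#' outside the base prefix are ignored, as are the reserved `source/` and
#' `statement/` path segments used for source and reified-statement
#' nodes.
#'
#' @param graph a [ProvenanceGraph-class].
#' @param ctx a [ProvenanceContext-class].
#' @return named list: context string -> sorted character vector of IRIs.
#' @export
groupByContext <- function(graph, ctx) {
  prefix <- paste0(ctx@baseUri, "/")
  nodes <- graphNodes(graph)
  nodes <- nodes[startsWith(nodes, prefix)]
  out <- list()
  for (n in nodes) {
    rest <- substring(n, nchar(prefix) + 1L)
    parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) next
    key <- percent_decode(parts[1])
    if (key %in% c("source", "statement")) next
    out[[key]] <- c(out[[key]], n)
  }
  if (!length(out)) return(list())
  lapply(out[order(names(out))], function(v) sort(unique(v)))
}

#' Triple-count summary per provenance encoding
#'
#' Runs the requested encodings over the assertion batch and reports, per
#' encoding, the total number of emitted triples and the number of
#' provenance-specific triples (attachment, source, annotation, and — for
#' reification — syntactic artifact triples).
#'
#' @param assertions assertions accepted by [contextualize()].
#' @param ctx a [ProvenanceContext-class].
#' @param encodings subset of
#'   `c("minimal", "intermediate", "exhaustive", "reification")`.
#' @param sourceClass optional schema class for source-node typing.
#' @return data.frame with columns encoding, total_triples,
#'   provenance_triples.
#' @export
countProvenanceTriples <- function(assertions, ctx,
                                   encodings = c("minimal", "intermediate",
                                                 "exhaustive", "reification"),
                                   sourceClass = NA_character_) {
  rows <- lapply(encodings, function(enc) {
    g <- if (enc == "reification") reify(assertions, ctx, sourceClass)
         else contextualize(assertions, enc, ctx, sourceClass)
    data.frame(encoding = enc, total_triples = tripleCount(g),
               provenance_triples = sum(tripleLabels(g) == "provenance"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

setMethod("show", "SourcedAssertion", function(object) {
  cat("SourcedAssertion:", object@subjectName, "->", object@predicateName,
      "->", object@objectName, sprintf("[%s]", object@source@sourceId), "\n")
})

setMethod("show", "ProvenanceContext", function(object) {
  cat("ProvenanceContext under", object@baseUri, "\n")
  cat("  terms:", if (length(object@contextTerms))
        paste(object@contextTerms, collapse = ", ") else "(none)", "\n")
  cat("  linking property:", object@linkingProperty, "\n")
})
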