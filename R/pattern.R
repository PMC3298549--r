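## Provenance patterns: validation against a schema and form-value
## instantiation into RDF (the computational core of ontology-driven
## annotation-form tooling).

#' Create a provenance pattern
#'
#' A pattern is an ordered chain of schema classes; each element after the
#' first is connected to its predecessor by a schema property (subject =
#' previous element, object = current element).
#'
#' @param classes character vector of class names.
#' @param properties character vector of connecting property names, length
#'   `length(classes) - 1` (or empty for a single-element pattern).
#' @return a [ProvenancePattern-class].
#' @examples
#' provenancePattern(c("gene_knockout_process", "researcher"), "has_agent")
#' @export
provenancePattern <- function(classes, properties = character()) {
  classes <- as.character(classes)
  properties <- as.character(properties)
  if (length(classes) == 0L) {
    el <- data.frame(class = character(), property = character(),
                     stringsAsFactors = FALSE)
  } else {
    if (length(properties) != length(classes) - 1L)
      stop("need one connecting property per element after the first")
    el <- data.frame(class = classes,
                     property = c(NA_character_, properties),
                     stringsAsFactors = FALSE)
  }
  new("ProvenancePattern", elements = el)
}

#' Read a provenance pattern from a YAML/JSON config file
#'
#' Config schema: a mapping with key `elements`, a list of
#' `{class, property}` entries (`property` omitted for the first element).
#'
#' @param path config file path.
#' @return a [ProvenancePattern-class].
#' @export
readPatternConfig <- function(path) {
  cfg <- read_config_file(path)
  unknown <- setdiff(names(cfg), "elements")
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cls <- vapply(cfg$elements, function(x) x$class, character(1))
  prp <- vapply(cfg$elements[-1], function(x) x$property %||% NA_character_,
                character(1))
  provenancePattern(cls, prp)
}

#' Validate a pattern against a schema
#'
#' For each element the report records whether the class exists in the
#' schema and whether the connecting property is domain/range compatible:
#' the previous element's class must be a subclass of (or equal to) the
#' property's declared domain and the current element's class a subclass
#' of its declared range. Violations are reported, never raised.
#'
#' @param pattern a [ProvenancePattern-class].
#' @param schema an [OntologySchema-class].
#' @return a list with `valid` (logical) and `report` (data.frame with one
#'   row per element: class, class_known, property, property_known,
#'   domain_ok, range_ok, message).
#' @export
validatePattern <- function(pattern, schema) {
  el <- pattern@elements
  n <- nrow(el)
  rep_df <- data.frame(class = el$class, class_known = logical(n),
                       property = el$property, property_known = rep(NA, n),
                       domain_ok = rep(NA, n), range_ok = rep(NA, n),
                       message = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cls <- el$class[i]
    rep_df$class_known[i] <- cls %in% schema@classes$name
    msg <- character()
    if (!rep_df$class_known[i]) msg <- c(msg, sprintf("unknown class '%s'", cls))
    prop <- el$property[i]
    if (!is.na(prop)) {
      known <- prop %in% schema@properties$name
      rep_df$property_known[i] <- known
      if (!known) {
        msg <- c(msg, sprintf("unknown property '%s'", prop))
      } else {
        pd <- schema@properties[schema@properties$name == prop, ]
        prev_cls <- el$class[i - 1L]
        dom_ok <- rep_df$class_known[i - 1L] && isSubclassOf(schema, prev_cls, pd$domain)
        rng_ok <- if (grepl("://", pd$range)) FALSE
                  else rep_df$class_known[i] && isSubclassOf(schema, cls, pd$range)
        rep_df$domain_ok[i] <- dom_ok
        rep_df$range_ok[i] <- rng_ok
        if (!dom_ok)
          msg <- c(msg, sprintf("'%s' is not in the domain of '%s' (%s)",
                                prev_cls, prop, pd$domain))
        if (!rng_ok)
          msg <- c(msg, sprintf("'%s' is not in the range of '%s' (%s)",
                                cls, prop, pd$range))
      }
    }
    rep_df$message[i] <- paste(msg, collapse = "; ")
  }
  list(valid = all(rep_df$message == ""), report = rep_df)
}

#' Mark a form value as an identifier rather than a literal
#'
#' Values passed to [instantiatePattern()] are literals by default; wrap a
#' value with `iriValue()` to supply a caller-chosen instance IRI instead.
#'
#' @param x an absolute IRI.
#' @export
iriValue <- function(x) structure(as.character(x), class = "provenir_iri")

#' Instantiate a validated pattern with form values
#'
#' Emits, per pattern element, an instance node typed to its class
#' (`rdf:type`) and an `rdf:value` triple when the supplied value is a
#' literal; consecutive elements are linked with the pattern's connecting
#' property. Field names are matched to element class names
#' (case-insensitively). Elements listed in `skip` are instantiated
#' without a value triple. Instance IRIs are
#' `instanceNamespace + class + "/" + counter` unless the value is an
#' [iriValue()]; generation is deterministic given the inputs.
#'
#' @param pattern a [ProvenancePattern-class], valid under `schema`.
#' @param values named list: field (class) name -> literal or [iriValue()].
#' @param schema an [OntologySchema-class].
#' @param instanceNamespace IRI prefix for minted instance nodes.
#' @param skip character vector of element class names instantiated
#'   without a value.
#' @return a [ProvenanceGraph-class] of the emitted triples.
#' @examples
#' sc <- demoExtensionSchema()
#' pat <- provenancePattern(c("gene_knockout_process", "priority"),
#'                          "has_parameter")
#' g <- instantiatePattern(pat, list(Priority = "High"), sc,
#'                         skip = "gene_knockout_process")
#' @export
instantiatePattern <- function(pattern, values, schema,
                               instanceNamespace = "http://example.org/instance/",
                               skip = character()) {
  vr <- validatePattern(pattern, schema)
  if (!vr$valid)
    stop("pattern invalid under schema: ",
         paste(vr$report$message[vr$report$message != ""], collapse = "; "))
  el <- pattern@elements
  fields <- tolower(names(values) %||% character())
  known <- tolower(c(el$class, skip))
  if (length(fields) && any(!fields %in% known))
    stop("instantiation error: value(s) for unknown field(s): ",
         paste(names(values)[!fields %in% known], collapse = ", "))

  tt <- tripleTable()
  nodes <- character(nrow(el))
  for (i in seq_len(nrow(el))) {
    cls <- el$class[i]
    hit <- match(tolower(cls), fields)
    val <- if (!is.na(hit)) values[[hit]] else NULL
    skipped <- tolower(cls) %in% tolower(skip)
    if (is.null(val) && !skipped)
      stop("instantiation error: element '", cls,
           "' has no value and is not marked skipped")
    if (inherits(val, "provenir_iri")) {
      node <- as.character(val)
      lit <- NULL
    } else {
      node <- paste0(instanceNamespace, percent_encode(cls), "/", i)
      lit <- val
    }
    nodes[i] <- node
    tt <- rbind(tt, tripleTable(node, RDF_TYPE, class_uri(schema, cls)))
    if (!is.null(lit) && !skipped) {
      dtype <- datatype_for_value(lit)
      if (!is.null(dtype$error)) stop("datatype error: ", dtype$error)
      tt <- rbind(tt, tripleTable(node, RDF_VALUE, dtype$lexical,
                                  o_type = "literal", o_datatype = dtype$iri))
    }
    if (i > 1L)
      tt <- rbind(tt, tripleTable(nodes[i - 1L],
                                  property_uri(schema, el$property[i]),
                                  node))
  }
  provenanceGraph(tt, schema = schema)
}

# Literal values are typed as plain strings unless the R value carries a
# more specific type.
datatype_for_value <- function(v) {
  if (is.numeric(v) && length(v) == 1L) {
    if (is.na(v)) return(list(error = "missing numeric value"))
    lex <- format(v, scientific = FALSE, trim = TRUE)
    iri <- if (v == round(v) && is.integer(v)) XSD_INTEGER else XSD_DOUBLE
    return(list(lexical = lex, iri = iri))
  }
  if (is.logical(v) && length(v) == 1L)
    return(list(lexical = tolower(as.character(v)), iri = XSD_BOOLEAN))
  if (is.character(v) && length(v) == 1L)
    return(list(lexical = v, iri = NA_character_))
  list(error = paste("unsupported value of class", class(v)[1]))
}

setMethod("show", "ProvenancePattern", function(object) {
  el <- object@elements
  if (!nrow(el)) { cat("ProvenancePattern: empty\n"); return(invisible()) }
  parts <- el$class[1]
  for (i in seq_len(nrow(el))[-1])
    parts <- paste0(parts, " -", el$property[i], "-> ", el$class[i])
  cat("ProvenancePattern:", parts, "\n")
})
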