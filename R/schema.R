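## Upper-level provenance schema: construction, extension, closure.

#' Create a class definition
#'
#' @param name class identifier (unique within a schema).
#' @param parent name of the parent class, or `NA` for top-level.
#' @param uri absolute IRI; minted from the schema base namespace when the
#'   class is added if omitted.
#' @return a [ClassDef-class].
#' @export
classDef <- function(name, parent = NA_character_, uri = NA_character_) {
  new("ClassDef", name = as.character(name), parent = as.character(parent),
      uri = as.character(uri))
}

#' Create a property definition
#'
#' @param name property identifier.
#' @param domain,range schema class names; `range` may instead be a
#'   datatype IRI (e.g. `xsd:string`) to declare a literal-valued property.
#' @param parent parent property name or `NA`.
#' @param uri absolute IRI (minted from the base namespace if omitted).
#' @return a [PropertyDef-class].
#' @export
propertyDef <- function(name, domain, range, parent = NA_character_,
                        uri = NA_character_) {
  new("PropertyDef", name = as.character(name), domain = as.character(domain),
      range = as.character(range), parent = as.character(parent),
      uri = as.character(uri))
}

new_schema <- function(baseNamespace, classes, properties) {
  classes$uri <- ifelse(is.na(classes$uri),
                        paste0(baseNamespace, classes$name), classes$uri)
  if (nrow(properties))
    properties$uri <- ifelse(is.na(properties$uri),
                             paste0(baseNamespace, properties$name),
                             properties$uri)
  new("OntologySchema", baseNamespace = baseNamespace,
      classes = classes, properties = properties)
}

#' The default Provenir upper-level provenance schema
#'
#' Returns the upper-level schema with three top-level classes (`data`,
#' `process`, `agent`), the `data_collection` and `parameter` subclasses of
#' `data`, the spatial/temporal/domain specializations of `parameter`
#' (8 classes in total), and the default registry of 11 named
#' relationships. Ten of the relationship names are adapted from the
#' Relation ontology; `has_temporal_value` links data to temporal
#' parameters. The registry is configurable via [extendSchema()]; the
#' properties `preceded_by`, `derives_from`, `has_agent`,
#' `has_participant` and `has_parameter` are relied on by the query
#' operators.
#'
#' @param baseNamespace IRI prefix for the schema vocabulary.
#' @return an [OntologySchema-class] with exactly 8 classes and 11
#'   properties. Repeated calls return structurally identical schemas.
#' @examples
#' sc <- defaultProvenirSchema()
#' nrow(schemaClasses(sc))     # 8
#' nrow(schemaProperties(sc))  # 11
#' @export
defaultProvenirSchema <- function(baseNamespace = PROVENIR_NS) {
  cls <- data.frame(
    name = c("data", "process", "agent",
             "data_collection", "parameter",
             "spatial_parameter", "temporal_parameter", "domain_parameter"),
    parent = c(NA, NA, NA, "data", "data",
               "parameter", "parameter", "parameter"),
    uri = NA_character_,
    stringsAsFactors = FALSE)
  prp <- data.frame(
    name = c("part_of", "contained_in", "located_in", "adjacent_to",
             "transformation_of", "derives_from", "preceded_by",
             "has_participant", "has_agent", "has_parameter",
             "has_temporal_value"),
    parent = NA_character_,
    domain = c("process", "data", "data", "data",
               "data", "data", "process",
               "process", "process", "process", "data"),
    range = c("process", "data", "spatial_parameter", "data",
              "data", "data", "process",
              "data", "agent", "parameter", "temporal_parameter"),
    uri = NA_character_,
    stringsAsFactors = FALSE)
  new_schema(baseNamespace, cls, prp)
}

#' Schema registry accessors
#'
#' `schemaClasses()` returns the class registry (name, uri, parent);
#' `schemaProperties()` the property registry (name, uri, parent, domain,
#' range).
#'
#' @param schema an [OntologySchema-class].
#' @return a data.frame registry.
#' @rdname schemaAccessors
#' @export
schemaClasses <- function(schema) schema@classes

#' @rdname schemaAccessors
#' @export
schemaProperties <- function(schema) schema@properties

class_uri <- function(schema, name) {
  i <- match(name, schema@classes$name)
  if (anyNA(i)) stop("unknown class: ", paste(name[is.na(i)], collapse = ", "))
  schema@classes$uri[i]
}

property_uri <- function(schema, name) {
  i <- match(name, schema@properties$name)
  if (anyNA(i)) stop("unknown property: ", paste(name[is.na(i)], collapse = ", "))
  schema@properties$uri[i]
}

class_name_from_uri <- function(schema, uri) {
  schema@classes$name[match(uri, schema@classes$uri)]
}

#' Extend a schema with new classes and properties
#'
#' Extensions use the standard subclass/subproperty mechanism: every new
#' class or property must name a parent reachable in the base schema or
#' among the new items (top-level additions with `NA` parents are also
#' accepted for domain roots). The base schema is never modified; the
#' returned schema is a strict superset (monotone extension).
#'
#' @param base an [OntologySchema-class].
#' @param newClasses list of [ClassDef-class] objects.
#' @param newProperties list of [PropertyDef-class] objects.
#' @return the merged [OntologySchema-class].
#' @export
extendSchema <- function(base, newClasses = list(), newProperties = list()) {
  stopifnot(is(base, "OntologySchema"))
  add_cl <- do.call(rbind, c(list(base@classes[0, ]), lapply(newClasses, function(x) {
    stopifnot(is(x, "ClassDef"))
    data.frame(name = x@name, parent = x@parent, uri = x@uri,
               stringsAsFactors = FALSE)
  })))
  add_pr <- do.call(rbind, c(list(base@properties[0, ]), lapply(newProperties, function(x) {
    stopifnot(is(x, "PropertyDef"))
    data.frame(name = x@name, parent = x@parent, domain = x@domain,
               range = x@range, uri = x@uri, stringsAsFactors = FALSE)
  })))
  all_cl_names <- c(base@classes$name, add_cl$name)
  dangling <- !is.na(add_cl$parent) & !(add_cl$parent %in% all_cl_names)
  if (any(dangling))
    stop("extension error: unknown parent class(es): ",
         paste(unique(add_cl$parent[dangling]), collapse = ", "))
  all_pr_names <- c(base@properties$name, add_pr$name)
  dangling_p <- !is.na(add_pr$parent) & !(add_pr$parent %in% all_pr_names)
  if (any(dangling_p))
    stop("extension error: unknown parent property(ies): ",
         paste(unique(add_pr$parent[dangling_p]), collapse = ", "))

  classes <- rbind(base@classes, add_cl)
  properties <- rbind(base@properties, add_pr)
  cyc <- schema_parent_acyclic(classes)
  if (!isTRUE(cyc))
    stop("cycle error: subclass cycle ", paste(cyc, collapse = " -> "))
  pcyc <- schema_parent_acyclic(properties)
  if (!isTRUE(pcyc))
    stop("cycle error: subproperty cycle ", paste(pcyc, collapse = " -> "))

  out <- new_schema(base@baseNamespace, classes, properties)
  # child property's domain/range must specialize (or equal) the parent's
  if (nrow(add_pr)) {
    for (i in seq_len(nrow(out@properties))) {
      p <- out@properties[i, ]
      if (is.na(p$parent)) next
      par <- out@properties[out@properties$name == p$parent, ]
      if (!isSubclassOf(out, p$domain, par$domain))
        stop("extension error: domain of '", p$name,
             "' is not a subclass of its parent's domain")
      dt_child <- grepl("://", p$range); dt_par <- grepl("://", par$range)
      range_ok <- if (dt_child || dt_par) identical(p$range, par$range)
                  else isSubclassOf(out, p$range, par$range)
      if (!range_ok)
        stop("extension error: range of '", p$name,
             "' is not a subclass of its parent's range")
    }
  }
  validObject(out)
  out
}

#' Is `a` a (reflexive, transitive) subclass of `b`?
#'
#' @param schema an [OntologySchema-class].
#' @param a,b class names.
#' @export
isSubclassOf <- function(schema, a, b) {
  if (is.na(a) || is.na(b)) return(FALSE)
  parent <- stats::setNames(schema@classes$parent, schema@classes$name)
  cur <- a
  while (!is.na(cur)) {
    if (cur == b) return(TRUE)
    cur <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
  }
  FALSE
}

#' Reflexive-transitive subclass closure of a class
#'
#' Used for RDFS-entailment expansion of query patterns: returns `cls`
#' together with every class reachable from it by inverse parent edges.
#'
#' @param schema an [OntologySchema-class].
#' @param cls a class name present in the schema.
#' @return character vector of class names (sorted, includes `cls`).
#' @examples
#' subclassesOf(defaultProvenirSchema(), "parameter")
#' @export
subclassesOf <- function(schema, cls) {
  if (!cls %in% schema@classes$name)
    stop("lookup error: unknown class '", cls, "'")
  out <- cls
  repeat {
    more <- schema@classes$name[schema@classes$parent %in% out &
                                !(schema@classes$name %in% out)]
    if (!length(more)) break
    out <- c(out, more)
  }
  sort(out)
}

#' Reflexive-transitive subproperty closure of a property
#'
#' @param schema an [OntologySchema-class].
#' @param prop a property name present in the schema.
#' @return character vector of property names.
#' @export
subpropertiesOf <- function(schema, prop) {
  if (!prop %in% schema@properties$name)
    stop("lookup error: unknown property '", prop, "'")
  out <- prop
  repeat {
    more <- schema@properties$name[schema@properties$parent %in% out &
                                   !(schema@properties$name %in% out)]
    if (!length(more)) break
    out <- c(out, more)
  }
  sort(out)
}

#' A small demo domain extension for parasite-experiment provenance
#'
#' A compact extension of the default schema in the style of a
#' parasite-experiment provenance ontology: reverse-genetics process
#' classes (gene knockout, transfection, drug selection, cloning, strain
#' creation), sample and plasmid data classes, researcher/instrument
#' agents, and experiment parameters (target gene, antibiotic, drug
#' concentration, temperature, priority, status). Purely illustrative; it
#' is the extension used by the synthetic protocol generator.
#'
#' @param base schema to extend (default [defaultProvenirSchema()]).
#' @return an [OntologySchema-class].
#' @export
demoExtensionSchema <- function(base = defaultProvenirSchema()) {
  ns <- "http://knoesis.wright.edu/demo/peo.owl#"
  cls <- list(
    classDef("gene_knockout_process", "process", paste0(ns, "gene_knockout_process")),
    classDef("transfection_process",  "process", paste0(ns, "transfection_process")),
    classDef("drug_selection_process","process", paste0(ns, "drug_selection_process")),
    classDef("cloning_process",       "process", paste0(ns, "cloning_process")),
    classDef("strain_creation_process","process", paste0(ns, "strain_creation_process")),
    classDef("sample",   "data_collection", paste0(ns, "sample")),
    classDef("plasmid",  "data_collection", paste0(ns, "plasmid")),
    classDef("researcher","agent",  paste0(ns, "researcher")),
    classDef("instrument","agent",  paste0(ns, "instrument")),
    classDef("target_gene",        "domain_parameter", paste0(ns, "target_gene")),
    classDef("antibiotic",         "domain_parameter", paste0(ns, "antibiotic")),
    classDef("drug_concentration", "domain_parameter", paste0(ns, "drug_concentration")),
    classDef("temperature",        "domain_parameter", paste0(ns, "temperature")),
    classDef("priority",           "domain_parameter", paste0(ns, "priority")),
    classDef("experiment_status",  "domain_parameter", paste0(ns, "experiment_status")),
    classDef("transfection_attempts", "domain_parameter",
             paste0(ns, "transfection_attempts")),
    classDef("selection_period",   "temporal_parameter",
             paste0(ns, "selection_period")))
  extendSchema(base, newClasses = cls)
}

#' Serialize a schema to RDFS triples
#'
#' Emits `owl:Class` / `owl:ObjectProperty` typing, `rdfs:subClassOf` /
#' `rdfs:subPropertyOf` hierarchy links, `rdfs:domain` / `rdfs:range`
#' assertions and `rdfs:label`s, as a [ProvenanceGraph-class] that can be
#' written in Turtle or RDF/XML with [writeGraph()].
#'
#' @param schema an [OntologySchema-class].
#' @return a [ProvenanceGraph-class] of schema (TBox) triples.
#' @export
schemaToGraph <- function(schema) {
  cl <- schema@classes; pr <- schema@properties
  tt <- rbind(
    tripleTable(cl$uri, RDF_TYPE, OWL_CLASS),
    tripleTable(cl$uri, RDFS_LABEL, cl$name, o_type = "literal"),
    {
      has_par <- !is.na(cl$parent)
      tripleTable(cl$uri[has_par], RDFS_SUBCLASSOF,
                  cl$uri[match(cl$parent[has_par], cl$name)])
    },
    tripleTable(pr$uri, RDF_TYPE, OWL_OBJECTPROPERTY),
    tripleTable(pr$uri, RDFS_LABEL, pr$name, o_type = "literal"),
    {
      has_par <- !is.na(pr$parent)
      tripleTable(pr$uri[has_par], RDFS_SUBPROPERTYOF,
                  pr$uri[match(pr$parent[has_par], pr$name)])
    },
    tripleTable(pr$uri, RDFS_DOMAIN, cl$uri[match(pr$domain, cl$name)]),
    {
      is_dt <- grepl("://", pr$range)
      rng_uri <- ifelse(is_dt, pr$range, cl$uri[match(pr$range, cl$name)])
      tripleTable(pr$uri, RDFS_RANGE, rng_uri)
    })
  provenanceGraph(tt, schema = schema)
}

#' Read a schema extension from a YAML/JSON config file
#'
#' The config is a mapping with optional `base_namespace`, `classes`
#' (list of `{name, parent, uri}`) and `properties` (list of
#' `{name, domain, range, parent, uri}`). The definitions are applied to
#' `base` via [extendSchema()]. Unknown keys are rejected.
#'
#' @param path config file path (.yaml/.yml/.json).
#' @param base schema to extend; defaults to [defaultProvenirSchema()].
#' @return an [OntologySchema-class].
#' @export
readSchemaConfig <- function(path, base = defaultProvenirSchema()) {
  cfg <- read_config_file(path)
  allowed <- c("base_namespace", "classes", "properties")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$base_namespace))
    base@baseNamespace <- cfg$base_namespace
  ncl <- lapply(cfg$classes, function(x)
    classDef(x$name, x$parent %||% NA_character_, x$uri %||% NA_character_))
  npr <- lapply(cfg$properties, function(x)
    propertyDef(x$name, x$domain, x$range, x$parent %||% NA_character_,
                x$uri %||% NA_character_))
  extendSchema(base, ncl, npr)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else
    yaml::read_yaml(path)
}

setMethod("show", "OntologySchema", function(object) {
  cat("OntologySchema:", nrow(object@classes), "classes,",
      nrow(object@properties), "properties\n")
  top <- object@classes$name[is.na(object@classes$parent)]
  cat("  top-level:", paste(top, collapse = ", "), "\n")
  cat("  namespace:", object@baseNamespace, "\n")
})
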