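## The four provenance query operators plus ASK-probe transitive closure.
## provenance() follows best-match semantics: absent components are
## omitted, never an error, so incomplete provenance shrinks the result
## instead of failing it.

role_property_uris <- function(schema, prop) {
  # a property and all its declared subproperties (RDFS entailment)
  property_uri(schema, subpropertiesOf(schema, prop))
}

#' Transitive closure over a property via SPARQL ASK probes
#'
#' Computes all instances reachable from `start` by repeatedly following
#' `property` edges (default the process/`preceded_by` combination),
#' issuing existence (ASK) probes of increasing path length and stopping
#' at the first `false`. A visited set guarantees termination on cyclic
#' graphs; the result is bounded by the node count. Nodes are returned in
#' discovery (depth) order, lexicographic among equal depths, excluding
#' `start`.
#'
#' @param graph a schema-backed [ProvenanceGraph-class].
#' @param start an IRI present in the graph.
#' @param property schema property name to traverse (subproperties are
#'   included via RDFS entailment).
#' @return character vector of reached IRIs in discovery order.
#' @export
transitiveClosure <- function(graph, start, property = "preceded_by") {
  schema <- graph@schema
  if (is.null(schema)) stop("graph has no schema")
  df <- graph@triples
  known <- unique(c(df$s, df$o[df$o_type == "iri"]))
  if (!start %in% known)
    stop("lookup error: start node not in graph: ", start)
  prop_uris <- role_property_uris(schema, property)

  visited <- start
  out <- character()
  k <- 1L
  max_depth <- length(known)
  while (k <= max_depth) {
    q <- closure_probe_query(start, prop_uris, k)
    if (!executeSparql(q$ask, graph)$boolean) break   # ASK returned false
    res <- executeSparql(q$select, graph)
    found <- sort(unique(stats::na.omit(res$bindings[[q$var]])))
    new <- setdiff(found, visited)
    if (!length(new)) break                            # cycle guard
    out <- c(out, new)
    visited <- c(visited, new)
    k <- k + 1L
  }
  out
}

# SPARQL ASK/SELECT pair probing for paths of length k from `start`.
closure_probe_query <- function(start, prop_uris, k) {
  vars <- paste0("?x", seq_len(k))
  subj <- c(paste0("<", start, ">"), vars[-k])
  prop_term <- if (length(prop_uris) == 1L) paste0("<", prop_uris, ">")
               else paste0("?pp", seq_len(k))
  bgp <- paste0("  ", subj, " ", prop_term, " ", vars, " .")
  filt <- if (length(prop_uris) > 1L)
    vapply(seq_len(k), function(i) sprintf(
      "  FILTER(?pp%d IN (%s))", i,
      paste0("<", prop_uris, ">", collapse = ", ")), character(1))
  else character()
  body <- paste(c(bgp, filt), collapse = "\n")
  list(ask = sprintf("ASK WHERE {\n%s\n}", body),
       select = sprintf("SELECT DISTINCT %s WHERE {\n%s\n}", vars[k], body),
       var = sub("^\\?", "", vars[k]))
}

edge_objects <- function(df, subjects, prop_uris) {
  unique(df$o[df$s %in% subjects & df$p %in% prop_uris & df$o_type == "iri"])
}

edge_subjects <- function(df, objects, prop_uris) {
  unique(df$s[df$o %in% objects & df$p %in% prop_uris & df$o_type == "iri"])
}

#' Retrieve the provenance of a data entity
#'
#' Returns the maximal best-match provenance subgraph of `entity`: its
#' derivation chain (transitive `derives_from`), the processes that
#' consumed or produced those data entities, the full `preceded_by`
#' closure of these processes, their agents, participants and parameters,
#' and the type and literal triples of everything pulled in. Components
#' absent from the graph are simply omitted.
#'
#' @param graph a schema-backed [ProvenanceGraph-class].
#' @param entity an IRI that is an instance of `data_collection` (or a
#'   subclass).
#' @return a [ProvenanceGraph-class].
#' @export
provenance <- function(graph, entity) {
  schema <- graph@schema
  if (is.null(schema)) stop("graph has no schema")
  df <- graph@triples
  known <- unique(c(df$s, df$o[df$o_type == "iri"]))
  if (!entity %in% known)
    stop("lookup error: entity not in graph: ", entity)
  if (!is_instance_of(graph, entity, "data_collection"))
    stop("precondition error: entity is not a data_collection instance: ",
         entity)

  p_df  <- role_property_uris(schema, "derives_from")
  p_pb  <- role_property_uris(schema, "preceded_by")
  p_ag  <- role_property_uris(schema, "has_agent")
  p_pt  <- role_property_uris(schema, "has_participant")
  p_pm  <- role_property_uris(schema, "has_parameter")

  D <- unique(c(entity, transitiveClosure(graph, entity, "derives_from")))
  P0 <- edge_subjects(df, D, p_pt)
  P <- unique(c(P0, unlist(lapply(P0, transitiveClosure, graph = graph,
                                  property = "preceded_by"))))
  agents <- edge_objects(df, P, p_ag)
  participants <- edge_objects(df, P, p_pt)
  params <- edge_objects(df, P, p_pm)
  N <- unique(c(D, P, agents, participants, params))

  keep <- (df$s == entity) | (df$o_type == "iri" & df$o == entity) |
    (df$p %in% p_df & df$s %in% D & df$o %in% D) |
    (df$p %in% p_pb & df$s %in% P & df$o %in% P) |
    (df$p %in% c(p_ag, p_pt, p_pm) & df$s %in% P) |
    (df$p == RDF_TYPE & df$s %in% N) |
    (df$o_type == "literal" & df$s %in% N)
  provenanceGraph(df[keep, , drop = FALSE], schema = schema,
                  labels = if (length(graph@labels)) graph@labels[keep]
                           else character())
}

#' ProvenanceConstraint: one condition on an entity's provenance
#'
#' @slot target a schema class name, a schema/annotation property name
#'   (`confidence`, `year`, `publication_date`, `impact_factor`,
#'   `source_version`, `value`), or a full property IRI.
#' @slot comparator one of `=`, `<`, `>`, `<=`, `>=`, `contains`.
#' @slot value the literal compared against.
#' @export
setClass("ProvenanceConstraint",
         representation(target = "character", comparator = "character",
                        value = "ANY"))

#' Create a provenance constraint
#'
#' @param target see [ProvenanceConstraint-class].
#' @param comparator `=`, `<`, `>`, `<=`, `>=` or `contains`.
#' @param value literal value (numeric for ordering comparators).
#' @return a [ProvenanceConstraint-class].
#' @export
provenanceConstraint <- function(target, comparator, value) {
  comparator <- match.arg(comparator, c("=", "<", ">", "<=", ">=", "contains"))
  if (comparator %in% c("<", ">", "<=", ">=") && !is.numeric(value))
    stop("ordering comparators require a numeric value")
  if (comparator == "contains" && !is.character(value))
    stop("'contains' requires a character value")
  new("ProvenanceConstraint", target = target, comparator = comparator,
      value = value)
}

ANNOTATION_PROPERTY_MAP <- c(confidence = NA, year = NA, publication_date = NA,
                             impact_factor = NA, source_version = NA,
                             value = NA)

resolve_constraint_target <- function(schema, target) {
  anno_map <- c(confidence = ANNO_CONFIDENCE, year = ANNO_YEAR,
                publication_date = ANNO_PUB_DATE,
                impact_factor = ANNO_IMPACTFACTOR,
                source_version = ANNO_VERSION, value = RDF_VALUE,
                label = ANNO_LABEL)
  if (target %in% schema@classes$name)
    return(list(kind = "class", uris = class_uri(
      schema, subclassesOf(schema, target))))
  if (target %in% schema@properties$name)
    return(list(kind = "property", uris = role_property_uris(schema, target)))
  if (target %in% names(anno_map))
    return(list(kind = "property", uris = unname(anno_map[target])))
  if (grepl("://", target))
    return(list(kind = "property", uris = target))
  stop("constraint error: unknown class/property '", target, "'")
}

compare_literals <- function(values, comparator, ref) {
  if (comparator == "contains")
    return(any(grepl(as.character(ref), values, fixed = TRUE)))
  if (comparator == "=") {
    num <- suppressWarnings(as.numeric(values))
    if (is.numeric(ref) && any(!is.na(num)))
      return(any(num == as.numeric(ref), na.rm = TRUE))
    return(any(values == as.character(ref)))
  }
  num <- suppressWarnings(as.numeric(values))
  ref <- as.numeric(ref)
  any(switch(comparator,
             "<" = num < ref, ">" = num > ref,
             "<=" = num <= ref, ">=" = num >= ref), na.rm = TRUE)
}

#' Retrieve data entities satisfying provenance constraints
#'
#' Evaluates each constraint (conjunctively) against the provenance
#' subgraph of every `data_collection` instance in the graph and returns
#' the entities whose provenance satisfies all of them. An empty
#' constraint list returns all data entities.
#'
#' @param graph a schema-backed [ProvenanceGraph-class].
#' @param constraints list of [ProvenanceConstraint-class] objects.
#' @return sorted character vector of entity IRIs.
#' @export
provenanceContext <- function(graph, constraints = list()) {
  schema <- graph@schema
  if (is.null(schema)) stop("graph has no schema")
  targets <- lapply(constraints, function(con)
    resolve_constraint_target(schema, con@target))
  candidates <- instances_of(graph, "data_collection")
  ok <- vapply(candidates, function(e) {
    sub <- provenance(graph, e)
    sdf <- sub@triples
    for (i in seq_along(constraints)) {
      con <- constraints[[i]]; tg <- targets[[i]]
      sat <- if (tg$kind == "class") {
        any(sdf$p == RDF_TYPE & sdf$o %in% tg$uris)
      } else {
        vals <- sdf$o[sdf$p %in% tg$uris & sdf$o_type == "literal"]
        length(vals) > 0 && compare_literals(vals, con@comparator, con@value)
      }
      if (!sat) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(candidates[ok])
}

## ---- provenance_compare ----------------------------------------------------

# Canonical form of a provenance graph under identifier abstraction:
# instance IRIs are replaced by Weisfeiler-Lehman colours; literals and
# schema class/property IRIs are kept verbatim.
canonical_provenance_form <- function(graph, tol = 0) {
  schema <- graph@schema
  df <- graph@triples
  kept <- unique(c(reserved_vocabulary(), XSD_STRING, XSD_INTEGER,
                   XSD_DECIMAL, XSD_DOUBLE, XSD_DATE, XSD_BOOLEAN,
                   if (!is.null(schema)) c(schema@classes$uri,
                                           schema@properties$uri)))
  if (tol > 0 && nrow(df)) {
    num_dt <- c(XSD_INTEGER, XSD_DECIMAL, XSD_DOUBLE)
    idx <- which(df$o_type == "literal" & df$o_datatype %in% num_dt)
    if (length(idx)) {
      v <- suppressWarnings(as.numeric(df$o[idx]))
      df$o[idx] <- ifelse(is.na(v), df$o[idx],
                          format(round(v / tol) * tol, scientific = FALSE,
                                 trim = TRUE))
    }
  }
  inst <- setdiff(unique(c(df$s, df$o[df$o_type == "iri"])), kept)
  if (!length(inst)) {
    lines <- paste(df$s, df$p, df$o, df$o_type, df$o_datatype)
    return(sort(lines))
  }
  colour <- stats::setNames(rep("0", length(inst)), inst)
  term_of <- function(x) ifelse(x %in% inst, paste0("~", colour[x]), x)
  for (iter in seq_len(length(inst) + 2L)) {
    sigs <- vapply(inst, function(v) {
      out_rows <- df[df$s == v, , drop = FALSE]
      in_rows <- df[df$o == v & df$o_type == "iri", , drop = FALSE]
      sig <- c(paste0(">", out_rows$p, "|",
                      ifelse(out_rows$o_type == "literal",
                             paste0("L", out_rows$o, "^", out_rows$o_datatype),
                             term_of(out_rows$o))),
               paste0("<", in_rows$p, "|", term_of(in_rows$s)))
      rlang::hash(c(colour[[v]], sort(sig)))
    }, character(1))
    new_colour <- stats::setNames(
      as.character(match(sigs, sort(unique(sigs)))), inst)
    if (identical(unname(new_colour[inst]), unname(colour[inst]))) break
    colour <- new_colour
  }
  s_term <- term_of(df$s)
  o_term <- ifelse(df$o_type == "literal", df$o, term_of(df$o))
  sort(paste(s_term, df$p, o_term, df$o_type, df$o_datatype))
}

#' Were two datasets generated under equivalent conditions?
#'
#' Compares two provenance graphs for equivalence up to instance
#' identifiers: instance IRIs are abstracted to anonymous nodes (via
#' colour refinement) while literals and schema class/property IRIs are
#' kept, and the abstracted triple multisets are compared. Reflexive and
#' symmetric. Literal comparison is exact by default; `tol` rounds
#' numeric parameter literals to a tolerance grid first.
#'
#' @param g1,g2 non-empty [ProvenanceGraph-class] objects.
#' @param tol numeric tolerance for numeric literals (0 = exact).
#' @return TRUE iff the two provenance graphs are equivalent.
#' @export
provenanceCompare <- function(g1, g2, tol = 0) {
  if (!tripleCount(g1) || !tripleCount(g2))
    stop("both graphs must be non-empty")
  identical(canonical_provenance_form(g1, tol),
            canonical_provenance_form(g2, tol))
}

## ---- provenance_merge ------------------------------------------------------

same_schema <- function(s1, s2) {
  !is.null(s1) && !is.null(s2) &&
    identical(s1@classes[order(s1@classes$name), c("name", "parent")],
              s2@classes[order(s2@classes$name), c("name", "parent")]) &&
    identical(s1@properties[order(s1@properties$name),
                            c("name", "domain", "range")],
              s2@properties[order(s2@properties$name),
                            c("name", "domain", "range")])
}

chain_depth <- function(graph, p) length(transitiveClosure(graph, p, "preceded_by"))

#' Merge provenance from consecutive protocol phases
#'
#' Returns the triple-set union of the two graphs. Where a process in
#' `g2` consumes a data entity produced (participated in) in `g1` — a
#' shared IRI — the earliest such `g2` process gains a `preceded_by` link
#' to the latest `g1` process, so the merged process chain is traversable
#' end-to-end by transitive closure.
#'
#' @param g1,g2 [ProvenanceGraph-class] objects sharing a schema.
#' @return the merged [ProvenanceGraph-class].
#' @export
provenanceMerge <- function(g1, g2) {
  if (!same_schema(g1@schema, g2@schema))
    stop("merge error: graphs do not share a schema")
  schema <- g1@schema
  merged <- union_graphs(g1, g2)
  p_pt <- role_property_uris(schema, "has_participant")
  pb_uri <- property_uri(schema, "preceded_by")
  shared <- intersect(graphNodes(g1), graphNodes(g2))
  shared <- shared[is_instance_of(merged, shared, "data")]
  bridges <- tripleTable()
  for (d in sort(shared)) {
    P1 <- edge_subjects(g1@triples, d, p_pt)
    P2 <- edge_subjects(g2@triples, d, p_pt)
    P2 <- setdiff(P2, P1)
    if (!length(P1) || !length(P2)) next
    depth1 <- vapply(sort(P1), chain_depth, numeric(1), graph = g1)
    depth2 <- vapply(sort(P2), chain_depth, numeric(1), graph = g2)
    latest1 <- names(depth1)[which.max(depth1)]
    earliest2 <- names(depth2)[which.min(depth2)]
    already <- any(merged@triples$s == earliest2 &
                     merged@triples$p == pb_uri &
                     merged@triples$o == latest1)
    if (!already && earliest2 != latest1)
      bridges <- rbind(bridges, tripleTable(earliest2, pb_uri, latest1))
  }
  if (nrow(bridges)) merged <- addTriples(merged, unique(bridges))
  merged
}
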