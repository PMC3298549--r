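## Seeded generators for synthetic provenance: experiment-protocol chains
## (reverse-genetics style) and extraction corpora (literature-triple
## style). Every emitted triple carries a ground-truth data/provenance
## label so graph-level operators can be checked against construction.

#' Create a protocol spec
#'
#' @param steps list of steps, each `list(process=, parameters=, agents=)`
#'   (see [ProtocolSpec-class]).
#' @param branching output samples of the final step per run.
#' @param seed integer seed of the spec's private random stream.
#' @return a [ProtocolSpec-class].
#' @export
protocolSpec <- function(steps, branching = 1L, seed = 1L) {
  steps <- lapply(steps, function(st) {
    st$parameters <- st$parameters %||% list()
    st$agents <- as.integer(st$agents %||% 1L)
    st
  })
  new("ProtocolSpec", steps = steps, branching = as.integer(branching),
      seed = as.integer(seed))
}

#' The default reverse-genetics protocol spec
#'
#' A four-step knockout/strain-creation style chain — gene knockout,
#' transfection, drug selection, cloning — recording per step the kind of
#' provenance a reverse-genetics protocol tracks: target gene and
#' priority, selection antibiotic and number of transfection attempts,
#' drug concentration (ug/ml) and selection period (days), incubation
#' temperature (degrees C) and experiment status. Parameter values are
#' purely illustrative; the shape (one process chain per run, parameters
#' and agents per step, samples linking consecutive steps) is what the
#' framework's operators assume.
#'
#' @param seed integer seed.
#' @param branching cloned samples produced by the final step.
#' @return a [ProtocolSpec-class].
#' @export
defaultTcruziProtocol <- function(seed = 1L, branching = 1L) {
  protocolSpec(list(
    list(process = "gene_knockout_process",
         parameters = list(
           target_gene = list(
             kind = "choice",
             values = c("TcCLB.506529.310", "TcCLB.503955.30",
                        "TcCLB.510101.60", "TcCLB.508569.20")),
           priority = list(kind = "choice",
                           values = c("High", "Medium", "Low"))),
         agents = 2L),
    list(process = "transfection_process",
         parameters = list(
           antibiotic = list(kind = "choice",
                             values = c("neomycin", "hygromycin")),
           transfection_attempts = list(kind = "integer", min = 1, max = 5)),
         agents = 2L),
    list(process = "drug_selection_process",
         parameters = list(
           drug_concentration = list(kind = "uniform", min = 100, max = 500),
           selection_period = list(kind = "integer", min = 14, max = 42)),
         agents = 2L),
    list(process = "cloning_process",
         parameters = list(
           temperature = list(kind = "uniform", min = 26, max = 28),
           experiment_status = list(kind = "choice",
                                    values = c("completed", "in_progress"))),
         agents = 2L)),
    branching = branching, seed = seed)
}

draw_parameter_value <- function(dist) {
  switch(dist$kind,
         uniform = list(lex = format(round(stats::runif(1, dist$min, dist$max), 3),
                                     scientific = FALSE, trim = TRUE),
                        dt = XSD_DOUBLE),
         integer = list(lex = as.character(sample(dist$min:dist$max, 1L)),
                        dt = XSD_INTEGER),
         choice = list(lex = as.character(sample(dist$values, 1L)),
                       dt = NA_character_))
}

#' Generate a synthetic experiment-protocol provenance graph
#'
#' Emits `nRuns` independent process chains following the spec: each
#' step's process is `preceded_by` its predecessor, consumes the previous
#' sample and produces the next (`has_participant` both ways,
#' `derives_from` linking the samples), draws its parameters from the
#' spec's distributions (`has_parameter` + `rdf:value`), and is operated
#' by an agent from the step's pool (`has_agent`). Sample type/label
#' triples are ground-truth "data"; everything else is "provenance".
#' Identical seeds give byte-identical canonical N-Triples.
#'
#' @param spec a [ProtocolSpec-class].
#' @param nRuns number of independent runs.
#' @param schema schema declaring the step's classes (default
#'   [demoExtensionSchema()]).
#' @param instanceNamespace IRI prefix for minted instances.
#' @return a labeled [ProvenanceGraph-class]; `metadata$final_samples`
#'   holds the last-step output sample IRIs per run.
#' @export
generateExperimentGraph <- function(spec, nRuns,
                                    schema = demoExtensionSchema(),
                                    instanceNamespace = "http://example.org/tcruzi/") {
  stopifnot(is(spec, "ProtocolSpec"))
  validObject(spec)
  if (nRuns < 0) stop("generation error: nRuns must be >= 0")
  for (st in spec@steps) {
    if (!st$process %in% schema@classes$name)
      stop("generation error: unknown process class '", st$process, "'")
    for (pn in names(st$parameters))
      if (!pn %in% schema@classes$name)
        stop("generation error: unknown parameter class '", pn, "'")
  }
  ns <- sub("/+$", "/", paste0(instanceNamespace, "/"))
  k <- length(spec@steps)

  tt <- tripleTable(); lab <- character()
  emit <- function(df, label) {
    tt <<- rbind(tt, df)
    lab <<- c(lab, rep(label, nrow(df)))
  }
  sample_uri <- class_uri(schema, "sample")
  agent_pools <- list()
  withr::with_seed(spec@seed, {
    for (i in seq_len(k)) {
      n_ag <- spec@steps[[i]]$agents
      pool <- paste0(ns, "agent/researcher_", i, "_", seq_len(n_ag))
      agent_pools[[i]] <- pool
      emit(tripleTable(pool, RDF_TYPE, class_uri(schema, "researcher")),
           "provenance")
    }
    final_samples <- vector("list", nRuns)
    for (r in seq_len(nRuns)) {
      run_ns <- paste0(ns, "run", r, "/")
      s_prev <- paste0(run_ns, "sample0")
      emit(tripleTable(s_prev, RDF_TYPE, sample_uri), "data")
      emit(tripleTable(s_prev, ANNO_LABEL, paste0("run ", r, " input sample"),
                       o_type = "literal"), "data")
      p_prev <- NA_character_
      for (i in seq_len(k)) {
        st <- spec@steps[[i]]
        proc <- paste0(run_ns, st$process, "_", i)
        emit(tripleTable(proc, RDF_TYPE, class_uri(schema, st$process)),
             "provenance")
        if (!is.na(p_prev))
          emit(tripleTable(proc, property_uri(schema, "preceded_by"), p_prev),
               "provenance")
        agent <- sample(agent_pools[[i]], 1L)
        emit(tripleTable(proc, property_uri(schema, "has_agent"), agent),
             "provenance")
        emit(tripleTable(proc, property_uri(schema, "has_participant"), s_prev),
             "provenance")
        for (pn in names(st$parameters)) {
          par_node <- paste0(run_ns, pn, "_", i)
          val <- draw_parameter_value(st$parameters[[pn]])
          emit(tripleTable(par_node, RDF_TYPE, class_uri(schema, pn)),
               "provenance")
          emit(tripleTable(proc, property_uri(schema, "has_parameter"), par_node),
               "provenance")
          emit(tripleTable(par_node, RDF_VALUE, val$lex, o_type = "literal",
                           o_datatype = val$dt), "provenance")
        }
        n_out <- if (i == k) spec@branching else 1L
        outs <- if (i == k && spec@branching > 1L)
          paste0(run_ns, "sample", i, "_", seq_len(n_out))
        else paste0(run_ns, "sample", i)
        for (s_out in outs) {
          emit(tripleTable(s_out, RDF_TYPE, sample_uri), "data")
          emit(tripleTable(s_out, ANNO_LABEL,
                           paste0("run ", r, " ", st$process, " output"),
                           o_type = "literal"), "data")
          emit(tripleTable(s_out, property_uri(schema, "derives_from"), s_prev),
               "provenance")
          emit(tripleTable(proc, property_uri(schema, "has_participant"), s_out),
               "provenance")
        }
        s_prev <- outs[1]
        p_prev <- proc
        if (i == k) final_samples[[r]] <- outs
      }
    }
    provenanceGraph(tt, schema = schema,
                    metadata = list(generator = "protocol", seed = spec@seed,
                                    n_runs = nRuns,
                                    final_samples = final_samples),
                    labels = lab)
  })
}

## ---- extraction corpus -----------------------------------------------------

#' Create a corpus spec
#'
#' @param nAssertions,nSources counts (`nAssertions >= nSources`; every
#'   source backs at least one assertion).
#' @param confidenceRange numeric length-2 uniform range.
#' @param yearRange integer length-2 publication-year interval.
#' @param impactFactorRange numeric length-2; one impact factor per
#'   source, drawn uniformly.
#' @param seed integer seed.
#' @return a [CorpusSpec-class].
#' @export
corpusSpec <- function(nAssertions, nSources, confidenceRange = c(0, 10),
                       yearRange = c(2000L, 2011L),
                       impactFactorRange = c(0.5, 12), seed = 1L) {
  if (nAssertions < nSources)
    stop("nAssertions must be >= nSources (every source is used)")
  new("CorpusSpec", nAssertions = as.integer(nAssertions),
      nSources = as.integer(nSources),
      confidenceRange = as.numeric(confidenceRange),
      yearRange = as.integer(yearRange),
      impactFactorRange = as.numeric(impactFactorRange),
      seed = as.integer(seed))
}

extraction_vocabulary <- function() {
  list(entities = c("lipoprotein", "inflammatory_cells", "IL-13", "COX-2",
                    "TNF-alpha", "interleukin-6", "macrophage", "NF-kB",
                    "apolipoprotein_E", "C-reactive_protein", "interferon-gamma",
                    "T_lymphocyte", "endothelial_cell", "atherosclerosis",
                    "oxidative_stress", "nitric_oxide", "prostaglandin_E2",
                    "chemokine_CCL2", "toll-like_receptor_4", "adiponectin",
                    "insulin_resistance", "smooth_muscle_cell", "foam_cell",
                    "LDL_receptor"),
       relations = c("affects", "inhibits", "stimulates", "interacts_with",
                     "associated_with", "causes"))
}

#' Generate a synthetic extraction corpus
#'
#' Draws sourced subject-relation-object assertions emulating
#' literature-extraction output: each assertion carries its source
#' article (with publication date), an extraction confidence drawn
#' uniformly from the spec range, and a per-source journal impact factor.
#' Every source backs at least one assertion. The returned record table
#' is the ground truth used to check provenance-constraint queries by
#' direct filtering.
#'
#' @param spec a [CorpusSpec-class].
#' @return data.frame with one row per assertion: subject, predicate,
#'   object, source_type, source_id, publication_date, year, confidence,
#'   impact_factor, subject_class, object_class, predicate_class.
#' @export
generateExtractionCorpus <- function(spec) {
  stopifnot(is(spec, "CorpusSpec"))
  validObject(spec)
  voc <- extraction_vocabulary()
  withr::with_seed(spec@seed, {
    n <- spec@nAssertions; m <- spec@nSources
    src_num <- sample(10000000:99999999, m)
    src_ids <- paste0("PUBMED_", src_num)
    src_year <- sample(spec@yearRange[1]:spec@yearRange[2], m, replace = TRUE)
    src_date <- sprintf("%d-%02d-%02d", src_year,
                        sample(1:12, m, replace = TRUE),
                        sample(1:28, m, replace = TRUE))
    src_if <- round(stats::runif(m, spec@impactFactorRange[1],
                                 spec@impactFactorRange[2]), 2)
    # round-robin guarantees every source appears, then shuffle
    src_idx <- sample(rep_len(seq_len(m), n))
    subj <- sample(voc$entities, n, replace = TRUE)
    obj <- vapply(subj, function(s)
      sample(setdiff(voc$entities, s), 1L), character(1), USE.NAMES = FALSE)
    data.frame(subject = subj,
               predicate = sample(voc$relations, n, replace = TRUE),
               object = obj,
               source_type = "literature",
               source_id = src_ids[src_idx],
               publication_date = src_date[src_idx],
               year = src_year[src_idx],
               confidence = round(stats::runif(n, spec@confidenceRange[1],
                                               spec@confidenceRange[2]), 2),
               impact_factor = src_if[src_idx],
               subject_class = "biomedical_entity",
               object_class = "biomedical_entity",
               predicate_class = NA_character_,
               stringsAsFactors = FALSE)
  })
}

#' Demo knowledge-repository schema extension
#'
#' Extends the default schema with `biomedical_entity` (a
#' `data_collection` subclass for extracted entities) and
#' `journal_article` (a `data` subclass usable as a provenance-context
#' term for literature sources).
#'
#' @param base schema to extend.
#' @return an [OntologySchema-class].
#' @export
bkrExtensionSchema <- function(base = defaultProvenirSchema()) {
  ns <- "http://knoesis.wright.edu/demo/bkr.owl#"
  extendSchema(base, newClasses = list(
    classDef("biomedical_entity", "data_collection",
             paste0(ns, "biomedical_entity")),
    classDef("journal_article", "data", paste0(ns, "journal_article"))))
}

#' Encode an extraction corpus as a provenance graph
#'
#' Convenience wrapper: builds the knowledge-repository provenance
#' context, encodes the record table with [contextualize()] (or
#' [reify()] for `mode = "reification"`), types the source nodes as
#' journal articles, and attaches each source's impact factor.
#'
#' @param records record table from [generateExtractionCorpus()] (or any
#'   assertion table with the same columns).
#' @param mode `"minimal"`, `"intermediate"`, `"exhaustive"` or
#'   `"reification"`.
#' @param baseUri base IRI for contextualized entity minting.
#' @param schema schema with the demo extension classes (default
#'   [bkrExtensionSchema()]).
#' @return a labeled [ProvenanceGraph-class].
#' @export
encodeCorpus <- function(records, mode = "minimal",
                         baseUri = "http://mor.nlm.nih.gov/bkr",
                         schema = bkrExtensionSchema()) {
  ctx <- paceContext(schema, baseUri, contextTerms = "journal_article")
  g <- if (mode == "reification") reify(records, ctx, sourceClass = "journal_article")
       else contextualize(records, mode, ctx, sourceClass = "journal_article")
  if (!is.null(records$impact_factor)) {
    per_src <- unique(records[, c("source_id", "impact_factor")])
    src_nodes <- source_node_iri(baseUri, per_src$source_id)
    g <- addTriples(g, tripleTable(src_nodes, ANNO_IMPACTFACTOR,
                                   format(per_src$impact_factor,
                                          scientific = FALSE, trim = TRUE),
                                   o_type = "literal", o_datatype = XSD_DOUBLE),
                    labels = rep("provenance", nrow(per_src)))
  }
  g
}

#' Write / read the ground-truth label sidecar
#'
#' Tab-delimited sidecar with one row per triple (subject, predicate,
#' object, object type, datatype, label) matching the graph's canonical
#' order, so generated graphs can travel with their ground truth.
#'
#' @param graph a labeled [ProvenanceGraph-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(graph, path) {
  if (!length(graph@labels)) stop("graph has no ground-truth labels")
  df <- cbind(graph@triples, label = graph@labels)
  df <- df[order(triple_key(graph@triples)), ]
  utils::write.table(df, path, sep = "\t", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' @describeIn writeGroundTruth read the sidecar back.
#' @export
readGroundTruth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "\"",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
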