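# Independent oracles: exhaustive traversals (plain R / igraph) used to
# check the operator implementations, plus random-input generators.

# reflexive-transitive subclass closure by exhaustive parent-edge DFS
oracle_subclasses <- function(schema, cls) {
  cl <- schemaClasses(schema)
  rec <- function(x) {
    kids <- cl$name[!is.na(cl$parent) & cl$parent == x]
    c(x, unlist(lapply(kids, rec)))
  }
  sort(unique(rec(cls)))
}

# BFS over one property's edges, depth order, lexicographic within depth
oracle_closure <- function(graph, start, property = "preceded_by") {
  sc <- graphSchema(graph)
  prop_uris <- provenir:::role_property_uris(sc, property)
  df <- triples(graph)
  edges <- df[df$p %in% prop_uris & df$o_type == "iri", c("s", "o")]
  visited <- start; frontier <- start; out <- character()
  while (length(frontier)) {
    nxt <- setdiff(sort(unique(edges$o[edges$s %in% frontier])), visited)
    out <- c(out, nxt); visited <- c(visited, nxt); frontier <- nxt
  }
  out
}

# reachable-provenance node set via igraph reachability
oracle_provenance_nodes <- function(graph, entity) {
  sc <- graphSchema(graph)
  df <- triples(graph)
  pu <- function(p) provenir:::role_property_uris(sc, p)
  reach <- function(edge_df, starts) {
    if (!nrow(edge_df) || !length(starts)) return(starts)
    gr <- igraph::graph_from_data_frame(edge_df, directed = TRUE)
    starts_in <- intersect(starts, igraph::V(gr)$name)
    r <- unique(unlist(lapply(starts_in, function(s)
      names(igraph::subcomponent(gr, s, mode = "out")))))
    union(starts, r)
  }
  D <- reach(df[df$p %in% pu("derives_from") & df$o_type == "iri",
                c("s", "o")], entity)
  hp <- df[df$p %in% pu("has_participant"), , drop = FALSE]
  P0 <- unique(hp$s[hp$o %in% D])
  P <- reach(df[df$p %in% pu("preceded_by") & df$o_type == "iri",
                c("s", "o")], P0)
  comp_props <- c(pu("has_agent"), pu("has_participant"), pu("has_parameter"))
  comps <- unique(df$o[df$s %in% P & df$p %in% comp_props &
                         df$o_type == "iri"])
  mention <- df[df$s == entity | (df$o_type == "iri" & df$o == entity), ,
                drop = FALSE]
  nodes <- unique(c(entity, D, P, comps, mention$s,
                    mention$o[mention$o_type == "iri"]))
  sort(setdiff(nodes, c(schemaClasses(sc)$uri, schemaProperties(sc)$uri,
                        provenir:::reserved_vocabulary())))
}

# randomized protocol spec (shape varies; distributions fully specified)
random_protocol_spec <- function(seed) {
  withr::with_seed(seed, {
    procs <- sample(c("gene_knockout_process", "transfection_process",
                      "drug_selection_process", "cloning_process",
                      "strain_creation_process"), sample(2:4, 1))
    par_pool <- list(
      target_gene = list(kind = "choice", values = c("gA", "gB", "gC")),
      antibiotic = list(kind = "choice",
                        values = c("neomycin", "hygromycin")),
      drug_concentration = list(kind = "uniform", min = 50, max = 400),
      temperature = list(kind = "uniform", min = 25, max = 29),
      selection_period = list(kind = "integer", min = 10, max = 40),
      transfection_attempts = list(kind = "integer", min = 1, max = 5))
    steps <- lapply(procs, function(p) {
      m <- sample(0:3, 1)
      list(process = p,
           parameters = if (m) par_pool[sample(names(par_pool), m)] else list(),
           agents = sample(1:3, 1))
    })
    protocolSpec(steps, branching = sample(1:3, 1), seed = seed + 1000L)
  })
}

# closed-form triple count for a generated protocol graph
expected_protocol_triples <- function(spec, nRuns) {
  steps <- spec@steps
  k <- length(steps)
  agents <- sum(vapply(steps, function(st) st$agents, numeric(1)))
  per_run <- 2
  for (i in seq_len(k)) {
    m <- length(steps[[i]]$parameters)
    b <- if (i == k) spec@branching else 1L
    per_run <- per_run + 1 + (i > 1) + 1 + 1 + 3 * m + 4 * b
  }
  agents + nRuns * per_run
}

lipoprotein_assertion <- function() {
  sourcedAssertion("lipoprotein", "affects", "inflammatory_cells",
                   sourceDescriptor("literature", "PUBMED_17209178"))
}

bkr_test_context <- function() {
  paceContext(bkrExtensionSchema(), "http://mor.nlm.nih.gov/bkr",
              contextTerms = "journal_article")
}

# contextualized subject IRIs expected for a record subset (ground truth)
expected_context_entities <- function(records) {
  sort(unique(paste0("http://mor.nlm.nih.gov/bkr/", records$source_id, "/",
                     gsub("[[:space:]]+", "_", records$subject))))
}

instances_of_entities <- function(g) provenir:::instances_of(g, "data_collection")

# count provenance-attachment triples (linking property) in a PaCE graph
attachment_count <- function(graph, ctx) {
  link <- provenir:::property_uri(ctx@schema, ctx@linkingProperty)
  df <- triples(graph)
  sum(df$p == link & startsWith(df$o, paste0(ctx@baseUri, "/source/")))
}
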