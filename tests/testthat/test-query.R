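# Query operators: provenance retrieval, constraint queries, comparison,
# merge, ASK-probe closure, SPARQL composition.

test_that("provenance() retrieves the process chain with its components", {
  g <- generateExperimentGraph(defaultTcruziProtocol(seed = 31), 2)
  sc <- graphSchema(g)
  fs <- g@metadata$final_samples[[1]][1]
  sub <- provenance(g, fs)
  df <- triples(sub)
  # the drug-selection step's concentration parameter travels with it
  conc <- df$s[df$p == provenir:::RDF_TYPE &
                 df$o == provenir:::class_uri(sc, "drug_concentration")]
  expect_length(conc, 1L)
  expect_true(any(df$s == conc & df$p == provenir:::RDF_VALUE))
  # nothing from the other run leaks in
  expect_false(any(grepl("run2/", c(df$s, df$o))))

  # best match: an entity with no provenance edges yields only its triples
  lone <- addTriples(g, rbind(
    tripleTable("http://x/alone", provenir:::RDF_TYPE,
                provenir:::class_uri(sc, "sample")),
    tripleTable("http://x/alone", provenir:::ANNO_LABEL, "unconnected",
                o_type = "literal")))
  sub_lone <- provenance(lone, "http://x/alone")
  expect_identical(sort(triples(sub_lone)$p),
                   sort(c(provenir:::RDF_TYPE, provenir:::ANNO_LABEL)))

  expect_error(provenance(g, "http://nowhere/e"), "lookup error")
  proc <- triples(g)$s[grepl("cloning_process", triples(g)$s)][1]
  expect_error(provenance(g, proc), "precondition error")
})

test_that("deleting provenance triples shrinks provenance() but never fails it", {
  g <- generateExperimentGraph(defaultTcruziProtocol(seed = 17), 1)
  fs <- g@metadata$final_samples[[1]][1]
  full <- provenance(g, fs)
  df <- triples(g)
  sc <- graphSchema(g)
  prov_rows <- df[df$p %in% schemaProperties(sc)$uri, ]
  g_cut <- g
  for (i in seq_len(min(6, nrow(prov_rows)))) {
    g_cut <- removeTriples(g_cut, prov_rows[i, ])
    sub <- provenance(g_cut, fs)
    expect_true(all(provenir:::triple_key(triples(sub)) %in%
                      provenir:::triple_key(triples(full))))
  }
})

test_that("provenance() matches the igraph reachability oracle", {
  for (seed in 1:12) {
    spec <- random_protocol_spec(seed)
    g <- generateExperimentGraph(spec, 2)
    finals <- unlist(g@metadata$final_samples)
    entity <- withr::with_seed(seed, sample(finals, 1))
    expect_identical(provenanceNodes(provenance(g, entity)),
                     oracle_provenance_nodes(g, entity),
                     label = paste("seed", seed))
  }
})

test_that("provenance_context equals a direct record filter", {
  rec <- generateExtractionCorpus(corpusSpec(80, 10, seed = 41))
  g <- encodeCorpus(rec, "minimal")
  cons <- list(provenanceConstraint("impact_factor", ">", 5),
               provenanceConstraint("year", ">", 2007),
               provenanceConstraint("confidence", ">", 8))
  got <- provenanceContext(g, cons)
  pass <- rec[rec$impact_factor > 5 & rec$year > 2007 & rec$confidence > 8, ]
  expect_identical(got, expected_context_entities(pass))

  # empty constraint list returns all data entities
  all_ents <- provenanceContext(g, list())
  expect_identical(all_ents, instances_of_entities(g))

  # unsatisfiable constraint returns the empty set
  expect_identical(
    provenanceContext(g, list(provenanceConstraint(
      "confidence", ">", max(rec$confidence)))),
    character())

  expect_error(provenanceContext(g, list(provenanceConstraint(
    "no_such_target", "=", 1))), "constraint error")
})

test_that("provenance_compare abstracts instance identifiers", {
  sp <- defaultTcruziProtocol(seed = 23)
  g1 <- generateExperimentGraph(sp, 1, instanceNamespace = "http://a.org/i")
  g2 <- generateExperimentGraph(sp, 1, instanceNamespace = "http://b.org/j")
  p1 <- provenance(g1, g1@metadata$final_samples[[1]][1])
  p2 <- provenance(g2, g2@metadata$final_samples[[1]][1])
  expect_true(provenanceCompare(p1, p1))            # reflexive
  expect_true(provenanceCompare(p1, p2))            # same conditions
  expect_identical(provenanceCompare(p1, p2), provenanceCompare(p2, p1))

  # one differing parameter literal flips the verdict
  df2 <- triples(g2)
  val_row <- which(df2$p == provenir:::RDF_VALUE &
                     grepl("temperature", df2$s))[1]
  df2$o[val_row] <- "99.9"
  g2b <- provenanceGraph(df2, schema = graphSchema(g2),
                         metadata = g2@metadata)
  p2b <- provenance(g2b, g2@metadata$final_samples[[1]][1])
  expect_false(provenanceCompare(p1, p2b))
  # ... unless the tolerance window absorbs it
  expect_false(provenanceCompare(p1, p2b, tol = 0.5))
  expect_error(provenanceCompare(p1, provenanceGraph()), "non-empty")
})

test_that("provenance_merge bridges consecutive protocol phases", {
  sc <- demoExtensionSchema()
  g1 <- generateExperimentGraph(defaultTcruziProtocol(seed = 3), 1)
  g1 <- provenanceGraph(triples(g1), schema = sc,
                        metadata = g1@metadata)   # drop labels for merging
  fs <- g1@metadata$final_samples[[1]][1]
  ns2 <- "http://example.org/tcruzi/phase2/"
  pu <- function(p) provenir:::property_uri(sc, p)
  g2 <- provenanceGraph(rbind(
    tripleTable(paste0(ns2, "strain_creation_process_1"),
                provenir:::RDF_TYPE,
                provenir:::class_uri(sc, "strain_creation_process")),
    tripleTable(paste0(ns2, "strain_creation_process_1"),
                pu("has_participant"), fs),
    tripleTable(paste0(ns2, "sample1"), provenir:::RDF_TYPE,
                provenir:::class_uri(sc, "sample")),
    tripleTable(paste0(ns2, "sample1"), pu("derives_from"), fs),
    tripleTable(paste0(ns2, "strain_creation_process_1"),
                pu("has_participant"), paste0(ns2, "sample1"))), schema = sc)

  m <- provenanceMerge(g1, g2)
  # union plus exactly one bridging preceded_by triple
  expect_identical(tripleCount(m), tripleCount(g1) + tripleCount(g2) + 1L)
  bridge <- triples(m)[triples(m)$p == pu("preceded_by") &
                         grepl("phase2", triples(m)$s), ]
  expect_identical(nrow(bridge), 1L)
  # the merged chain is closure-traversable end to end
  cl <- transitiveClosure(m, paste0(ns2, "strain_creation_process_1"))
  expect_length(cl, 4L)

  # merge with an empty (same-schema) graph is the identity
  expect_identical(canonicalNTriples(provenanceMerge(
    g1, provenanceGraph(schema = sc))), canonicalNTriples(g1))

  # commutative up to isomorphism on disjoint graphs
  ga <- generateExperimentGraph(defaultTcruziProtocol(seed = 61), 1,
                                instanceNamespace = "http://a.org/d")
  gb <- generateExperimentGraph(defaultTcruziProtocol(seed = 62), 1,
                                instanceNamespace = "http://b.org/d")
  ga <- provenanceGraph(triples(ga), schema = sc)
  gb <- provenanceGraph(triples(gb), schema = sc)
  expect_identical(canonicalNTriples(provenanceMerge(ga, gb)),
                   canonicalNTriples(provenanceMerge(gb, ga)))

  expect_error(provenanceMerge(g1, provenanceGraph(schema = NULL)),
               "merge error")
})

test_that("ASK-probe closure matches BFS and terminates on cycles", {
  sc <- demoExtensionSchema()
  pu <- function(p) provenir:::property_uri(sc, p)
  mk <- function(edges) provenanceGraph(rbind(
    tripleTable(unique(c(edges$s, edges$o)), provenir:::RDF_TYPE,
                provenir:::class_uri(sc, "process")),
    tripleTable(edges$s, pu("preceded_by"), edges$o)), schema = sc)

  chain <- mk(data.frame(s = c("http://x/p3", "http://x/p2"),
                         o = c("http://x/p2", "http://x/p1")))
  expect_identical(transitiveClosure(chain, "http://x/p3"),
                   c("http://x/p2", "http://x/p1"))
  expect_identical(transitiveClosure(chain, "http://x/p1"), character())

  cyc2 <- mk(data.frame(s = c("http://x/p1", "http://x/p2"),
                        o = c("http://x/p2", "http://x/p1")))
  expect_identical(transitiveClosure(cyc2, "http://x/p1"), "http://x/p2")

  self <- mk(data.frame(s = "http://x/p1", o = "http://x/p1"))
  expect_identical(transitiveClosure(self, "http://x/p1"), character())

  expect_error(transitiveClosure(chain, "http://x/none"), "lookup error")

  # randomized graphs, including dense cyclic ones
  for (seed in 1:10) {
    g <- withr::with_seed(seed, {
      n <- sample(4:9, 1)
      nodes <- paste0("http://x/p", seq_len(n))
      ne <- sample(3:(2 * n), 1)
      mk(data.frame(s = sample(nodes, ne, replace = TRUE),
                    o = sample(nodes, ne, replace = TRUE)))
    })
    start <- triples(g)$s[1]
    expect_identical(transitiveClosure(g, start),
                     oracle_closure(g, start), label = paste("seed", seed))
  }
})

test_that("composed SPARQL matches the direct operators", {
  # single-class pattern: one triple pattern, zero OPTIONAL blocks
  sc <- demoExtensionSchema()
  single <- composeSparql("pattern", provenancePattern("researcher"), sc)
  expect_identical(single$metrics$triple_count, 1L)
  expect_identical(single$metrics$nesting_depth, 0L)

  expect_error(composeSparql("no_such_operator", NULL, sc),
               "composition error")

  # provenance(): executing the composed text reproduces the direct result
  for (seed in c(7, 19)) {
    g <- generateExperimentGraph(random_protocol_spec(seed), 2)
    fs <- g@metadata$final_samples[[1]][1]
    qp <- composeSparql("provenance", fs, graphSchema(g),
                        dDepth = 5, pDepth = 5)
    res <- executeSparql(qp$query, g)
    expect_identical(sparqlResultNodes(res, fs),
                     provenanceNodes(provenance(g, fs)),
                     label = paste("seed", seed))
  }

  # provenance_context(): same entity sets as the direct operator
  rec <- generateExtractionCorpus(corpusSpec(60, 8, seed = 77))
  g <- encodeCorpus(rec, "intermediate")
  cons <- list(provenanceConstraint("confidence", ">", 7),
               provenanceConstraint("impact_factor", ">", 4))
  qp <- composeSparql("provenance_context", cons, graphSchema(g), dDepth = 2)
  res <- executeSparql(qp$query, g)
  expect_identical(sort(unique(res$bindings$e)), provenanceContext(g, cons))
})

test_that("query metrics agree with text-level counts", {
  g <- generateExperimentGraph(defaultTcruziProtocol(seed = 2), 1)
  qp <- composeSparql("provenance", g@metadata$final_samples[[1]][1],
                      graphSchema(g), dDepth = 3, pDepth = 3)
  m <- qp$metrics
  # oracle: plain text scans of the emitted query
  body <- sub(".*?WHERE", "", qp$query)
  expect_identical(m$variable_count,
                   length(unique(unlist(regmatches(
                     qp$query, gregexpr("\\?[A-Za-z0-9_]+", qp$query))))))
  expect_identical(m$triple_count,
                   length(gregexpr(" \\.", body)[[1]]))
  expect_gte(m$variable_count, 10L)
  expect_identical(m$nesting_depth, 1L)
})

test_that("the evaluator agrees with a conformant SPARQL engine", {
  rec <- generateExtractionCorpus(corpusSpec(40, 6, seed = 55))
  g <- encodeCorpus(rec, "exhaustive")
  cons <- list(provenanceConstraint("confidence", ">", 6),
               provenanceConstraint("year", ">=", 2005))
  qp <- composeSparql("provenance_context", cons, graphSchema(g), dDepth = 1)
  ours <- sort(unique(executeSparql(qp$query, g)$bindings$e))

  gf <- withr::local_tempfile(fileext = ".nt")
  qf <- withr::local_tempfile(fileext = ".rq")
  pf <- withr::local_tempfile(fileext = ".py")
  writeGraph(g, gf)
  writeLines(qp$query, qf)
  writeLines(c(
    "import sys, rdflib",
    "g = rdflib.Graph(); g.parse(sys.argv[1], format='nt')",
    "q = open(sys.argv[2]).read()",
    "vals = sorted({str(r['e']) for r in g.query(q)})",
    "print('\\n'.join(vals))"), pf)
  out <- system2("python", c(pf, gf, qf), stdout = TRUE)
  expect_identical(ours, out[nzchar(out)])
})
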