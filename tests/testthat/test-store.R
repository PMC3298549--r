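# Single-graph storage: classification, propagation, serialization.

test_that("the classifier recovers generator ground truth exactly", {
  g <- generateExperimentGraph(defaultTcruziProtocol(seed = 13), 4)
  expect_identical(classifyTripleLabels(g), tripleLabels(g))
  st <- classifyTriples(g)
  expect_identical(st@provenanceTriples, sum(tripleLabels(g) == "provenance"))
  # default generator emulates protocols where most triples are provenance
  expect_gt(st@provenanceFraction, 80)
})

test_that("pure-data and pure-provenance graphs classify to 0% and 100%", {
  sc <- demoExtensionSchema()
  pure_data <- provenanceGraph(rbind(
    tripleTable("http://x/s1", provenir:::RDF_TYPE,
                provenir:::class_uri(sc, "sample")),
    tripleTable("http://x/s1", provenir:::ANNO_LABEL, "a sample",
                o_type = "literal")), schema = sc)
  expect_identical(classifyTriples(pure_data)@provenanceFraction, 0)

  chain <- provenanceGraph(rbind(
    tripleTable(c("http://x/p1", "http://x/p2"), provenir:::RDF_TYPE,
                provenir:::class_uri(sc, "process")),
    tripleTable("http://x/p2", provenir:::property_uri(sc, "preceded_by"),
                "http://x/p1")), schema = sc)
  expect_identical(classifyTriples(chain)@provenanceFraction, 100)

  expect_error(classifyTriples(provenanceGraph(triples(chain))),
               "classification error")
})

test_that("propagation exports the full provenance closure", {
  g <- generateExperimentGraph(defaultTcruziProtocol(seed = 5), 2)
  fs <- g@metadata$final_samples[[1]][1]
  ex <- propagate(g, fs)
  sc <- graphSchema(g)
  procs <- triples(ex)$s[triples(ex)$p == provenir:::RDF_TYPE &
    triples(ex)$o %in% provenir:::class_uri(sc, c(
      "gene_knockout_process", "transfection_process",
      "drug_selection_process", "cloning_process"))]
  expect_length(unique(procs), 4L)   # all steps of the run
  expect_true(all(grepl("run1/", unique(procs))))

  # entity with no provenance edges exports only its own triples
  lone <- addTriples(g, tripleTable("http://x/lonely", provenir:::RDF_TYPE,
                                    provenir:::class_uri(sc, "sample")))
  ex_lone <- propagate(lone, "http://x/lonely")
  expect_identical(tripleCount(ex_lone), 1L)

  # totality and monotonicity
  all_nodes <- graphNodes(g)
  expect_identical(canonicalNTriples(propagate(g, all_nodes)),
                   canonicalNTriples(g))
  small <- propagate(g, fs)
  bigger <- propagate(g, c(fs, g@metadata$final_samples[[2]][1]))
  expect_true(all(provenir:::triple_key(triples(small)) %in%
                    provenir:::triple_key(triples(bigger))))

  # classification is stable under total propagation
  expect_identical(classifyTriples(propagate(g, all_nodes))@provenanceTriples,
                   classifyTriples(g)@provenanceTriples)

  expect_error(propagate(g, "http://nowhere/x"), "propagation error")
})

test_that("graphs round-trip losslessly through all formats", {
  g <- generateExperimentGraph(defaultTcruziProtocol(seed = 8), 2)
  for (ext in c(".nt", ".ttl", ".rdf")) {
    f <- withr::local_tempfile(fileext = ext)
    writeGraph(g, f)
    expect_identical(canonicalNTriples(readGraph(f)), canonicalNTriples(g),
                     label = paste("round-trip", ext))
  }
  # canonical N-Triples output is byte-identical across writes
  f1 <- withr::local_tempfile(fileext = ".nt")
  f2 <- withr::local_tempfile(fileext = ".nt")
  writeGraph(g, f1); writeGraph(g, f2)
  expect_identical(readLines(f1), readLines(f2))

  # literal escaping survives the trip
  tricky <- provenanceGraph(tripleTable(
    "http://x/s", provenir:::ANNO_LABEL, "line1\nline2 \"quoted\" \\slash",
    o_type = "literal"))
  f <- withr::local_tempfile(fileext = ".nt")
  writeGraph(tricky, f)
  expect_identical(triples(readGraph(f))$o, triples(tricky)$o)
})

test_that("malformed input is reported with its line number", {
  f <- withr::local_tempfile(fileext = ".nt")
  writeLines(c("<http://a> <http://b> <http://c> .",
               "not a triple at all"), f)
  expect_error(readGraph(f), "line 2")
  writeLines(c("<http://a> <http://b> <http://c>"), f)  # missing dot
  expect_error(readGraph(f), "line 1")
})

test_that("TriG named-graph blocks collapse into the default graph", {
  f <- withr::local_tempfile(fileext = ".trig")
  writeLines(c("@prefix ex: <http://x/> .",
               "<http://g/1> {",
               "ex:a ex:p ex:b .",
               "}",
               "<http://g/2> {",
               "ex:c ex:p ex:d .",
               "} ."), f)
  g <- readGraph(f)
  expect_identical(tripleCount(g), 2L)
  expect_setequal(triples(g)$s, c("http://x/a", "http://x/c"))
})

test_that("ground-truth sidecars round-trip", {
  g <- generateExperimentGraph(defaultTcruziProtocol(seed = 4), 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGroundTruth(g, f)
  gt <- readGroundTruth(f)
  expect_identical(nrow(gt), tripleCount(g))
  expect_setequal(unique(gt$label), c("data", "provenance"))
})
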