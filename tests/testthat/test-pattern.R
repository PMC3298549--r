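# Provenance patterns: validation and form-value instantiation.

test_that("pattern validation checks class existence and domain/range", {
  sc <- demoExtensionSchema()
  ok <- validatePattern(provenancePattern(
    c("gene_knockout_process", "researcher"), "has_agent"), sc)
  expect_true(ok$valid)

  bad <- validatePattern(provenancePattern(c("agent", "agent"),
                                           "preceded_by"), sc)
  expect_false(bad$valid)
  expect_match(bad$report$message[2], "domain")

  unk <- validatePattern(provenancePattern("no_such_class"), sc)
  expect_false(unk$valid)
  expect_match(unk$report$message[1], "unknown class")
})

test_that("random patterns agree with a brute-force domain/range check", {
  sc <- demoExtensionSchema()
  cl <- schemaClasses(sc); pr <- schemaProperties(sc)
  for (seed in 1:40) {
    pat <- withr::with_seed(seed, {
      n <- sample(2:4, 1)
      provenancePattern(sample(cl$name, n, replace = TRUE),
                        sample(pr$name, n - 1L, replace = TRUE))
    })
    got <- validatePattern(pat, sc)$valid
    # oracle: exhaustive constraint check on each link
    el <- pat@elements
    exp_ok <- TRUE
    for (i in seq_len(nrow(el))[-1]) {
      pd <- pr[pr$name == el$property[i], ]
      if (!isSubclassOf(sc, el$class[i - 1L], pd$domain) ||
          grepl("://", pd$range) ||
          !isSubclassOf(sc, el$class[i], pd$range)) exp_ok <- FALSE
    }
    expect_identical(got, exp_ok)
  }
})

test_that("instantiation emits type, value and link triples", {
  sc <- demoExtensionSchema()
  pat <- provenancePattern(c("gene_knockout_process", "priority"),
                           "has_parameter")
  g <- instantiatePattern(pat, list(Priority = "High"), sc,
                          skip = "gene_knockout_process")
  df <- triples(g)
  expect_identical(sum(df$p == provenir:::RDF_VALUE), 1L)
  expect_identical(df$o[df$p == provenir:::RDF_VALUE], "High")
  pri_nodes <- df$s[df$p == provenir:::RDF_TYPE &
                      df$o == provenir:::class_uri(sc, "priority")]
  expect_length(pri_nodes, 1L)

  # empty pattern -> empty triple set
  expect_identical(tripleCount(instantiatePattern(
    provenancePattern(character()), list(), sc)), 0L)

  # 3-element chain, all values: 3 type + 3 value + 2 link
  g3 <- instantiatePattern(provenancePattern(
    c("gene_knockout_process", "sample", "plasmid"),
    c("has_participant", "contained_in")),
    list(gene_knockout_process = "knockout of TcCLB.506529.310",
         sample = "epimastigote culture 12", plasmid = "pTrex"),
    sc)
  df3 <- triples(g3)
  expect_identical(sum(df3$p == provenir:::RDF_TYPE), 3L)
  expect_identical(sum(df3$p == provenir:::RDF_VALUE), 3L)
  link_p <- provenir:::property_uri(sc, c("has_participant", "contained_in"))
  expect_identical(sum(df3$p %in% link_p), 2L)
  expect_identical(tripleCount(g3), 8L)

  # deterministic
  g3b <- instantiatePattern(provenancePattern(
    c("gene_knockout_process", "sample", "plasmid"),
    c("has_participant", "contained_in")),
    list(gene_knockout_process = "knockout of TcCLB.506529.310",
         sample = "epimastigote culture 12", plasmid = "pTrex"),
    sc)
  expect_identical(canonicalNTriples(g3), canonicalNTriples(g3b))
})

test_that("instantiation errors on unknown fields and invalid patterns", {
  sc <- demoExtensionSchema()
  pat <- provenancePattern(c("gene_knockout_process", "priority"),
                           "has_parameter")
  expect_error(instantiatePattern(pat, list(Nonexistent = "x"), sc),
               "unknown field")
  expect_error(instantiatePattern(
    provenancePattern(c("agent", "agent"), "preceded_by"),
    list(agent = "a"), sc), "invalid")
  expect_error(instantiatePattern(pat, list(priority = "High"), sc),
               "not marked skipped")
})

test_that("instantiated output re-validates cleanly against the schema", {
  sc <- demoExtensionSchema()
  pat <- provenancePattern(
    c("gene_knockout_process", "sample", "plasmid"),
    c("has_participant", "contained_in"))
  g <- instantiatePattern(pat, list(
    gene_knockout_process = "ko", sample = "s1", plasmid = "p1"), sc)
  df <- triples(g)
  types <- df[df$p == provenir:::RDF_TYPE, ]
  cls_of <- stats::setNames(
    schemaClasses(sc)$name[match(types$o, schemaClasses(sc)$uri)], types$s)
  expect_false(anyNA(cls_of))   # every instance typed to a schema class
  links <- df[df$p %in% schemaProperties(sc)$uri, ]
  for (i in seq_len(nrow(links))) {
    pd <- schemaProperties(sc)[schemaProperties(sc)$uri == links$p[i], ]
    expect_true(isSubclassOf(sc, cls_of[[links$s[i]]], pd$domain))
    expect_true(isSubclassOf(sc, cls_of[[links$o[i]]], pd$range))
  }
})

test_that("patterns read from config files", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("elements:",
               "  - class: gene_knockout_process",
               "  - class: researcher",
               "    property: has_agent"), f)
  pat <- readPatternConfig(f)
  expect_identical(pat@elements$class,
                   c("gene_knockout_process", "researcher"))
  expect_true(validatePattern(pat, demoExtensionSchema())$valid)
})
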