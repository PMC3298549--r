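# Upper-level schema: construction, extension, subclass closure.

test_that("default schema has the documented shape and is stable", {
  sc <- defaultProvenirSchema()
  expect_identical(nrow(schemaClasses(sc)), 8L)
  expect_identical(nrow(schemaProperties(sc)), 11L)
  expect_setequal(schemaClasses(sc)$name[is.na(schemaClasses(sc)$parent)],
                  c("data", "process", "agent"))
  # parameter specializations along the three dimensions, under data
  cl <- schemaClasses(sc)
  parent_of <- function(x) cl$parent[cl$name == x]
  expect_identical(parent_of("temporal_parameter"), "parameter")
  expect_identical(parent_of("parameter"), "data")
  expect_identical(parent_of("data_collection"), "data")
  expect_true(all(c("preceded_by", "derives_from", "has_agent",
                    "has_participant", "has_parameter") %in%
                    schemaProperties(sc)$name))
  # idempotent and structurally equal across calls
  expect_identical(schemaClasses(sc), schemaClasses(defaultProvenirSchema()))
  expect_identical(schemaProperties(sc),
                   schemaProperties(defaultProvenirSchema()))
})

test_that("extension is monotone and rejects dangling parents and cycles", {
  base <- defaultProvenirSchema()
  ext <- extendSchema(base, list(classDef("gene_knockout_process", "process")))
  expect_identical(nrow(schemaClasses(ext)), 9L)
  # base unchanged, all base entries retained
  expect_identical(nrow(schemaClasses(base)), 8L)
  expect_true(all(schemaClasses(base)$name %in% schemaClasses(ext)$name))
  expect_true(all(schemaProperties(base)$name %in%
                    schemaProperties(ext)$name))

  expect_error(extendSchema(base, list(classDef("x", "no_such_class"))),
               "unknown parent")
  expect_error(extendSchema(base, list(classDef("x", "x"))), "cycle")

  # child property domain/range must specialize the parent's
  ext2 <- extendSchema(base,
    list(classDef("assay_process", "process")),
    list(propertyDef("uses_sample", "assay_process", "data_collection",
                     parent = "has_participant")))
  expect_true("uses_sample" %in% schemaProperties(ext2)$name)
  expect_error(extendSchema(base, newProperties = list(
    propertyDef("bad_prop", "agent", "data", parent = "has_participant"))),
    "domain")
})

test_that("demo domain extension validates", {
  sc <- demoExtensionSchema()
  expect_true(validObject(sc))
  expect_true(all(c("gene_knockout_process", "drug_selection_process",
                    "priority", "researcher") %in% schemaClasses(sc)$name))
  expect_true(isSubclassOf(sc, "priority", "data"))
})

test_that("subclass closure matches exhaustive parent-edge traversal", {
  sc <- defaultProvenirSchema()
  expect_setequal(subclassesOf(sc, "parameter"),
                  c("parameter", "spatial_parameter", "temporal_parameter",
                    "domain_parameter"))
  expect_identical(subclassesOf(sc, "agent"), "agent")
  expect_error(subclassesOf(sc, "no_such"), "lookup error")

  # randomized schemas (<= 50 classes)
  for (seed in 1:20) {
    ext <- withr::with_seed(seed, {
      n <- sample(5:40, 1)
      names <- paste0("c", seq_len(n))
      parents <- vapply(seq_len(n), function(i) {
        pool <- c("data", "process", "agent", names[seq_len(i - 1L)])
        sample(pool, 1)
      }, character(1))
      extendSchema(defaultProvenirSchema(),
                   mapply(classDef, names, parents, SIMPLIFY = FALSE))
    })
    for (cls in sample(schemaClasses(ext)$name, 5))
      expect_identical(subclassesOf(ext, cls), oracle_subclasses(ext, cls))
  }
})

test_that("schema serializes to RDFS and reads back from config", {
  sc <- defaultProvenirSchema()
  g <- schemaToGraph(sc)
  df <- triples(g)
  expect_identical(sum(df$p == provenir:::RDFS_SUBCLASSOF), 5L)
  expect_identical(sum(df$p == provenir:::RDFS_SUBPROPERTYOF), 0L)
  f <- withr::local_tempfile(fileext = ".ttl")
  writeGraph(g, f)
  expect_identical(canonicalNTriples(readGraph(f)), canonicalNTriples(g))

  cfgf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("classes:",
               "  - name: sonication_process",
               "    parent: process",
               "properties:",
               "  - name: sonicates",
               "    domain: sonication_process",
               "    range: data_collection",
               "    parent: has_participant"), cfgf)
  ext <- readSchemaConfig(cfgf)
  expect_true("sonication_process" %in% schemaClasses(ext)$name)
  expect_true("sonicates" %in% schemaProperties(ext)$name)

  writeLines(c("classes: []", "bogus_key: 1"), cfgf)
  expect_error(readSchemaConfig(cfgf), "unknown config key")
})
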