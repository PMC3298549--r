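# PaCE encoding: contextualized IRIs, granularity modes, reification
# baseline, grouping, triple counts.

test_that("contextualized IRIs follow the base/context/name scheme", {
  u <- mintUri("http://mor.nlm.nih.gov/bkr", "PUBMED_17209178", "lipoprotein")
  expect_identical(renderUri(u),
                   "http://mor.nlm.nih.gov/bkr/PUBMED_17209178/lipoprotein")
  expect_identical(
    renderUri(mintUri("http://mor.nlm.nih.gov/bkr", "PUBMED_17209178",
                      "inflammatory_cells")),
    "http://mor.nlm.nih.gov/bkr/PUBMED_17209178/inflammatory_cells")
  # RFC 3986 percent-encoding of reserved characters
  expect_match(renderUri(mintUri("http://x.org/base", "SRC_1", "a b")),
               "/a%20b$")
  expect_error(mintUri("http://x.org", "SRC", ""), "minting error")
  expect_error(mintUri("ftp://x.org", "SRC", "y"), "minting error")
})

test_that("minted IRIs round-trip through parsing", {
  for (seed in 1:25) {
    nm <- withr::with_seed(seed, {
      chars <- c(letters, LETTERS, 0:9, " ", "-", "_", "(", ")", "/", "%")
      paste(sample(chars, sample(3:20, 1), replace = TRUE), collapse = "")
    })
    if (!nzchar(trimws(nm))) next
    u <- mintUri("http://x.org/base", paste0("SRC_", seed), nm)
    r <- parseContextUri(renderUri(u), "http://x.org/base")
    expect_identical(r@contextString, u@contextString)
    expect_identical(r@localName, u@localName)
    expect_true(provenir:::is_absolute_http_iri(renderUri(u)))
  }
})

test_that("the three granularities emit 1, 2 and 3 attachment triples", {
  ctx <- bkr_test_context()
  a <- lipoprotein_assertion()
  expect_identical(attachment_count(contextualize(a, "minimal", ctx), ctx), 1L)
  expect_identical(attachment_count(contextualize(a, "intermediate", ctx), ctx), 2L)
  expect_identical(attachment_count(contextualize(a, "exhaustive", ctx), ctx), 3L)
  expect_error(contextualize(a, "maximal", ctx), "mode error")

  # intermediate mode records its shared-source assumption on the graph
  gi <- contextualize(a, "intermediate", ctx)
  expect_true(isTRUE(gi@metadata$assumes_shared_object_source))
  expect_null(contextualize(a, "exhaustive", ctx)@metadata$assumes_shared_object_source)
})

test_that("PaCE output has no blank nodes and no reification vocabulary", {
  ctx <- bkr_test_context()
  rec <- generateExtractionCorpus(corpusSpec(30, 5, seed = 9))
  for (mode in c("minimal", "intermediate", "exhaustive")) {
    g <- contextualize(rec, mode, ctx, sourceClass = "journal_article")
    df <- triples(g)
    expect_false(any(grepl("^_:", c(df$s, df$o))))
    expect_false(any(c(df$s, df$p, df$o) %in% provenir:::REIFICATION_VOCAB))
  }
})

test_that("reification creates exactly four artifact triples per assertion", {
  ctx <- bkr_test_context()
  g <- reify(lipoprotein_assertion(), ctx)
  df <- triples(g)
  artifacts <- df$p %in% c(provenir:::RDF_SUBJECT, provenir:::RDF_PREDICATE,
                           provenir:::RDF_OBJECT) |
    (df$p == provenir:::RDF_TYPE & df$o == provenir:::RDF_STATEMENT)
  expect_identical(sum(artifacts), 4L)
  expect_identical(attachment_count(g, ctx), 1L)

  # empty batch -> empty output; n assertions -> 4n artifacts
  expect_identical(tripleCount(reify(list(), ctx)), 0L)
  rec <- generateExtractionCorpus(corpusSpec(37, 5, seed = 3))
  gb <- reify(rec, ctx)
  dfb <- triples(gb)
  n_art <- sum(dfb$p %in% c(provenir:::RDF_SUBJECT, provenir:::RDF_PREDICATE,
                            provenir:::RDF_OBJECT) |
                 (dfb$p == provenir:::RDF_TYPE &
                    dfb$o == provenir:::RDF_STATEMENT))
  expect_identical(n_art, 4L * 37L)
})

test_that("entities group by their provenance context", {
  ctx <- bkr_test_context()
  g <- contextualize(lipoprotein_assertion(), "exhaustive", ctx)
  grp <- groupByContext(g, ctx)
  expect_identical(names(grp), "PUBMED_17209178")
  expect_length(grp[["PUBMED_17209178"]], 3L)

  expect_identical(groupByContext(provenanceGraph(), ctx), list())

  # n sources x m entities -> n keys with m members each
  schema <- bkrExtensionSchema()
  rows <- expand.grid(src = paste0("PUBMED_", 11111110 + 1:4),
                      ent = paste0("entity", 1:5),
                      stringsAsFactors = FALSE)
  tt <- tripleTable(
    vapply(seq_len(nrow(rows)), function(i)
      renderUri(mintUri(ctx@baseUri, rows$src[i], rows$ent[i])), character(1)),
    provenir:::RDF_TYPE, provenir:::class_uri(schema, "biomedical_entity"))
  grp2 <- groupByContext(provenanceGraph(tt, schema = schema), ctx)
  expect_length(grp2, 4L)
  expect_true(all(lengths(grp2) == 5L))
})

test_that("per-encoding triple counts follow the closed-form totals", {
  ctx <- bkr_test_context()
  # distinct component/source combinations so the per-assertion closed
  # form k*n holds exactly (repeated pairs would merge under set
  # semantics); no annotations, no typing
  n <- 50L
  rec_bare <- data.frame(subject = paste0("subj_", 1:n),
                         predicate = paste0("rel_", 1:n),
                         object = paste0("obj_", 1:n),
                         source_id = paste0("SRC_", 1:n),
                         stringsAsFactors = FALSE)
  cnt <- countProvenanceTriples(rec_bare, ctx)
  expect_identical(cnt$provenance_triples,
                   c(1L, 2L, 3L, 5L) * n)         # k per mode
  expect_identical(cnt$total_triples, c(2L, 3L, 4L, 6L) * n)

  # duplicate-heavy generator output still orders strictly by mode
  rec <- generateExtractionCorpus(corpusSpec(50, 10, seed = 21))
  pr <- countProvenanceTriples(rec, ctx)$provenance_triples
  expect_true(all(diff(pr) > 0))

  # zero assertions -> all counts zero
  cnt0 <- countProvenanceTriples(rec_bare[0, ], ctx)
  expect_true(all(cnt0$total_triples == 0L))
  expect_true(all(cnt0$provenance_triples == 0L))
})

test_that("assertion corpora round-trip through the delimited format", {
  rec <- generateExtractionCorpus(corpusSpec(25, 5, seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAssertions(rec, f)
  back <- readAssertions(f)
  expect_setequal(names(back), names(rec))
  expect_identical(back[, names(rec)], rec)
  expect_error(readAssertions(withr::local_tempfile(fileext = ".tsv")),
               "not found")
})
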