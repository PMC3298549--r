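Package: provenir
Title: Semantic Provenance Management for Translational Research Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for managing provenance metadata of translational
    research data as RDF. Provides the Provenir upper-level provenance
    schema (data/process/agent with parameter and data-collection
    subclasses) together with an extension mechanism for domain-specific
    provenance ontologies, provenance-pattern validation and form-value
    instantiation, Provenance Context Entity (PaCE) triple generation at
    three granularities with an RDF-reification baseline, single-graph
    storage of data and provenance with triple classification and
    propagation export, four provenance query operators (provenance,
    provenance_context, provenance_compare, provenance_merge) with
    ASK-probe transitive closure over process chains, SPARQL query
    composition with best-match OPTIONAL semantics and RDFS-entailment
    expansion, materialized provenance views, and seeded generators for
    synthetic experiment-protocol graphs and extraction corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2,
    yaml,
    withr,
    rlang,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
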