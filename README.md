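# provenir

Semantic provenance management for translational research data, in R.

Research data earns trust through its history: which experiment
processes produced a cloned sample, who ran them and with what
parameters, which journal article an extracted assertion came from and
with what confidence. `provenir` is a toolkit for representing,
storing, and querying that history as RDF, aimed at two settings:

* **bench (pre-publication) provenance** — experiment-protocol chains
  such as reverse-genetics gene knockout and strain creation, collected
  through validated ontology-driven patterns;
* **repository (post-publication) provenance** — literature-extraction
  corpora where every subject–predicate–object assertion carries its
  source article, publication date, and extraction confidence.

## The model

The core is an upper-level provenance ontology with three top classes —
`data`, `process`, `agent` — five subclasses (`data_collection` and
`parameter` under `data`; spatial/temporal/domain parameters under
`parameter`), and 11 named relationships (`preceded_by`,
`derives_from`, `has_agent`, `has_participant`, `has_parameter`, …).
Domain ontologies extend it by `rdfs:subClassOf` / `rdfs:subPropertyOf`.

For extraction corpora, provenance is encoded by **contextualized
identifiers** instead of RDF reification: an entity from source
`PUBMED_17209178` is minted as

    http://mor.nlm.nih.gov/bkr/PUBMED_17209178/lipoprotein

(`base / provenance-context-string / entity-name`), and the assertion's
components are linked to the source node at one of three granularities —
minimal (subject only, 1 attachment triple), intermediate (subject +
predicate, 2), exhaustive (subject + predicate + object, 3). The
reification baseline spends 4 purely syntactic triples per assertion
before any provenance is attached; avoiding that overhead is the point.

Data and provenance are stored in a **single RDF graph** (what counts as
provenance is application-relative), with a classifier, propagation
export, and four query operators — `provenance()`,
`provenanceContext()`, `provenanceCompare()`, `provenanceMerge()` —
built on ASK-probe transitive closure over ⟨process, `preceded_by`⟩,
SPARQL composition with best-match OPTIONAL semantics, and materialized
provenance views.

## Worked example

```r
library(provenir)

defaultProvenirSchema()
#> OntologySchema: 8 classes, 11 properties
#>   top-level: data, process, agent
#>   namespace: http://knoesis.wright.edu/provenir/provenir.owl#

## encoding cost of one extracted assertion, per representation
a <- sourcedAssertion("lipoprotein", "affects", "inflammatory_cells",
                      sourceDescriptor("literature", "PUBMED_17209178"))
ctx <- paceContext(bkrExtensionSchema(), "http://mor.nlm.nih.gov/bkr",
                   contextTerms = "journal_article")
countProvenanceTriples(a, ctx)
#>       encoding total_triples provenance_triples
#> 1      minimal             2                  1
#> 2 intermediate             3                  2
#> 3   exhaustive             4                  3
#> 4  reification             6                  5

## a synthetic 5-run knockout/strain-creation protocol instance base
g <- generateExperimentGraph(defaultTcruziProtocol(seed = 1), 5)
classifyTriples(g)
#> StorageStats: 293 triples, 243 provenance-specific (82.9%)

## "find the drug concentration used to create this cloned sample"
fs <- g@metadata$final_samples[[1]][1]   # .../run1/sample4
sub <- provenance(g, fs)
sub
#> ProvenanceGraph: 61 triples (schema-backed); 51 labeled provenance
df <- triples(sub)
df[grepl("drug_concentration", df$s) & grepl("value$", df$p), c("s", "o")]
#>                                                      s       o
#> 40 http://example.org/tcruzi/run1/drug_concentration_3 364.319

## the process chain behind it, via ASK-probe transitive closure
transitiveClosure(g, df$s[grepl("cloning_process", df$s)][1])
#> [1] "http://example.org/tcruzi/run1/drug_selection_process_3"
#> [2] "http://example.org/tcruzi/run1/transfection_process_2"
#> [3] "http://example.org/tcruzi/run1/gene_knockout_process_1"
```

The provenance subgraph answers the question directly: the cloned
sample's drug-selection step used a concentration of 364.319 ug/ml, and
the closure lists the full chain of processes that led to the sample.

A command-line surface over the same functions ships in
`inst/scripts/spftool.R` (subcommands `generate`, `encode`, `stats`,
`query`, `closure`, `validate`; exit codes 0/2/3 for
success/usage/data errors).

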