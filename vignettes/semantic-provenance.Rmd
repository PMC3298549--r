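---
title: "Managing semantic provenance with provenir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing semantic provenance with provenir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provenir)
```

## The problem

Translational research data changes hands constantly: a cloned parasite
strain moves from the bench into a publication, an extracted literature
assertion moves from a text-mining pipeline into a knowledge repository.
At each hand-off, *provenance* — which processes produced an entity, who
ran them, under which parameter values, from which source a statement was
extracted and with what confidence — decides whether the data can be
trusted, reproduced, or filtered. `provenir` implements a unified
framework for this metadata: one upper-level RDF schema with a
domain-extension mechanism, source-contextualized triple generation for
extraction corpora, single-graph storage of data and provenance, and a
set of dedicated query operators.

## The upper-level schema and its extensions

The core model is a small upper-level provenance ontology with three
top-level classes — `data`, `process`, `agent` — and five subclasses:
`data_collection` and `parameter` under `data`, with `parameter`
specialized along the spatial, temporal and thematic dimensions. These 8
classes are linked by 11 named relationships.

A caveat on the relationship registry: the upper-level model fixes the
*number* of relationships but their full names, domains and ranges are
not enumerated in one normative list, so the default registry here is a
reconstruction — ten names adapted from the Relation ontology
(`part_of`, `contained_in`, `located_in`, `adjacent_to`,
`transformation_of`, `derives_from`, `preceded_by`, `has_participant`,
`has_agent`, `has_parameter`) plus `has_temporal_value` linking data to
temporal parameters. The registry is deliberately configurable through
`extendSchema()`; only `preceded_by`, `derives_from`, `has_agent`,
`has_participant` and `has_parameter` are load-bearing, because the
query operators traverse them.

```{r}
sc <- defaultProvenirSchema()
sc
subclassesOf(sc, "parameter")
```

Domain ontologies are built by subclassing (`rdfs:subClassOf` /
`rdfs:subPropertyOf` on serialization): `demoExtensionSchema()` ships a
compact reverse-genetics extension (knockout, transfection,
drug-selection, cloning processes; samples, plasmids, researchers;
experiment parameters), and `bkrExtensionSchema()` a knowledge-repository
extension (biomedical entities, journal articles). Extensions are
validated: single parent per class and property (multiple inheritance is
disallowed to keep closure and domain/range checking simple, and no use
case here needs it), acyclic hierarchies, child property domains/ranges
specializing their parents'. Full description-logic reasoning is out of
scope; subclass, domain and range checking is all the framework relies
on.

## Provenance patterns and form instantiation

Provenance collection is modeled after ontology-driven annotation forms:
a *provenance pattern* is an ordered chain of schema classes joined by
schema properties. `validatePattern()` reports, per element, class
existence and domain/range compatibility (violations are reported, not
raised, so a form designer can see all problems at once).
`instantiatePattern()` turns field values into RDF: one instance node
per element (typed with `rdf:type`), an `rdf:value` literal where the
field value is a literal, and the connecting property between
consecutive instances. Instance IRIs are minted as
`namespace + class + "/" + position`, so instantiation is deterministic;
callers can supply their own IRIs with `iriValue()`. Field values are
plain strings unless the R value is numeric or logical — whether nominal
drop-down values ("High"/"Medium"/"Low") should be literals or
individuals is genuinely open in ontology-engineering practice; literals
were chosen because they keep forms schema-independent, and a caller who
wants individuals can pass `iriValue()`.

## PaCE encoding and the reification baseline

For extraction corpora, provenance is represented by *contextualizing
identifiers* rather than by reifying statements: an entity extracted
from source `PUBMED_17209178` is named

```{r}
renderUri(mintUri("http://mor.nlm.nih.gov/bkr", "PUBMED_17209178",
                  "lipoprotein"))
```

so the source is part of the identifier (base IRI, provenance context
string, entity name), entities group by context for free
(`groupByContext()`), and no blank nodes or reification vocabulary are
needed. Three granularities are supported: `minimal` attaches only the
subject to the source node (1 extra triple per assertion),
`intermediate` the subject and predicate (2), `exhaustive` all three
components (3). The `reify()` baseline spends 4 syntactic artifact
triples per assertion before attaching any provenance — that gap is the
point of the contextualized encoding, and the strict count ordering
minimal < intermediate < exhaustive < reification is asserted as a test
property for every corpus.

Choices the encoding had to fix: all three of S, P and O use
contextualized IRIs in every mode (only the *attachment* triples differ
between modes); source nodes live under the reserved `source/` path
segment and statement nodes under `statement/`, both excluded from
context grouping; entity labels are normalized (trim, internal
whitespace to `_`) before percent-encoding, because real extraction
labels contain spaces; the attachment predicate defaults to the schema's
`derives_from` and is configurable in `paceContext()`; confidence and
publication date are annotation properties on the subject node (on the
statement node under reification), and the intermediate mode's
assumption that the object shares the subject's source is recorded in
the graph metadata so downstream consumers can detect it.

## Single-graph storage

Data and provenance triples live in one RDF graph, because what counts
as provenance is application-relative (an incubation temperature is
provenance for a knockout experiment, but a patient's body temperature
is data in a clinical study). `classifyTriples()` makes the split
operational: a triple is provenance-specific iff its predicate is a
schema property (or subproperty) or its subject/object is transitively
an instance of `process`, `agent` or `parameter`. This rule is a
reconstruction — no operational definition is fixed by the model — so
the synthetic generator labels every triple at creation and the test
suite requires the classifier to recover those labels exactly.
Statistics are instance-level: TBox triples are excluded, which is a
documented choice. Graphs are copy-on-write, so data and provenance can
never fall out of sync.

`propagate()` exports a self-contained bundle: the requested entities,
every triple mentioning them, the closure along provenance properties in
both directions, and the type/literal triples of everything pulled in.
One traversal rule matters: agent instances are included but not
expanded *through* — agents are shared resources (one researcher
operates many runs), and traversing through them would connect otherwise
unrelated lineages into one export.

Serialization: canonical (sorted) N-Triples for diffable, byte-stable
output, Turtle and RDF/XML writers, and readers for all three plus TriG
(named-graph blocks collapse into the default graph). The Turtle reader
covers the one-statement-per-line dialect the writer emits; parse errors
name the offending line.

## Query operators

Four operators cover the query patterns provenance work keeps asking
for:

* `provenance(graph, entity)` — the maximal best-match provenance
  subgraph of a `data_collection` instance: its `derives_from` chain,
  the processes touching that chain, their `preceded_by` closure,
  agents, participants, parameters, and the type/literal triples of
  every node involved. Missing components are omitted, never an error —
  deleting provenance triples shrinks the answer monotonically.
  Provenance-of-provenance (e.g. the source of a parameter value) is
  included one level deep only; deeper nesting is not traversed, a
  deliberate cut that keeps results interpretable.
* `provenanceContext(graph, constraints)` — data entities whose
  provenance satisfies all constraints (conjunctive), e.g. confidence,
  publication year, journal impact factor.
* `provenanceCompare(g1, g2)` — were two datasets generated under
  equivalent conditions? Equivalence is identifier-abstracted
  isomorphism: instance IRIs are abstracted by Weisfeiler–Lehman colour
  refinement while literals and schema vocabulary are kept, and the
  abstracted triple multisets are compared. Colour refinement is exact
  on the tree- and chain-shaped graphs experiment protocols produce;
  pathological symmetric graphs could in principle collide, a known
  limitation. Literal comparison is exact by default; `tol` rounds
  numeric literals to a grid first for instrument-noise tolerance.
* `provenanceMerge(g1, g2)` — triple-set union of two protocol phases;
  where a phase-2 process consumes a phase-1 entity, the earliest such
  phase-2 process gains one bridging `preceded_by` link to the latest
  phase-1 process, so the merged chain is closure-traversable end to
  end. The bridge is a reconstruction: without it the union is not a
  connected history.

`transitiveClosure()` implements reachability the way a SPARQL-only
deployment must: existence (ASK) probes of increasing path length,
stopping at the first `false`. Two safeguards are added to the bare
loop: a visited set (cyclic histories would otherwise satisfy every path
length) and a bound by node count. Discovery order is by depth,
lexicographic among ties, for deterministic output.

## SPARQL composition and evaluation

`composeSparql()` maps operators to SPARQL text: classes expand to their
subclass sets and properties to subproperty sets (RDFS entailment),
provenance components sit in OPTIONAL blocks, and structural metrics
(variables, triple patterns, OPTIONAL nesting) are returned with the
text. One design decision deserves its own paragraph: an early version
nested every component OPTIONAL inside every closure-depth OPTIONAL in
one conjunctive pattern, and its solution multiset grew as the product
of component matches across depths — roughly $6^{10}$ rows for a
four-step chain — which no engine should be asked to evaluate. The
template is instead a UNION over depth-limited linear chains (one branch
per derivation depth × process-chain depth), with the component OPTIONAL
blocks at each branch's terminal process. Best-match behaviour is
unchanged — every chain prefix has its own branch, so partial provenance
still matches — and the result multiset stays linear in the depths.
Unrolled depths default to `dDepth = 4`, `pDepth = 6` (and are
arguments); chains longer than the unrolled depth are not reached by the
composed text, which is the standard price of closure-free SPARQL.

Because no RDF store is assumed, the package ships an evaluator for
exactly the dialect the composer emits (BGP, nested OPTIONAL as left
joins, UNION, FILTER with comparisons and IN). Composed queries are
cross-validated two ways in the test suite: against the direct operator
implementations on every test graph, and against an independent SPARQL
engine (`rdflib` via Python) on a fixture corpus.

## Materialized provenance views

`queryWithMpv()` serves `provenance()` answers from cached views. Views
are keyed per entity by default; a schema-region view (keyed by a class
name, materializing the propagation closure of all its instances) can
answer member queries by evaluation over its self-contained subgraph.
Freshness is by fingerprint: graphs are immutable, so any mutation
produces a new fingerprint, the overlapping view is marked stale, and a
stale view is never served — cached answers are identical to uncached
evaluation by construction, which the tests check under random
query/update interleavings.

## The synthetic generators

Oracle-based testing needs inputs with known ground truth, so the
generators are first-class, seeded, and label every triple at creation.

`generateExperimentGraph()` emits independent reverse-genetics style
runs: per step a process instance (`preceded_by` its predecessor), an
agent drawn from the step's pool, the input and output samples
(`has_participant` both ways, `derives_from` between samples), and
parameter instances with drawn values. The default four-step spec
(knockout → transfection → drug selection → cloning) records target gene
and priority, antibiotic and transfection attempts, drug concentration
(100–500 ug/ml) and selection period (14–42 days), temperature (26–28 °C)
and status — the kinds of values such protocols actually track; the
values themselves are illustrative, not biological. Each spec owns a
private random stream (seeded, global RNG state untouched), so identical
seeds give byte-identical canonical serializations.

`generateExtractionCorpus()` emulates literature-extraction output:
assertions over a small biomedical vocabulary, each with a source
article (every source backs at least one assertion), a publication date
in the spec's year range, a uniform extraction confidence, and a
per-source journal impact factor. The record table is retained so
constraint queries can be checked by direct filtering.

What the generators do *not* emulate: real extraction noise (synonymy,
mis-segmented entity labels), skewed source distributions, schema
heterogeneity across projects, or biologically meaningful parameter
values. Passing tests therefore demonstrate correctness of the
*mechanics* — encoding counts, closure, classification, query/oracle
agreement — on graphs with the assumed shape, not robustness to
real-world dirt.

## Problem sizes and numerical choices

The test suite runs the operator/oracle equivalence on 100 seeded
protocol graphs (2–4 steps, up to 3 parameters/step, branching up to 3)
plus 15 corpora of 60 assertions, and the acceptance script recomputes
its quantities on 30 protocol graphs, 10 corpora, and a
25-run/1,433-triple instance base — sizes chosen so the whole suite
evaluates in about a minute while still exercising every branch shape.
Other fixed choices: percent-encoding follows RFC 3986 unreserved
characters; numeric literal comparison in filters is by value
(`"5.0" = 5`); `provenanceCompare`'s tolerance default is 0 (exact);
closure depth in composed queries must cover the protocol length (tests
use 5); duplicate triples always collapse (set semantics), which is why
closed-form count tests use corpora with distinct component/source
pairs.

## Known limitations

* The Turtle/TriG readers parse the canonical subset the writers emit,
  not the full grammars; no language-tagged literal support beyond
  accepting and dropping tags on input.
* The SPARQL evaluator covers the composed dialect only; it is a
  correctness vehicle, not a query engine.
* `provenanceCompare` is colour-refinement equivalence, exact for the
  generated protocol shapes but not a general graph-isomorphism
  decision.
* No transactional or concurrent storage backend; persistence is plain
  files.
* The schema's 11-relationship registry is a configurable
  reconstruction, not a normative vocabulary.
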