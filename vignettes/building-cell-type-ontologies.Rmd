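---
title: "Building data-driven cell-type ontologies from cluster taxonomies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building data-driven cell-type ontologies from cluster taxonomies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccn2ont)
```

## The problem

Large-scale single-cell and single-nucleus RNA sequencing of the brain
defines cell types by unsupervised hierarchical clustering of
transcriptomes. The cluster hierarchy — not a textbook description — is the
ground truth for these types. Classical cell ontologies, in contrast, define
classes by categorical assertions about morphology, location and marker
expression. `ccn2ont` implements a schema and pipeline that bridges the two:
it compiles hierarchical cluster taxonomies (CCN-style dendrogram documents
plus nomenclature tables), NS-Forest marker sets and light-weight curation
into an OWL 2 fragment in which

* every cluster is an OWL **individual**, linked to its parent cluster by a
  transitive `subcluster_of` relation and retaining all original metadata;
* selected clusters (every leaf, plus internal nodes flagged by the taxonomy
  authors, minus curator-excluded over-general groupings) become
  **classes**, each defined by a single equivalence axiom

  ```
  EquivalentClasses(c, cell and has_exemplar value i)
  ```

  where `i` is the cluster individual — the *exemplar pattern*;
* NS-Forest marker sets are reified as intermediate classes
  (`C has_characterizing_marker_set some S`, `S has_part some gene`), each
  carrying its F-beta classification accuracy as an
  `fbeta_confidence_score` annotation;
* cross-species homology groups are rendered pairwise with the symmetric
  `in_historical_homology_relationship_with` relation, `choose(k, 2)` axioms
  per group of `k` classes.

Because classification is carried by the exemplar equivalence plus the
property chain `has_exemplar o subcluster_of -> has_exemplar`, the class
hierarchy entailed by a reasoner *mirrors the cluster hierarchy exactly* and
stays insulated from manual edits: the provenance of every subsumption is
recoverable.

## The dedicated pattern reasoner

A general OWL DL reasoner is not needed: the schema exercises exactly three
entailment patterns, and the package implements them directly so that every
inference is auditable and testable against brute-force oracles.

1. **Subcluster closure** — the irreflexive transitive closure of the
   direct parent links (memoized depth-first traversal; a cycle is a hard
   error naming the node).
2. **Data-driven classification** — class `A` is a strict subclass of `B`
   iff `A`'s exemplar is a strict descendant of `B`'s exemplar; classes
   sharing an exemplar are reported *equivalent but are not collapsed*,
   because a shared exemplar is virtually always a modelling error worth
   surfacing (it is also a QC finding).
3. **Structural subsumption** — grouping classes (e.g. "primary motor
   cortex pyramidal cell") are defined in an imports-stub table as one named
   conjunct plus existential restrictions. A generated class is placed under
   a grouping class iff one of its asserted named superclasses reaches the
   named conjunct through the subclass closure, and every restriction
   conjunct `R some F` is matched by an asserted restriction `R' some F'`
   with `R'` a subproperty of `R` and `F'` a subclass of `F`. This is the
   EL-style fragment; any other constructor in a definition is a hard error.

Asserted, data-driven and structural subsumptions are combined, checked to
be a DAG, and transitively reduced; each surviving edge keeps a provenance
tag (`asserted` / `data-driven` / `structural`) that survives into the
property-graph export. All outputs are sorted by identifier, so reasoning is
deterministic. Ties between provenances for the same pair resolve in the
order asserted > data-driven > structural.

Curated morphology *and* projection terms are both rendered as `bearer_of`
existential restrictions. This was a genuinely open choice (a projection
class could also have been an asserted named superclass); the restriction
rendering keeps grouping-class definitions in the single-named-conjunct
normal form the structural classifier consumes, and it matches how the
worked grouping-class examples are axiomatised.

## What is deliberately *not* axiomatised

Marker sets and soma location are **never** compiled into
`EquivalentClasses` axioms. Marker-based equivalence would let a reasoner
classify any cell matching the markers into the type; with marker precision
around 98%, rare types (below ~2% prevalence) would be misclassified more
often than correctly classified, and the pattern could not accommodate
multiple competing marker sets per type. The reification pattern used
instead records the markers and their confidence without licensing such
inferences. This exclusion is enforced twice: the builder has no code path
that emits the pattern, and the QC stage (`qc_report`) plus a dedicated
negative test assert its absence from every build. For the same reason the
imports stub keeps grouping-class definitions as structured data for the
classifier and as a definition *annotation*, not as equivalence axioms.

## Naming

Labels, definitions and synonyms are expanded from configurable templates
(`default_naming_config()`). Two patterns matter:

* anchor species (the taxonomy whose aliases anchor cross-species names,
  typically mouse): `"{alias} ({species_common_name} {region_acronym})"`,
  e.g. `L5 ET (Mouse M1)`;
* non-anchor species with an alias transferred by cross-species alignment:
  `"({anchor_species} {aligned_alias})-like ({species_common_name})"`,
  e.g. `(Mouse Sncg)-like (Marmoset)` — the "-like" wrapper signals that the
  marmoset cluster was *aligned* to the mouse Sncg cluster and need not
  express Sncg.

A node with no usable alias falls back to its accession; a label is never
empty, an unbound template placeholder is a hard error, and a label
collision is a hard error naming both sources.

## Identifiers and determinism

Every generated entity identifier is minted deterministically. The default
policy is a slug of (kind, taxonomy, accession) — a pure function of its
inputs, so a partial rebuild can never renumber untouched entities; an
OBO-style zero-padded numeric policy (ids assigned in sorted-accession
order over a batch) is available via `mint_numeric_ids()`. Distinct sources
colliding on one identifier (e.g. two metadata keys slugging identically)
is a hard error.

Byte determinism is treated as a feature of the whole pipeline, not just of
the serializer: axiom lists are kept canonically sorted and deduplicated,
numeric literals are rendered with shortest round-trip decimal notation
(capped at 17 significant digits, so `0.93` stays `0.93`), table writers
sort rows, and files are written with fixed `\n` endings in UTF-8. Two
builds from identical inputs are byte-identical across the functional-syntax
ontology, the OBO export, the graph tables and the reports; this is asserted
by tests.

## The synthetic-fixture generator

All tests run on synthetic inputs generated in-repo (`generate_taxonomy`,
`generate_markers`, `generate_curation_and_homology`,
`generate_fixture_set`); nothing is downloaded. The generator emulates the
*shape* of real taxonomy releases:

* random trees with an exact leaf count, bounded depth (≤ 4 children per
  node) and strictly leafward-decreasing dendrogram heights, retained as the
  division-confidence measure in [0, 1];
* internal nodes flagged for class generation with probability 0.5 — the
  default emulating the roughly three-level hierarchies taxonomy authors
  flag in practice;
* marker rows for every classed node with 2–4 genes from a synthetic pool
  and F-beta drawn uniformly on [0.5, 1], the range in which published
  NS-Forest scores for cortical taxonomies typically land;
* a marmoset taxonomy whose aliases are partially transferred from the
  mouse anchor (drawn without replacement, so generated labels are unique);
* curation that always contains at least one exclusion row and guarantees at
  least one generated class satisfies a grouping-class definition, so the
  structural stage is always exercised;
* homology groups spanning 2–3 distinct taxonomies.

One integer seed drives everything, and each generator returns a
ground-truth record, which makes every count-based oracle in the test suite
exact (individuals = nodes + datasets; subcluster assertions = nodes −
roots; classes = leaves + flagged − excluded; marker-set classes = marker
rows; `has_part` axioms = total genes; homology axioms = Σ choose(k, 2)).

What the generator does **not** emulate: expression matrices, realistic
marker-gene co-expression statistics, noisy or inconsistent release files
(those are covered by fault-injection tests instead). A green suite
therefore demonstrates the correctness of the compilation, reasoning and
projection machinery on well-formed inputs of realistic shape, not
robustness to every dialect variant in the wild.

The default test problem sizes — taxonomies of ~10 leaves for end-to-end
builds, 100 random trees of up to 200 nodes for the reasoner-versus-oracle
equivalence — were chosen as the smallest sizes at which every code path
(multi-root forests, unary chains, maximal branching, excluded flagged
nodes, unresolvable homology members) is routinely exercised.

## Serialization

OWL 2 Functional-Style Syntax is the canonical interchange format: it is
line-oriented, diffable, and the supported fragment covers exactly what the
builder emits (declarations; SubClassOf / EquivalentClasses over
intersection, existential and has-value restrictions; class, property and
annotation assertions; transitivity, symmetry and the exemplar property
chain). `write(parse(write(x)))` is a fixed point; constructs outside the
fragment (cardinality, union, complement, ...) fail with an explicit
unsupported-construct error carrying a location. RDF serializations are out
of scope — they would require graph canonicalization for determinism — and
the OBO export is a documented lossy convenience (terms, names, definitions,
synonyms, reduced is-a lines).

## Property-graph projection and semantic tags

The projection follows the neo4j2owl philosophy: preserve entailments and
annotations, drop OWL syntax. Classes and individuals become nodes;
reduced subsumption becomes `is_a` edges carrying their provenance;
restrictions to named fillers, exemplar has-value equivalences and
object-property assertions become typed edges. Semantic tags are driven by
declarative rules — a subclass-of condition evaluated against the inferred
hierarchy (reflexive, so the target class tags itself) and/or an asserted
restriction condition with optional filler-subclass closure. This restricted
form covers every tag family the application layer needs (species, brain
region, gross class, morphology, projection) without embedding a DL or
SPARQL engine; tagging is monotone in the rule list.

## Known limitations

* The structural classifier handles only the EL-style conjunctive fragment;
  grouping classes needing disjunction or negation cannot be expressed.
* Equivalence groups (shared exemplars) are surfaced, not resolved.
* The OBO export is lossy by design; the `.ofn` file is the artifact of
  record.
* Dataset links can attach at cluster or taxonomy level (configurable);
  both are supported because release practice varies.
* Rebuilding the full published multi-species release requires its pinned
  public input repositories, which are not redistributed here; the package
  ships small worked-example and synthetic fixtures instead.
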