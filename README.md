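# ccn2ont

Compile hierarchical single-cell cell-type taxonomies into formally
reasoned OWL ontologies and labelled property graphs.

## The problem

Brain cell atlases define cell types by unsupervised hierarchical
clustering of single-cell/nucleus transcriptomes, exchanged as CCN-style
taxonomy files (a dendrogram of accessioned clusters plus a nomenclature
table), with NS-Forest marker sets scoring how well a minimal gene
combination identifies each cluster. Classical ontologies cannot represent
"this class is defined by that cluster". `ccn2ont` is for ontology
engineers and atlas data wranglers who need to turn such taxonomies into an
ontology whose classification *is* the data-driven one, with transparent
provenance, and into a property graph that can drive search applications.

## The schema in brief

For a cluster individual `i` and its generated class `c`:

```
EquivalentClasses(c, cell and has_exemplar value i)      # exemplar pattern
ObjectPropertyAssertion(subcluster_of, i_child, i_parent)  # transitive
has_exemplar o subcluster_of ⊑ has_exemplar                # property chain
```

so `c_child ⊑ c_parent` is *entailed* whenever the child's exemplar sits
below the parent's exemplar in the cluster hierarchy. Marker sets are
reified (`C has_characterizing_marker_set some S`, `S has_part some gene`,
F-beta as an `fbeta_confidence_score` annotation on `S`) — deliberately
*never* as equivalence axioms, which would misclassify rare types. A
dedicated pattern reasoner computes the subcluster closure, the exemplar
chain entailments, and EL-style structural placement under grouping classes
(named conjunct + existential restrictions), then transitively reduces the
union with per-edge provenance (`asserted` / `data-driven` / `structural`).
Homology groups across species become pairwise
`in_historical_homology_relationship_with` restrictions, `C(k,2)` per group.

## Worked example

The packaged three-level chain fixture (clusters CS001 ⊃ CS002 ⊃ CS003, all
flagged for classes):

```r
library(ccn2ont)
fig3 <- system.file("extdata", "fig3", "manifest.json", package = "ccn2ont")
inputs <- load_inputs(fig3)
b <- build_ontology(inputs$taxonomies)
b$ontology
#> <ontology_document> 29 entities (6 classes, 3 individuals, 9 obj-props, 11 ann-props), 43 axioms
b$hierarchy$pairs
#>                   sub                 sup  provenance
#> 1 ONT:cc-txfig3-cs002 ONT:cc-txfig3-cs001 data-driven
#> 2 ONT:cc-txfig3-cs003 ONT:cc-txfig3-cs002 data-driven
content_summary(b$ontology)
#> individuals_total            3
#> taxonomy_node_individuals    3
#> dataset_individuals          0
#> classes_total                6
#> namespace_classes            3
#> cell_type_classes            3
#> marker_set_classes           0
#> homology_axioms              0
```

The two `data-driven` pairs are the transitive reduction of the entailed
chain c3 ⊑ c2 ⊑ c1: the class hierarchy mirrors the cluster hierarchy, and
each edge records where it came from. `write_functional_syntax()` then
serializes the merged, reasoned document deterministically;
`project_graph()` / `apply_tags()` / `emit_graph()` produce `nodes.tsv` and
`edges.tsv` for application use.

A command-line wrapper over the same functions ships in
`inst/cli/ccn2ont.R`:

```sh
Rscript inst/cli/ccn2ont.R synth --seed 7 --out /tmp/bundle
Rscript inst/cli/ccn2ont.R build --manifest /tmp/bundle/manifest.json --out /tmp/build
Rscript inst/cli/ccn2ont.R export-graph --ontology /tmp/build/ontology.ofn \
        --stub /tmp/bundle/imports_stub.tsv --out /tmp/graph
```

Exit codes: 0 ok, 1 validation/QC failure, 2 usage error.

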