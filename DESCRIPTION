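Package: ccn2ont
Title: Compile Cell-Type Taxonomies into Data-Driven OWL Ontologies and
    Property Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compiles hierarchical single-cell transcriptomic cell-type
    taxonomies (CCN-style dendrogram documents and nomenclature tables),
    NS-Forest marker sets with F-beta confidence scores, curated class
    annotations and cross-species homology mappings into a formally
    reasoned OWL 2 fragment. Each cluster becomes an OWL individual linked
    to its parent by a transitive subcluster_of relation; selected
    clusters become classes defined by an exemplar has-value pattern, so
    that a dedicated pattern reasoner (transitive closure, exemplar
    property chain, EL-style structural subsumption under grouping
    classes) rebuilds the cluster hierarchy as a class hierarchy. The
    reasoned ontology is serialized deterministically to OWL functional
    syntax and OBO, projected into a labelled property graph with
    rule-driven semantic tags, and summarised by content and
    quality-control reports. A synthetic-fixture generator makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
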