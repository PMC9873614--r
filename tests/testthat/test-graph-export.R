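cfg <- default_config()
v <- cfg$vocabulary

test_that("restrictions project to typed edges and lone classes to bare nodes", {
  doc <- ontology_document()
  doc <- declare(doc, c("ONT:C", "UBERON:0001384"), "class")
  doc <- declare(doc, v$has_soma_location, "object_property")
  doc <- add_axioms(doc, ax_subclass("ONT:C", ce_some(v$has_soma_location,
                                                      "UBERON:0001384")))
  g <- project_graph(doc, NULL, cfg)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$from, "ONT:C")
  expect_identical(g$edges$to, "UBERON:0001384")
  expect_identical(g$edges$type, "has_soma_location")

  lone <- declare(ontology_document(), "ONT:X", "class")
  g2 <- project_graph(lone, NULL, cfg)
  expect_identical(nrow(g2$nodes), 1L)
  expect_identical(nrow(g2$edges), 0L)
})

test_that("projection counts and content follow closed forms on a build", {
  d <- withr::local_tempdir()
  fx <- generate_fixture_set(23, d)
  b <- build_from_manifest(file.path(d, "manifest.json"))
  doc <- merge_inferred(b$ontology, b$hierarchy)
  g <- project_graph(doc, b$hierarchy, cfg)
  expect_identical(nrow(g$nodes),
                   sum(doc$entities$kind %in% c("class", "individual")))
  # every inferred subclass pair survives as an is-a path in the graph
  is_a <- g$edges[g$edges$type == "is_a", ]
  reach <- oracle_closure(is_a$from, is_a$to)
  full <- hierarchy_closure(b$hierarchy)$pairs
  expect_true(all(paste(full$sub, full$sup) %in%
                    paste(reach$from, reach$to)))
  # exemplar equivalences become has_exemplar edges class -> individual
  ex <- exemplar_map(b$ontology)
  ee <- g$edges[g$edges$type == "has_exemplar", ]
  expect_identical(sort(paste(ee$from, ee$to)),
                   sort(paste(names(ex), unname(ex))))
  # no duplicate (from, to, type) triples, all endpoints exist
  expect_false(any(duplicated(paste(g$edges$from, g$edges$to, g$edges$type))))
  expect_true(all(c(g$edges$from, g$edges$to) %in% g$nodes$id))
})

test_that("tag rules evaluate like per-node brute force and stay monotone", {
  d <- withr::local_tempdir()
  fx <- generate_fixture_set(29, d)
  inputs <- load_inputs(file.path(d, "manifest.json"))
  b <- build_from_manifest(file.path(d, "manifest.json"))
  g <- project_graph(b$ontology, b$hierarchy, cfg)
  rules <- list(
    tag_rule("neuron", requires_subclass_of = "STUB:0000001"),
    tag_rule("pyramidal",
             requires_subclass_of = "STUB:0000001",
             requires_restriction = list(property = v$bearer_of,
                                         filler = "STUB:0000010")),
    tag_rule("mouse",
             requires_restriction = list(property = v$in_taxon,
                                         filler = "NCBITaxon:10090")))
  tagged <- apply_tags(g, rules, b$hierarchy, b$ontology, cfg)

  # brute-force per-node evaluation
  full <- hierarchy_closure(b$hierarchy)$pairs
  below <- function(t) c(t, full$sub[full$sup == t])
  restr_of <- function(id) Filter(function(a) a$sub == id &&
                                    a$sup$type == "Some",
                                  axioms_of_type(b$ontology, "SubClassOf"))
  for (id in tagged$nodes$id) {
    want <- character(0)
    if (id %in% below("STUB:0000001")) want <- c(want, "neuron")
    has_restr <- function(p, f) any(vapply(restr_of(id), function(a)
      a$sup$property == p && a$sup$filler$id %in% below(f), logical(1)))
    if (id %in% below("STUB:0000001") &&
        has_restr(v$bearer_of, "STUB:0000010")) want <- c(want, "pyramidal")
    if (has_restr(v$in_taxon, "NCBITaxon:10090")) want <- c(want, "mouse")
    expect_identical(tagged$nodes$tags[tagged$nodes$id == id],
                     paste(sort(want), collapse = "|"))
  }
  expect_true(any(nzchar(tagged$nodes$tags)))

  # monotone: adding a rule never removes a tag
  more <- apply_tags(g, c(rules, list(tag_rule("cortex",
    requires_restriction = list(property = v$has_soma_location,
                                filler = "UBERON:0001384")))),
    b$hierarchy, b$ontology, cfg)
  for (i in seq_len(nrow(tagged$nodes))) {
    old <- setdiff(strsplit(tagged$nodes$tags[i], "|", fixed = TRUE)[[1]], "")
    new <- setdiff(strsplit(more$nodes$tags[i], "|", fixed = TRUE)[[1]], "")
    expect_true(all(old %in% new))
  }

  # empty rule list leaves every node untagged; unknown ids are hard errors
  none <- apply_tags(g, list(), b$hierarchy, b$ontology, cfg)
  expect_false(any(nzchar(none$nodes$tags)))
  expect_error(apply_tags(g, list(tag_rule("x",
    requires_subclass_of = "NOPE:1")), b$hierarchy, b$ontology, cfg),
    class = "ccn2ont_UNKNOWN_RULE_ID")
  expect_error(tag_rule("empty"), class = "ccn2ont_EMPTY_RULE")
})

test_that("graph tables round-trip and the statement script is line-complete", {
  d <- withr::local_tempdir()
  fx <- generate_fixture_set(37, d, n_leaves_anchor = 6, n_leaves_other = 5)
  b <- build_from_manifest(file.path(d, "manifest.json"))
  g <- project_graph(b$ontology, b$hierarchy, cfg)
  out <- file.path(d, "graph")
  emit_graph(g, out, "script")
  back <- read_graph_tables(out)
  expect_identical(back$nodes, g$nodes)
  expect_identical(back$edges, g$edges)
  script <- readLines(file.path(out, "graph.cypher"))
  expect_identical(length(script), nrow(g$nodes) + nrow(g$edges))
  # determinism of emission
  out2 <- file.path(d, "graph2")
  emit_graph(g, out2, "script")
  expect_identical(readLines(file.path(out, "nodes.tsv")),
                   readLines(file.path(out2, "nodes.tsv")))
  # empty graph emits headers only
  eg <- project_graph(ontology_document(), NULL, cfg)
  out3 <- file.path(d, "graph3")
  emit_graph(eg, out3)
  expect_identical(length(readLines(file.path(out3, "nodes.tsv"))), 1L)
})
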