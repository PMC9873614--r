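test_that("an empty ontology serializes to prefixes and an empty frame", {
  txt <- write_functional_syntax(ontology_document())
  expect_true(any(startsWith(txt, "Prefix(")))
  oline <- which(startsWith(txt, "Ontology("))
  expect_identical(txt[length(txt)], ")")
  expect_identical(length(txt), oline + 1L)  # nothing between frame delimiters
})

test_that("write-parse-write is a fixed point on full synthetic builds", {
  d <- withr::local_tempdir()
  fx <- generate_fixture_set(41, d)
  b <- build_from_manifest(file.path(d, "manifest.json"))
  doc <- merge_inferred(b$ontology, b$hierarchy)
  t1 <- write_functional_syntax(doc)
  back <- parse_functional_syntax(t1)
  t2 <- write_functional_syntax(back)
  expect_identical(t1, t2)
  # and the parsed document matches the original axiom for axiom
  expect_identical(vapply(back$axioms, render_axiom, character(1)),
                   vapply(doc$axioms, render_axiom, character(1)))
  expect_identical(back$entities, doc$entities)
})

test_that("the parsed chain fixture carries the expected assertion counts", {
  d <- withr::local_tempdir()
  inputs <- load_inputs(fig3_manifest)
  b <- build_ontology(inputs$taxonomies)
  p <- file.path(d, "fig3.ofn")
  write_functional_syntax(b$ontology, p)
  doc <- parse_functional_syntax(p)
  v <- default_config()$vocabulary
  sc <- Filter(function(a) a$property == v$subcluster_of,
               axioms_of_type(doc, "ObjectPropertyAssertion"))
  expect_identical(length(sc), 2L)
  expect_identical(length(axioms_of_type(doc, "EquivalentClasses")), 3L)
})

test_that("unsupported constructs fail with a located error", {
  bad <- c("Prefix(ONT:=<http://x/>)",
           "Ontology(<http://x/o>",
           "Declaration(Class(ONT:a))",
           "SubClassOf(ONT:a ObjectMinCardinality(2 ONT:p ONT:b))",
           ")")
  err <- tryCatch(parse_functional_syntax(bad), error = function(e) e)
  expect_s3_class(err, "ccn2ont_UNSUPPORTED")
  expect_match(conditionMessage(err), "ObjectMinCardinality")
  expect_match(conditionMessage(err), "line 4")
})

test_that("whitespace and comment variations parse identically", {
  base <- c("Prefix(ONT:=<http://x/>)", "Prefix(CTO:=<http://y/>)",
            "Ontology(<http://x/o>",
            "Declaration(Class(ONT:a))", "Declaration(Class(ONT:b))",
            "Declaration(ObjectProperty(CTO:p))",
            "SubClassOf(ONT:a ObjectSomeValuesFrom(CTO:p ONT:b))",
            ")")
  messy <- c("# a leading comment", "Prefix(ONT:=<http://x/>)",
             "  Prefix(CTO:=<http://y/>)",
             "Ontology(<http://x/o>   # trailing comment",
             "Declaration(  Class( ONT:a ) )",
             "", "Declaration(Class(ONT:b))",
             "Declaration(ObjectProperty(CTO:p))",
             "SubClassOf( ONT:a",
             "  ObjectSomeValuesFrom(CTO:p ONT:b) )", ")")
  expect_identical(write_functional_syntax(parse_functional_syntax(base)),
                   write_functional_syntax(parse_functional_syntax(messy)))
})

test_that("serialization refuses undeclared identifiers and unknown prefixes", {
  doc <- declare(ontology_document(), "ONT:a", "class")
  doc$axioms <- list(ax_subclass("ONT:a", ce_class("ONT:ghost")))
  expect_error(write_functional_syntax(doc), class = "ccn2ont_UNDECLARED")
  doc2 <- declare(ontology_document(prefixes = c(ONT = "http://x/")),
                  "MYSTERY:1", "class")
  expect_error(write_functional_syntax(doc2), class = "ccn2ont_UNKNOWN_PREFIX")
})

test_that("OBO export writes one stanza per class with sorted detail lines", {
  d <- withr::local_tempdir()
  fx <- generate_fixture_set(43, d, n_leaves_anchor = 6, n_leaves_other = 5)
  b <- build_from_manifest(file.path(d, "manifest.json"))
  obo <- write_obo(b$ontology, b$hierarchy)
  n_classes <- sum(b$ontology$entities$kind == "class")
  expect_identical(sum(obo == "[Term]"), n_classes)
  # single parent chain: one is_a per reduced pair
  expect_identical(sum(startsWith(obo, "is_a: ")), nrow(b$hierarchy$pairs))
  syn <- obo[startsWith(obo, "synonym: ")]
  expect_true(all(grepl("^synonym: \".+\" EXACT \\[\\]$", syn)))
  # determinism
  expect_identical(obo, write_obo(b$ontology, b$hierarchy))
})

test_that("numeric annotation literals round-trip at full precision", {
  vv <- default_config()$vocabulary
  doc <- declare(ontology_document(), "ONT:s", "class")
  doc <- declare(doc, vv$fbeta_confidence_score, "annotation_property")
  doc <- add_axioms(doc, ax_annotation(vv$fbeta_confidence_score, "ONT:s",
                                       0.1 + 0.2))
  txt <- write_functional_syntax(doc)
  back <- parse_functional_syntax(txt)
  val <- annotation_map(back, vv$fbeta_confidence_score)[["ONT:s"]]
  expect_identical(as.numeric(val), 0.1 + 0.2)
  expect_identical(format_shortest(0.93), "0.93")
  expect_identical(format_shortest(1), "1")
})
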