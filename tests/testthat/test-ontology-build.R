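cfg <- default_config()
v <- cfg$vocabulary

subcluster_assertions <- function(doc) {
  ax <- axioms_of_type(doc, "ObjectPropertyAssertion")
  Filter(function(a) a$property == v$subcluster_of, ax)
}

test_that("individuals carry direct subcluster links only", {
  tx <- chain_taxonomy(3)  # i3 inside i2 inside i1
  bi <- build_individuals(tx)
  expect_identical(nrow(bi$fragment$entities[
    bi$fragment$entities$kind == "individual", ]), 3L)
  sc <- subcluster_assertions(bi$fragment)
  got <- sort(vapply(sc, function(a) paste(a$subject, a$object), character(1)))
  ind <- bi$individual_index
  expect_identical(got, sort(c(paste(ind[["i2"]], ind[["i1"]]),
                               paste(ind[["i3"]], ind[["i2"]]))))
  # the (i3, i1) hop is entailed, never asserted
  expect_false(paste(ind[["i3"]], ind[["i1"]]) %in% got)

  solo <- tx_from_parents(c(only = NA_character_))
  bs <- build_individuals(solo)
  expect_identical(length(subcluster_assertions(bs$fragment)), 0L)
})

test_that("a tree with n nodes yields n individuals and n-1 subcluster links", {
  gen <- generate_taxonomy(5, n_leaves = 20, max_depth = 4)
  bi <- build_individuals(gen$taxonomy)
  n <- gen$ground_truth$n_nodes
  expect_identical(sum(bi$fragment$entities$kind == "individual"), n)
  expect_identical(length(subcluster_assertions(bi$fragment)),
                   n - length(gen$ground_truth$roots))
})

test_that("classes are defined by a single exemplar equivalence axiom", {
  tx <- chain_taxonomy(3)
  bi <- build_individuals(tx)
  bc <- build_classes(tx, list(), bi$individual_index)
  eqs <- axioms_of_type(bc$fragment, "EquivalentClasses")
  expect_identical(length(eqs), 3L)  # all three nodes flagged
  ex <- exemplar_map(bc$fragment)
  expect_identical(length(ex), 3L)
  expect_identical(unname(ex[bc$class_index[["i2"]]]),
                   unname(bi$individual_index[["i2"]]))
  # the equivalence is exactly "cell and has_exemplar value i"
  eq2 <- Filter(function(a) a$id == bc$class_index[["i2"]], eqs)[[1]]
  expect_identical(render_axiom(eq2), sprintf(
    "EquivalentClasses(%s ObjectIntersectionOf(%s ObjectHasValue(%s %s)))",
    bc$class_index[["i2"]], v$cell, v$has_exemplar,
    bi$individual_index[["i2"]]))
})

test_that("exclusion suppresses classes; leaves are always classed", {
  parents <- c(root = NA, a = "root", b = "root", l1 = "a", l2 = "a",
               l3 = "b", l4 = "b")
  tx <- tx_from_parents(parents, flagged = c("root", "a"))
  bi <- build_individuals(tx)
  cur <- list(curated_class_record("root", exclude = TRUE))
  bc <- build_classes(tx, cur, bi$individual_index)
  # 4 leaves + flagged {root, a} - excluded {root}
  expect_setequal(names(bc$class_index), c("a", "l1", "l2", "l3", "l4"))

  bc2 <- build_classes(tx_from_parents(parents), list(), bi$individual_index)
  expect_setequal(names(bc2$class_index), c("l1", "l2", "l3", "l4"))
})

test_that("naming reproduces cross-species alias wrapping", {
  naming <- default_naming_config()
  naming$anchor_species <- "Mouse"
  marmo <- taxonomy("TXC", "NCBITaxon:9483", "UBERON:0001384", list(
    cluster_node("CS1", preferred_alias = "Sncg_marmo",
                 aligned_alias = "Sncg")), is_anchor = FALSE)
  nm <- expand_templates(marmo$nodes[[1]], marmo, naming = naming)
  expect_identical(nm$label, "(Mouse Sncg)-like (Marmoset)")

  mouse <- taxonomy("TXM", "NCBITaxon:10090", "UBERON:0001384", list(
    cluster_node("CS2", preferred_alias = "L5 ET")), is_anchor = TRUE)
  nm2 <- expand_templates(mouse$nodes[[1]], mouse, naming = naming)
  expect_identical(nm2$label, "L5 ET (Mouse M1)")

  bare <- taxonomy("TXB", "NCBITaxon:10090", "UBERON:0001384", list(
    cluster_node("CS3")), is_anchor = TRUE)
  nm3 <- expand_templates(bare$nodes[[1]], bare, naming = naming)
  expect_identical(nm3$label, "CS3 (Mouse M1)")
  expect_true(nzchar(nm3$label))

  naming$anchor_label <- "{alias} {missing_thing}"
  expect_error(expand_templates(mouse$nodes[[1]], mouse, naming = naming),
               class = "ccn2ont_UNBOUND_PLACEHOLDER")
})

test_that("duplicate generated labels are a hard error naming both classes", {
  tx <- taxonomy("TXD", "NCBITaxon:10090", "UBERON:0001384", list(
    cluster_node("A", preferred_alias = "same"),
    cluster_node("B", preferred_alias = "same")), is_anchor = TRUE)
  bi <- build_individuals(tx)
  expect_error(build_classes(tx, list(), bi$individual_index),
               class = "ccn2ont_LABEL_COLLISION")
})

test_that("marker sets are reified with has_part axioms and an fbeta score", {
  tx <- tx_from_parents(c(root = NA, a = "root", b = "root"))
  bi <- build_individuals(tx)
  bc <- build_classes(tx, list(), bi$individual_index)
  ms <- list(marker_set("a", c("GENE:1", "GENE:2"), 0.93),
             marker_set("a", c("GENE:3"), 0.8, method = "other"),
             marker_set("b", c("GENE:1"), 0.7))
  bm <- build_marker_axioms(ms, bc$class_index, "TX")
  doc <- bm$fragment
  roles <- annotation_map(doc, v$entity_role)
  sids <- names(roles)[roles == "marker_set_class"]
  expect_identical(length(sids), 3L)  # one S per row, two for cluster a
  has_part <- Filter(function(a) a$sup$type == "Some" &&
                       a$sup$property == v$has_part,
                     axioms_of_type(doc, "SubClassOf"))
  expect_identical(length(has_part), 4L)  # total genes
  links <- Filter(function(a) a$sup$type == "Some" &&
                    a$sup$property == v$has_characterizing_marker_set,
                  axioms_of_type(doc, "SubClassOf"))
  expect_identical(length(links), 3L)
  expect_identical(sum(vapply(links, `[[`, character(1), "sub") ==
                         bc$class_index[["a"]]), 2L)
  fb <- annotation_map(doc, v$fbeta_confidence_score)
  expect_setequal(unname(fb), c("0.93", "0.8", "0.7"))
  # rejected design: markers never induce an equivalence axiom
  expect_identical(length(axioms_of_type(doc, "EquivalentClasses")), 0L)
})

test_that("marker rows for unclassed clusters are skipped with a finding", {
  tx <- tx_from_parents(c(root = NA, a = "root", b = "root"))
  bi <- build_individuals(tx)
  bc <- build_classes(tx, list(), bi$individual_index)
  ms <- list(marker_set("root", "GENE:1", 0.5))  # root is not classed
  bm <- build_marker_axioms(ms, bc$class_index, "TX")
  expect_identical(bm$report$code, "MARKERS_NO_CLASS")
  expect_error(build_marker_axioms(ms, bc$class_index, "TX", strict = TRUE),
               class = "ccn2ont_MARKERS_NO_CLASS")
})

test_that("homology groups render pairwise with choose(k,2) axioms", {
  idx <- list(T1 = c(a = "ONT:c1"), T2 = c(b = "ONT:c2"),
              T3 = c(c = "ONT:c3"))
  g3 <- homology_group("G3", data.frame(
    taxonomy_id = c("T1", "T2", "T3"),
    cluster_accession = c("a", "b", "c")))
  bh <- build_homology_axioms(list(g3), idx)
  expect_identical(length(bh$fragment$axioms), 3L)
  g2 <- homology_group("G2", data.frame(
    taxonomy_id = c("T1", "T2"), cluster_accession = c("a", "b")))
  expect_identical(length(build_homology_axioms(list(g2), idx)$fragment$axioms),
                   1L)
  # unresolvable member drops below 2: group dropped with a warning finding
  gx <- homology_group("GX", data.frame(
    taxonomy_id = c("T1", "T2"), cluster_accession = c("a", "zz")))
  bx <- build_homology_axioms(list(gx), idx)
  expect_identical(length(bx$fragment$axioms), 0L)
  expect_identical(bx$report$code, "HOMOLOGY_UNRESOLVED")
})

test_that("dataset links connect every cluster individual when configured", {
  tx <- tx_from_parents(c(root = NA, a = "root", b = "root", c = "root",
                          d = "root", e = "root"))
  bi <- build_individuals(tx)
  ds <- list(dataset_record("DS1", "TX", "https://x.test/1", "t"))
  frag <- build_dataset_links(ds, list(TX = tx), list(TX = bi$individual_index))
  expect_identical(sum(frag$entities$kind == "individual"), 1L)
  expect_identical(length(axioms_of_type(frag, "ObjectPropertyAssertion")), 6L)
  cfg2 <- default_config(); cfg2$dataset_link_level <- "taxonomy"
  frag2 <- build_dataset_links(ds, list(TX = tx),
                               list(TX = bi$individual_index), cfg2)
  expect_identical(length(axioms_of_type(frag2, "ObjectPropertyAssertion")), 1L)
  expect_error(dataset_record("DS2", "TX", ""), class = "ccn2ont_EMPTY_URL")
  empty <- build_dataset_links(list(), list(TX = tx),
                               list(TX = bi$individual_index))
  expect_identical(length(empty$axioms), 0L)
})

test_that("merge is identity-preserving, commutative and deduplicating", {
  tx <- chain_taxonomy(4)
  bi <- build_individuals(tx)
  bc <- build_classes(tx, list(), bi$individual_index)
  x <- bi$fragment; y <- bc$fragment
  empty <- ontology_document()
  expect_identical(merge_ontologies(x, empty), x)
  expect_identical(merge_ontologies(x, y), merge_ontologies(y, x))
  self <- merge_ontologies(x, x)
  expect_identical(length(self$axioms), length(x$axioms))
  # declaration conflicts are hard errors
  a <- declare(ontology_document(), "Z:1", "class")
  b <- declare(ontology_document(), "Z:1", "individual")
  expect_error(merge_ontologies(a, b), class = "ccn2ont_DECL_CONFLICT")
})

test_that("axiom counts on a synthetic build match the closed forms", {
  d <- withr::local_tempdir()
  fx <- generate_fixture_set(13, d)
  b <- build_from_manifest(file.path(d, "manifest.json"))
  doc <- b$ontology
  gt1 <- fx$anchor$ground_truth; gt2 <- fx$other$ground_truth
  n_nodes <- gt1$n_nodes + gt2$n_nodes
  n_roots <- length(gt1$roots) + length(gt2$roots)
  expect_identical(sum(doc$entities$kind == "individual"),
                   n_nodes + length(fx$datasets))
  expect_identical(length(Filter(function(a)
    a$property == v$subcluster_of,
    axioms_of_type(doc, "ObjectPropertyAssertion"))), n_nodes - n_roots)
  # classes = leaves + flagged - excluded, per taxonomy
  expected_classes <- sum(vapply(
    list(list(gt = gt1, tx = fx$anchor$taxonomy),
         list(gt = gt2, tx = fx$other$taxonomy)),
    function(z) length(classed_accessions(
      z$tx, fx$curation_homology$curation[[z$gt$taxonomy_id]])),
    integer(1)))
  expect_identical(length(exemplar_map(doc)), expected_classes)
  # marker-set classes = marker rows that have a class; has_part = their genes
  roles <- annotation_map(doc, v$entity_role)
  kept <- function(tid) Filter(function(s)
    s$cluster_accession %in% names(b$class_indexes[[tid]]),
    fx$markers[[tid]]$marker_sets)
  ms_kept <- c(kept("TXMOUSE"), kept("TXMARMO"))
  expect_identical(sum(roles == "marker_set_class"), length(ms_kept))
  expect_identical(
    length(Filter(function(a) a$sup$type == "Some" &&
                    a$sup$property == v$has_part,
                  axioms_of_type(doc, "SubClassOf"))),
    sum(vapply(ms_kept, function(s) length(s$genes), integer(1))))
  # homology axioms = sum choose(k_i, 2) over fully resolvable groups
  resolvable <- vapply(fx$curation_homology$homology, function(g) {
    k <- sum(vapply(seq_len(nrow(g$members)), function(i)
      g$members$cluster_accession[i] %in%
        names(b$class_indexes[[g$members$taxonomy_id[i]]]), logical(1)))
    if (k >= 2) choose(k, 2) else 0
  }, numeric(1))
  expect_identical(content_summary(doc)$homology_axioms,
                   as.integer(sum(resolvable)))
})
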