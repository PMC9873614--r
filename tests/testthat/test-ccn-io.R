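test_that("dendrogram parsing maps nesting to parent links", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"taxonomy_id":"T","species":"s","brain_region":"r",
    "nodes":[{"accession":"A","height":1.0,
      "children":[{"accession":"B","height":0.5},
                  {"accession":"C","height":0.4}]}]}', p)
  tx <- parse_dendrogram(p)
  expect_identical(length(tx$nodes), 3L)
  parents <- taxonomy_parents(tx)
  expect_identical(unname(parents[c("B", "C")]), c("A", "A"))
  expect_true(is.na(parents[["A"]]))
  expect_identical(tx$nodes[[1]]$confidence, 1.0)

  p2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"accession":"only"}', p2)
  solo <- parse_dendrogram(p2, taxonomy_id = "T1")
  expect_identical(length(solo$nodes), 1L)
  expect_true(is.na(taxonomy_parents(solo)[["only"]]))

  p3 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes":[{"accession":"A"},{"accession":"A"}]}', p3)
  expect_error(parse_dendrogram(p3), class = "ccn2ont_DUP_ACCESSION")
})

test_that("dendrogram and nomenclature round-trip the generator ground truth", {
  d <- withr::local_tempdir()
  gen <- generate_taxonomy(7, n_leaves = 50, max_depth = 5,
                           taxonomy_id = "TXR", dir = d)
  tx <- parse_dendrogram(file.path(d, "TXR_dendrogram.json"))
  tx <- parse_nomenclature_table(file.path(d, "TXR_nomenclature.tsv"), tx)
  gt <- gen$ground_truth
  expect_identical(length(tx$nodes), gt$n_nodes)
  expect_identical(canonical_sort(taxonomy_leaves(tx)), gt$leaves)
  expect_identical(taxonomy_parents(tx)[names(gt$parents)], gt$parents)
  expect_identical(canonical_sort(taxonomy_accessions(tx)[
    vapply(tx$nodes, `[[`, logical(1), "flagged_for_class")]), gt$flagged)
  # every alias and metadata cell survives the round trip
  orig <- gen$taxonomy
  for (i in seq_along(orig$nodes)) {
    a <- orig$nodes[[i]]$accession
    j <- which(taxonomy_accessions(tx) == a)
    expect_identical(tx$nodes[[j]]$preferred_alias,
                     orig$nodes[[i]]$preferred_alias)
    expect_identical(tx$nodes[[j]]$metadata[["cell_set_color"]],
                     orig$nodes[[i]]$metadata[["cell_set_color"]])
  }
})

test_that("nomenclature keeps unrecognised columns and maps the class flag", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_set_accession\tcell_set_class_flag\tcell_set_color",
               "A\ttrue\t#123456"), p)
  recs <- parse_nomenclature_table(p)
  expect_true(recs[[1]]$flagged_for_class)
  expect_identical(recs[[1]]$metadata[["cell_set_color"]], "#123456")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("wrong_column\ttrue", "A\ttrue"), p2)
  expect_error(parse_nomenclature_table(p2), class = "ccn2ont_MISSING_COLUMN")
})

test_that("marker tables resolve symbols against the gene list", {
  genes <- data.frame(identifier = c("GENE:1", "GENE:2"),
                      symbol = c("Sncg", "Vip"))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_set_accession\tmarkers\tf_beta",
               "CLUS_0001\tSncg,Vip\t0.93"), p)
  res <- parse_marker_table(p, genes)
  expect_identical(length(res$marker_sets), 1L)
  expect_identical(res$marker_sets[[1]]$genes, c("GENE:1", "GENE:2"))
  expect_identical(res$marker_sets[[1]]$fbeta, 0.93)

  # case sensitivity is the default; lenient mode drops with a warning entry
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_set_accession\tmarkers\tf_beta",
               "CLUS_0001\tSNCG,Vip\t0.8"), p2)
  res2 <- parse_marker_table(p2, genes, strict = FALSE)
  expect_identical(res2$marker_sets[[1]]$genes, "GENE:2")
  expect_true("UNKNOWN_GENE" %in% res2$report$code)
  expect_error(parse_marker_table(p2, genes, strict = TRUE),
               class = "ccn2ont_UNKNOWN_GENE")
  ci <- default_config(); ci$gene_match_case_insensitive <- TRUE
  res3 <- parse_marker_table(p2, genes, config = ci)
  expect_identical(res3$marker_sets[[1]]$genes, c("GENE:1", "GENE:2"))

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_set_accession\tmarkers\tf_beta", "CLUS_0001\t\t0.9"), p3)
  expect_error(parse_marker_table(p3, genes), class = "ccn2ont_EMPTY_MARKERS")
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_set_accession\tmarkers\tf_beta", "CLUS_0001\tVip\t1.2"), p4)
  expect_error(parse_marker_table(p4, genes), class = "ccn2ont_FBETA_RANGE")
})

test_that("marker fixture counts match the generator record", {
  gen <- generate_taxonomy(21, n_leaves = 12, taxonomy_id = "TXM")
  d <- withr::local_tempdir()
  mk <- generate_markers(22, gen$taxonomy, dir = d)
  res <- parse_marker_table(file.path(d, "TXM_markers.tsv"),
                            parse_gene_list(file.path(d, "gene_list.tsv")))
  expect_identical(length(res$marker_sets), mk$ground_truth$n_rows)
  expect_identical(sum(vapply(res$marker_sets,
                              function(s) length(s$genes), integer(1))),
                   mk$ground_truth$total_genes)
})

test_that("curation rows map typed fields and flag malformed identifiers", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("cell_set_accession", "parent_class_ids",
                     "morphology_term", "projection_term", "extra_synonyms",
                     "exclude", sep = "\t"),
               "A\tCL:0000540\tPATO:0001873\t\tL5 PT\tfalse",
               "B\t\t\t\t\ttrue",
               "C\tnot an id\t\t\t\tfalse"), p)
  res <- parse_curation_table(p)
  expect_identical(res$records[[1]]$parent_class_ids, "CL:0000540")
  expect_identical(res$records[[1]]$morphology_term, "PATO:0001873")
  expect_true(res$records[[2]]$exclude)
  expect_identical(res$report$code, "BAD_TERM_ID")
  expect_identical(res$report$entity, "C")
})

test_that("homology groups assemble across rows and drop singletons", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("homology_group\ttaxonomy_id\tcell_set_accession",
               "G1\tT1\ta", "G1\tT2\tb", "G1\tT3\tc", "G2\tT1\tz"), p)
  res <- parse_homology_table(p)
  expect_identical(length(res$groups), 1L)
  expect_identical(nrow(res$groups[[1]]$members), 3L)
  expect_identical(res$report$code, "SINGLETON_HOMOLOGY")
})

test_that("every table writer round-trips through its reader", {
  d <- withr::local_tempdir()
  fx <- generate_fixture_set(31, d, n_leaves_anchor = 8, n_leaves_other = 6)
  ch <- fx$curation_homology
  # homology
  hp <- file.path(d, "rt_homology.tsv")
  write_homology_table(ch$homology, hp)
  back <- parse_homology_table(hp)$groups
  expect_identical(length(back), length(ch$homology))
  for (i in seq_along(back))
    expect_identical(back[[i]]$members[order(back[[i]]$members$taxonomy_id), ],
                     ch$homology[[i]]$members[
                       order(ch$homology[[i]]$members$taxonomy_id), ],
                     ignore_attr = TRUE)
  # curation
  cp <- file.path(d, "rt_curation.tsv")
  write_curation_table(ch$curation$TXMOUSE, cp)
  back_c <- parse_curation_table(cp)$records
  orig <- ch$curation$TXMOUSE
  orig_by <- orig[order(vapply(orig, `[[`, character(1), "cluster_accession"))]
  expect_identical(lapply(back_c, unclass), lapply(orig_by, unclass))
  # gene list
  gp <- file.path(d, "rt_genes.tsv")
  gl <- fx$markers$TXMOUSE$gene_list
  write_gene_list(gl, gp)
  expect_identical(parse_gene_list(gp),
                   gl[order(gl$identifier), ], ignore_attr = TRUE)
})
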