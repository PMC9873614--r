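test_that("subcluster closure entails exactly the ancestor pairs of a chain", {
  tx <- chain_taxonomy(3)
  cl <- subcluster_closure(tx)
  expect_identical(pairs_key(cl, "descendant", "ancestor"),
                   sort(c("i2 i1", "i3 i2", "i3 i1")))
  solo <- tx_from_parents(c(only = NA_character_))
  expect_identical(nrow(subcluster_closure(solo)), 0L)
})

test_that("closure equals the matrix-power oracle on random trees", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(2:60, 1)
    parents <- random_tree_parents(n)
    tx <- tx_from_parents(parents)
    got <- subcluster_closure(tx)
    keep <- !is.na(parents)
    want <- oracle_closure(names(parents)[keep], unname(parents[keep]))
    expect_identical(pairs_key(got, "descendant", "ancestor"),
                     pairs_key(want, "from", "to"))
  }
})

test_that("a parent cycle is a hard error naming the cycle", {
  doc <- ontology_document()
  doc <- declare(doc, c("ONT:a", "ONT:b"), "individual")
  doc <- declare(doc, "CTO:subcluster_of", "object_property")
  v <- default_config()$vocabulary
  doc <- add_axioms(doc,
                    ax_obj_assertion(v$subcluster_of, "ONT:a", "ONT:b"),
                    ax_obj_assertion(v$subcluster_of, "ONT:b", "ONT:a"))
  expect_error(subcluster_closure(doc), class = "ccn2ont_CYCLE")
})

test_that("the exemplar chain classifies c3 under c2 under c1 and nothing else", {
  b <- build_from_manifest(fig3_manifest)
  ex <- exemplar_map(b$ontology)
  cls <- b$class_indexes$TXFIG3
  dd <- classify_data_driven(b$ontology, subcluster_closure(b$ontology),
                             reduce = FALSE)
  expect_identical(pairs_key(dd$pairs),
                   sort(c(paste(cls[["CS002"]], cls[["CS001"]]),
                          paste(cls[["CS003"]], cls[["CS002"]]),
                          paste(cls[["CS003"]], cls[["CS001"]]))))
  red <- transitive_reduction(dd)
  expect_identical(pairs_key(red$pairs),
                   sort(c(paste(cls[["CS002"]], cls[["CS001"]]),
                          paste(cls[["CS003"]], cls[["CS002"]]))))
  # no reflexive pairs, ever
  expect_false(any(dd$pairs$sub == dd$pairs$sup))
})

test_that("classes sharing an exemplar are reported equivalent, not subsumed", {
  closure <- data.frame(descendant = "i2", ancestor = "i1")
  ex <- c(cA = "i2", cB = "i2", cC = "i1")
  dd <- classify_data_driven(ex, closure)
  expect_identical(dd$equivalences, list(c("cA", "cB")))
  expect_identical(pairs_key(dd$pairs), sort(c("cA cC", "cB cC")))
})

test_that("data-driven classification equals the pairwise oracle on random fixtures", {
  set.seed(202)
  for (rep in 1:15) {
    n <- sample(3:50, 1)
    parents <- random_tree_parents(n)
    # a random subset of nodes gets a class
    classed <- sample(names(parents), max(2, floor(n * 0.6)))
    ex <- stats::setNames(classed, paste0("c_", classed))
    tx <- tx_from_parents(parents)
    dd <- classify_data_driven(ex, subcluster_closure(tx), reduce = FALSE)
    want <- oracle_data_driven(as.list(ex), as.list(parents))
    expect_identical(pairs_key(dd$pairs), pairs_key(want))
  }
})

test_that("structural placement matches the worked grouping-class example", {
  cfg <- default_config()
  inputs <- load_inputs(fig4_manifest, cfg)
  b <- build_from_manifest(fig4_manifest, cfg)
  st <- classify_structural(b$ontology, inputs$stub, config = cfg)
  l5 <- b$class_indexes$TXFIG4[["CS101"]]
  # under both satisfiable grouping classes ...
  expect_setequal(st$pairs$sup[st$pairs$sub == l5],
                  c("FIX:0000020", "FIX:0000021"))
  # ... and under neither distractor (wrong morphology / wrong lineage)
  expect_false(any(st$pairs$sup %in% c("FIX:0000022", "FIX:0000023")))
  other <- b$class_indexes$TXFIG4[["CS102"]]
  expect_identical(sum(st$pairs$sub == other), 0L)
})

test_that("a grouping class with an unmatched conjunct attracts nothing", {
  cfg <- default_config()
  inputs <- load_inputs(fig4_manifest, cfg)
  stub <- inputs$stub
  # tighten the pyramidal grouping with a conjunct nothing asserts
  i <- which(stub$id == "FIX:0000021")
  stub$conjuncts[[i]] <- c(stub$conjuncts[[i]],
                           list(list(type = "some",
                                     property = "CTO:bearer_of",
                                     filler = "FIX:0000012")))
  b <- build_from_manifest(fig4_manifest, cfg)
  st <- classify_structural(b$ontology, stub, config = cfg)
  expect_false("FIX:0000021" %in% st$pairs$sup)
  expect_true("FIX:0000020" %in% st$pairs$sup)
})

test_that("structural placements equal the conjunct-matching oracle on random mini-ontologies", {
  cfg <- default_config()
  v <- cfg$vocabulary
  set.seed(303)
  fillers <- sprintf("STUB:%07d", 100:105)
  named_pool <- sprintf("STUB:%07d", 1:8)
  for (rep in 1:10) {
    # random stub hierarchy over the named pool (parent index < child)
    stub_rows <- lapply(seq_along(named_pool), function(i) {
      parent <- if (i == 1) "" else named_pool[sample.int(i - 1, 1)]
      data.frame(id = named_pool[i], label = named_pool[i], kind = "class",
                 parent = parent, definition_conjuncts = "",
                 stringsAsFactors = FALSE)
    })
    stub <- do.call(rbind, stub_rows)
    stub$conjuncts <- rep(list(list()), nrow(stub))
    # random grouping definitions
    for (gi in sample(2:8, 3)) {
      k <- sample(0:2, 1)
      stub$conjuncts[[gi]] <- c(
        list(list(type = "named", id = stub$parent[gi])),
        lapply(seq_len(k), function(j)
          list(type = "some", property = v$bearer_of,
               filler = sample(fillers, 1))))
      if (stub$parent[gi] == "")
        stub$conjuncts[[gi]][[1]]$id <- named_pool[1]
    }
    # random generated classes with asserted parents and restrictions
    doc <- ontology_document()
    doc <- declare(doc, c(named_pool, fillers), "class")
    doc <- declare(doc, v$bearer_of, "object_property")
    named_sup <- list(); restr <- list()
    cand <- sprintf("ONT:g%02d", 1:8)
    doc <- declare(doc, cand, "class")
    axs <- list()
    for (g in cand) {
      named_sup[[g]] <- sample(named_pool, sample(1:2, 1))
      restr[[g]] <- lapply(seq_len(sample(0:3, 1)), function(j)
        c(v$bearer_of, sample(fillers, 1)))
      for (p in named_sup[[g]]) axs <- c(axs, list(ax_subclass(g, p)))
      for (r in restr[[g]])
        axs <- c(axs, list(ax_subclass(g, ce_some(r[1], r[2]))))
    }
    doc <- add_axioms(doc, axs)
    st <- classify_structural(doc, stub, candidates = cand, config = cfg)
    want <- oracle_structural(named_sup, restr, stub)
    expect_identical(pairs_key(st$pairs), pairs_key(want))
  }
})

test_that("transitive reduction is minimal, idempotent and closure-preserving", {
  h <- inferred_hierarchy(data.frame(
    sub = c("a", "b", "a"), sup = c("b", "c", "c"),
    provenance = "data-driven"))
  red <- transitive_reduction(h)
  expect_identical(pairs_key(red$pairs), sort(c("a b", "b c")))
  expect_identical(transitive_reduction(red)$pairs, red$pairs)
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(4:25, 1)
    ids <- sprintf("x%02d", seq_len(n))
    pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
    pairs <- pairs[pairs$i < pairs$j, ]
    pick <- pairs[stats::runif(nrow(pairs)) < 0.2, ]
    if (!nrow(pick)) next
    h <- inferred_hierarchy(data.frame(sub = ids[pick$i], sup = ids[pick$j],
                                       provenance = "asserted"))
    red <- transitive_reduction(h)
    expect_identical(pairs_key(hierarchy_closure(red)$pairs),
                     pairs_key(hierarchy_closure(h)$pairs))
    expect_true(nrow(red$pairs) <= nrow(unique(h$pairs[, 1:2])))
    expect_identical(transitive_reduction(red)$pairs, red$pairs)
  }
})

test_that("the combined hierarchy stays a DAG and mirrors the cluster tree", {
  d <- withr::local_tempdir()
  fx <- generate_fixture_set(17, d)
  b <- build_from_manifest(file.path(d, "manifest.json"))
  h <- b$hierarchy
  # DAG: closure computation must not error
  expect_s3_class(hierarchy_closure(h), "inferred_hierarchy")
  expect_identical(length(h$equivalences), 0L)
  # data-driven pairs are isomorphic to the cluster hierarchy restricted to
  # classed nodes: check via the exemplar map and the subcluster closure
  ex <- exemplar_map(b$ontology)
  closure <- subcluster_closure(b$ontology)
  anc_key <- paste(closure$descendant, closure$ancestor)
  full <- hierarchy_closure(h)$pairs
  dd <- full[full$sub %in% names(ex) & full$sup %in% names(ex), ]
  expect_identical(sort(paste(ex[dd$sub], ex[dd$sup])) %in% sort(anc_key),
                   rep(TRUE, nrow(dd)))
})
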